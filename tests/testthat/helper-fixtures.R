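# Shared fixtures, lazily built and cached for the whole test run.
# Heavy FEM fixtures use the default phantom geometry at 2 mm voxels
# (solver-grade discretization; see the methods vignette on runtime
# scaling) so the suite stays within desk-scale budgets.

.fix <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fix)) assign(name, build(), envir = .fix)
  get(name, envir = .fix)
}

# default phantom geometry at solver resolution (2 mm)
solver_phantom_spec <- function() {
  phantom_spec(n_slices = 48L, slice_spacing = 2, pixel_spacing = 2,
               n_pixels = 24L)
}

fix_truth_1mm <- function() fixture("truth_1mm", function()
  build_phantom(phantom_spec()))

fix_solver <- function() fixture("solver", function() {
  vol <- build_phantom(solver_phantom_spec())
  mesh <- voxel_to_tet(vol)
  sys <- assemble(mesh, tissue_properties(), f_eval = 1e3)
  electrodes <- list(
    electrode_spec(c(42, 24, 48), "+x", c(20, 20), +1L),
    electrode_spec(c(6, 24, 48), "-x", c(20, 20), -1L))
  load <- electrode_load(sys, electrodes, I = 0.01)
  list(vol = vol, sys = sys, electrodes = electrodes, load = load)
})

fix_solver_dc <- function() fixture("solver_dc", function()
  solve_phasor(fix_solver()$sys, fix_solver()$load, f = 0))

fix_solver_ac <- function() fixture("solver_ac", function()
  solve_phasor(fix_solver()$sys, fix_solver()$load, f = 1e3))

# three-layer slab (skin/fat/muscle along z), full-face electrodes,
# mesh spacing h mm with layer thicknesses 8 h (i.e. h = thickness / 8)
build_slab <- function(h = 0.5, nx = 8L, layer_voxels = 8L) {
  nz <- 3L * layer_voxels
  lab <- array(0L, c(nx, nx, nz))
  lab[, , seq_len(layer_voxels)] <- 3L
  lab[, , layer_voxels + seq_len(layer_voxels)] <- 4L
  lab[, , 2L * layer_voxels + seq_len(layer_voxels)] <- 5L
  vol <- label_volume(lab, rep(h, 3))
  mesh <- voxel_to_tet(vol)
  sys <- assemble(mesh, tissue_properties(), f_eval = 1e3)
  side <- nx * h
  electrodes <- list(
    electrode_spec(c(side / 2, side / 2, nz * h), "+z", c(side, side), +1L),
    electrode_spec(c(side / 2, side / 2, 0), "-z", c(side, side), -1L))
  load <- electrode_load(sys, electrodes, I = 0.01)
  list(vol = vol, sys = sys, electrodes = electrodes, load = load,
       layer_mm = layer_voxels * h)
}

fix_slab <- function() fixture("slab", function() build_slab())

# two-layer concentric cylinder (bone-like core in muscle-like annulus)
build_two_layer_cylinder <- function(h, a = 6, b = 10, height = 8) {
  n <- ceiling(2 * (b + 2) / h)
  nz <- round(height / h)
  ctr <- n * h / 2
  xc <- (seq_len(n) - 0.5) * h - ctr
  d2 <- outer(xc^2, xc^2, `+`)
  sl <- matrix(0L, n, n)
  sl[d2 <= b^2] <- 3L
  sl[d2 <= a^2] <- 2L
  lab <- array(sl, c(n, n, nz))
  vol <- label_volume(lab, rep(h, 3))
  mesh <- voxel_to_tet(vol)
  sys <- assemble(mesh, tissue_properties(), f_eval = 1e3)
  w <- 4                                   # electrode tangential half-width
  electrodes <- list(
    electrode_spec(c(n * h, ctr, height / 2), "+x", c(2 * w, 10 * height),
                   +1L),
    electrode_spec(c(0, ctr, height / 2), "-x", c(2 * w, 10 * height),
                   -1L))
  load <- electrode_load(sys, electrodes, I = 0.01)
  list(vol = vol, sys = sys, load = load, ctr = c(ctr, ctr, height / 2),
       a = a, b = b, height = height, w = w)
}

# homogeneous box + smooth harmonic Neumann load (geometry-exact case)
box_mode_fem_error <- function(h, L = c(16, 16, 16), g0 = 25) {
  vol <- label_volume(array(3L, round(L / h)), rep(h, 3))
  mesh <- voxel_to_tet(vol)
  sys <- assemble(mesh, tissue_properties(), f_eval = 1e3)
  sigma <- tissue_properties_at(tissue_properties(), "muscle", 1e3)[["sigma"]]
  orc <- box_mode_solution(L, sigma, g0)
  fc <- sys$face_centroid * 1e3
  fn <- sys$face_normal
  b <- numeric(nrow(sys$mesh$nodes))
  for (side in list(list(sel = fn[, 3] > 0.9, sgn = +1),
                    list(sel = fn[, 3] < -0.9, sgn = -1))) {
    faces <- which(side$sel)
    g <- side$sgn * orc$flux_top(fc[faces, 1], fc[faces, 2])
    fl <- g * sys$face_area[faces] / 3
    fnodes <- sys$mesh$boundary_faces[faces, , drop = FALSE]
    for (v in 1:3) {
      acc <- tapply(fl, fnodes[, v], sum)
      at <- as.integer(names(acc))
      b[at] <- b[at] + acc
    }
  }
  sol <- solve_phasor(sys, b, f = 0)
  nd <- sys$mesh$nodes
  ex <- orc$phi(nd[, 1], nd[, 2], nd[, 3])
  w <- sys$node_weight
  ex <- ex - sum(w * ex) / sum(w)
  ph <- Re(sol$phi)
  sqrt(sum(w * (ph - ex)^2) / sum(w * ex^2))
}

# voxelized sphere label volume of radius r (skin), grid of half-width R
build_sphere_volume <- function(r = 10, R = 12) {
  n <- 2L * R + 1L
  ax <- seq_len(n) - (R + 1L)
  d2 <- outer(outer(ax^2, ax^2, `+`), ax^2, `+`)
  label_volume(array(ifelse(d2 <= r^2, 5L, 0L), c(n, n, n)), c(1, 1, 1))
}

# noiseless 1 mm pipeline: render -> segment -> reconstruct (surfaces from
# cumulative filled hulls, innermost-wins solidification)
fix_recon_1mm <- function() fixture("recon_1mm", function() {
  truth <- fix_truth_1mm()
  gi <- gray_index(sds = 0)
  seg <- threshold_segment(render_slices(truth, gi, seed = 1),
                           threshold_spec_from_gray_index(gi))
  tc <- tissue_codes()
  surfaces <- lapply(c("skin", "fat", "muscle", "bone", "marrow"),
                     function(t) {
    hull <- label_volume(array(as.integer(seg$labels > 0L &
                                            seg$labels <= tc[[t]]) *
                                 tc[[t]], dim(seg$labels)), seg$spacing)
    reconstruct_surface(extract_point_cloud(hull, t), voxel = 1)
  })
  list(truth = truth, seg = seg, recon = solidify(surfaces, seg))
})
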