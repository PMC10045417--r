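# solver: assembly identities, electrode loads, phasor/transient solves

test_that("stiffness rows sum to zero and energies match linear fields", {
  slab <- fix_slab()
  sys <- slab$sys
  rs <- as.numeric(sys$Ks %*% rep(1, nrow(sys$mesh$nodes)))
  expect_lt(max(abs(rs)), 1e-12 * max(abs(sys$Ks)))
  # energy of a linear potential a.x: phi' K phi = sum_t sigma_t |a|^2 V_t
  nd <- sys$mesh$nodes * 1e-3
  for (a in list(c(1, 0, 0), c(0, 2, -1))) {
    phi <- as.numeric(nd %*% a)
    want <- sum(sys$sigma * sys$vol) * 0 +
      sum(sys$sigma * sys$vol * sum(a^2))
    expect_equal(as.numeric(phi %*% (sys$Ks %*% phi)), want,
                 tolerance = 1e-10)
  }
  # linearity in sigma: doubling one tissue's sigma adds its energy share
  pr <- tissue_properties()
  pr2 <- unclass(pr); pr2$muscle$sigma <- pr2$muscle$sigma * 2
  sys2 <- assemble(sys$mesh, validate_tissue_properties(pr2), f_eval = 1e3)
  phi <- as.numeric(nd %*% c(1, 0, 0))
  mus <- sys$mesh$tissue == tissue_codes()[["muscle"]]
  dE <- as.numeric(phi %*% (sys2$Ks %*% phi)) -
    as.numeric(phi %*% (sys$Ks %*% phi))
  expect_equal(dE, sum(sys$sigma[mus] * sys$vol[mus]), tolerance = 1e-10)
})

test_that("assembly refuses unknown tissue tags", {
  vol <- label_volume(array(5L, c(2, 2, 2)), c(1, 1, 1))
  mesh <- voxel_to_tet(vol)
  expect_error(assemble(mesh, tissue_properties(), 1e3,
                        tag_map = c(skin = "dermis")), "skin")
})

test_that("a 20 x 20 mm patch at 10 mA realizes j = 25 A/m^2", {
  lab <- array(3L, c(20, 20, 10))
  vol <- label_volume(lab, c(1, 1, 1))
  sys <- assemble(voxel_to_tet(vol), tissue_properties(), 1e3)
  e <- list(electrode_spec(c(10, 10, 10), "+z", c(20, 20), +1L),
            electrode_spec(c(10, 10, 0), "-z", c(20, 20), -1L))
  ld <- electrode_load(sys, e, I = 0.01)
  expect_equal(ld$electrodes[[1]]$j_realized, 25, tolerance = 1e-12)
  expect_equal(ld$electrodes[[1]]$area_m2, 4e-4, tolerance = 1e-12)
  # charge balance
  expect_lt(abs(sum(ld$b)), 1e-12 * sum(abs(ld$b)))
  # zero current -> zero load
  ld0 <- electrode_load(sys, e, I = 0)
  expect_true(all(ld0$b == 0))
  # a patch off the surface errors with a diagnostic
  far <- list(electrode_spec(c(200, 200, 5), "+x", c(5, 5), +1L),
              e[[2]])
  expect_error(electrode_load(sys, far, 0.01), "no boundary face")
  # overlapping patches are rejected
  ovl <- list(electrode_spec(c(10, 10, 10), "+z", c(20, 20), +1L),
              electrode_spec(c(11, 10, 10), "+z", c(20, 20), -1L))
  expect_error(electrode_load(sys, ovl, 0.01), "overlap")
})

test_that("phasor solve reproduces the layered slab to far within 2%", {
  slab <- fix_slab()
  pr <- tissue_properties()
  for (f in c(0, 1e3)) {
    sol <- solve_phasor(slab$sys, slab$load, f = f)
    expect_lt(sol$residual, 1e-8)
    lay <- c("skin", "fat", "muscle")           # entry (anode, +z) first
    orc <- slab_solution(rep(slab$layer_mm, 3),
                         sapply(lay, function(t) pr[[t]]$sigma[1]),
                         sapply(lay, function(t) pr[[t]]$eps_r[1]),
                         J0 = slab$load$electrodes[[1]]$j_realized,
                         frequency = f)
    nd <- slab$sys$mesh$nodes
    z_top <- max(nd[, 3])
    nid <- vapply(orc$interfaces_mm, function(dep)
      which(nd[, 3] == z_top - dep & nd[, 1] == nd[1, 1] &
              nd[, 2] == nd[1, 2])[1], integer(1))
    err <- max(Mod(sol$phi[nid] - orc$phi)) / max(Mod(orc$phi))
    expect_lt(err, 0.02)
    expect_lt(err, 1e-6)                        # in fact machine-exact
  }
})

test_that("solve is linear in the load and antisymmetric under swap", {
  slab <- fix_slab()
  s1 <- solve_phasor(slab$sys, slab$load, f = 1e3)
  s2 <- solve_phasor(slab$sys, slab$load$b * 2, f = 1e3)
  expect_lt(max(Mod(s2$phi - 2 * s1$phi)) / max(Mod(s1$phi)), 1e-10)
  swapped <- list(
    electrode_spec(slab$electrodes[[1]]$center, "+z",
                   slab$electrodes[[1]]$edge, -1L),
    electrode_spec(slab$electrodes[[2]]$center, "-z",
                   slab$electrodes[[2]]$edge, +1L))
  ld_sw <- electrode_load(slab$sys, swapped, I = 0.01)
  s3 <- solve_phasor(slab$sys, ld_sw, f = 1e3)
  expect_lt(max(Mod(s3$phi + s1$phi)) / max(Mod(s1$phi)), 1e-10)
})

test_that("potential differences are gauge independent", {
  slab <- fix_slab()
  n <- nrow(slab$sys$mesh$nodes)
  sA <- solve_phasor(slab$sys, slab$load, f = 1e3, gauge = "zero-mean")
  sB <- solve_phasor(slab$sys, slab$load, f = 1e3, gauge = "ground",
                     ground = max(1L, n %/% 2L))
  dA <- sA$phi - sA$phi[1]
  dB <- sB$phi - sB$phi[1]
  expect_lt(max(Mod(dA - dB)) / max(Mod(dA)), 1e-10)
  # zero-mean gauge: volume-weighted mean vanishes
  w <- slab$sys$node_weight
  expect_lt(Mod(sum(w * sA$phi)) / sum(w), 1e-10 * max(Mod(sA$phi)))
})

test_that("incompatible loads are rejected", {
  slab <- fix_slab()
  b <- slab$load$b
  b[1] <- b[1] + 1
  expect_error(solve_phasor(slab$sys, b), "incompatible")
})

test_that("transient DC relaxes to the resistive solution", {
  slab <- fix_slab()
  tr <- solve_transient(slab$sys, slab$load, stimulus_waveform("DC", 0.01))
  dc <- solve_phasor(slab$sys, slab$load, f = 0)
  final <- tr$stored_phi[, ncol(tr$stored_phi)]
  expect_lt(max(abs(final - Re(dc$phi))) / max(abs(dc$phi)), 0.005)
})

test_that("transient AC settles onto the phasor amplitude within 1%", {
  slab <- fix_slab()
  tr <- solve_transient(slab$sys, slab$load,
                        stimulus_waveform("AC", 0.01, 1e3))
  amp <- ac_amplitude(tr)
  ph <- Mod(solve_phasor(slab$sys, slab$load, f = 1e3)$phi)
  sel <- ph > 0.05 * max(ph)
  expect_lt(max(abs(amp[sel] - ph[sel]) / ph[sel]), 0.01)
})

test_that("transient guards: zero stimulus, under-resolved cycle, limits", {
  slab <- fix_slab()
  tr0 <- solve_transient(slab$sys, slab$load,
                         stimulus_waveform("AC", 0, 1e3), t_end = 2e-3)
  expect_true(all(tr0$traces == 0))
  expect_error(solve_transient(slab$sys, slab$load,
                               stimulus_waveform("AC", 0.01, 1e3),
                               dt = 1e-3), "under-resolves")
  expect_error(stimulus_waveform("DC", 0.05), "20 mA")
})

test_that("element current density honors the slab flux and linearity", {
  slab <- fix_slab()
  dc <- solve_phasor(slab$sys, slab$load, f = 0)
  J <- current_density(dc, slab$sys)
  jm <- attr(J, "Jmag")
  j0 <- slab$load$electrodes[[1]]$j_realized
  expect_lt(max(abs(jm - j0) / j0), 0.01)      # uniform axial flux
  # doubling current doubles J everywhere
  ld2 <- electrode_load(slab$sys, slab$electrodes, I = 0.02)
  J2 <- current_density(solve_phasor(slab$sys, ld2, f = 0), slab$sys)
  expect_lt(max(Mod(J2 - 2 * J)) / max(Mod(J)), 1e-9)
  # recovered electrode current within 0.5%
  I_rec <- armstim:::boundary_flux(slab$sys, J,
                                   slab$load$electrodes[[2]]$faces)
  expect_lt(abs(abs(I_rec) - 0.01) / 0.01, 0.005)
})
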