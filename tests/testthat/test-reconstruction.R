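# reconstruction: cleaning, surfaces, solidification, thin-layer growth

test_that("outlier removal strips far points and keeps regular shells", {
  # perfectly regular shell (equal kNN statistics): points on a circle
  th <- seq(0, 2 * pi, length.out = 201)[-201]
  ring <- point_cloud(cbind(10 * cos(th), 10 * sin(th), 0), "skin")
  expect_identical(clean_point_cloud(ring, k = 8, sd_factor = 2)$points,
                   ring$points)
  # the ring plus 5 points at 10x radius: exactly those 5 removed
  out5 <- ring$points[seq(1, 200, by = 40), ] * 10
  noisy <- point_cloud(rbind(ring$points, out5), "skin")
  cleaned <- clean_point_cloud(noisy, k = 8, sd_factor = 2)
  expect_identical(cleaned$points, ring$points)
  # a voxel-sphere shell (nearly regular) loses at most a few percent
  pc <- extract_point_cloud(build_sphere_volume(), "skin")
  kept <- clean_point_cloud(pc, k = 8, sd_factor = 2)
  expect_gte(nrow(kept$points), 0.97 * nrow(pc$points))
  # degenerate sizes
  expect_identical(nrow(clean_point_cloud(point_cloud(
    matrix(numeric(0), 0, 3), "skin"))$points), 0L)
  expect_warning(small <- clean_point_cloud(point_cloud(
    diag(3), "skin"), k = 8), "unchanged")
  expect_identical(nrow(small$points), 3L)
})

test_that("sphere cloud reconstructs to a watertight, volume-true surface", {
  pc <- extract_point_cloud(build_sphere_volume(), "skin")
  s <- reconstruct_surface(pc, voxel = 1)
  expect_true(isTRUE(surface_is_watertight(s)))
  v_true <- 4 / 3 * pi * 10^3
  expect_lt(abs(surface_volume(s) - v_true) / v_true, 0.05)
  chi <- surface_euler(s)
  expect_identical(chi %% 2L, 0L)              # closed orientable: 2 - 2g
  expect_lte(chi, 2L)
  expect_error(reconstruct_surface(point_cloud(matrix(numeric(0), 0, 3),
                                               "skin")), "failed")
})

test_that("phantom skin surface area matches the tapered cylinder", {
  spec <- phantom_spec()
  vol <- fix_truth_1mm()
  hull <- label_volume(array(as.integer(vol$labels > 0L) * 5L,
                             dim(vol$labels)), vol$spacing)
  s <- reconstruct_surface(extract_point_cloud(hull, "skin"), voxel = 1)
  r <- spec$outer_radius_profile
  analytic <- sum(2 * pi * r) * spec$slice_spacing +
    pi * r[1]^2 + pi * r[length(r)]^2          # lateral + end caps
  expect_lt(abs(surface_area(s) - analytic) / analytic, 0.10)
})

test_that("solidify labels by innermost containing surface", {
  vol <- build_sphere_volume()
  s_outer <- reconstruct_surface(extract_point_cloud(vol, "skin"), 1)
  grid <- list(dim = dim(vol$labels), spacing = vol$spacing,
               origin = vol$origin)
  lab <- solidify(list(s_outer), grid)
  oracle <- sum(vol$labels > 0L)               # analytic containment count
  expect_lt(abs(sum(lab$labels > 0L) - oracle) / oracle, 0.02)
  # nested spheres: inner tissue wins inside both
  inner_vol <- build_sphere_volume(r = 5)
  s_inner <- reconstruct_surface(extract_point_cloud(inner_vol, "skin"), 1)
  s_inner$tissue <- "muscle"
  lab2 <- solidify(list(s_outer, s_inner), grid)
  ctr <- round(dim(vol$labels) / 2)
  expect_identical(lab2$labels[ctr[1], ctr[2], ctr[3]],
                   tissue_codes()[["muscle"]])
  expect_gt(sum(lab2$labels == tissue_codes()[["skin"]]), 0L)
  # non-watertight input is rejected
  broken <- s_outer
  broken$triangles <- broken$triangles[-1, ]
  expect_error(solidify(list(broken), grid), "watertight")
})

test_that("full reconstruct path achieves Dice >= 0.95 per tissue", {
  fx <- fix_recon_1mm()
  vol <- fx$truth; recon <- fx$recon
  tc <- tissue_codes()
  for (t in c("skin", "fat", "muscle", "bone", "marrow")) {
    a <- vol$labels == tc[[t]]; b <- recon$labels == tc[[t]]
    expect_gte(2 * sum(a & b) / (sum(a) + sum(b)), 0.95)
  }
  # total body volume change < 3% (before any skin compensation)
  expect_lt(abs(sum(recon$labels > 0L) - sum(vol$labels > 0L)) /
              sum(vol$labels > 0L), 0.03)
})

test_that("thin-layer compensation is a morphological rind and idempotent", {
  # thin 0.4 mm skin at 1 mm voxels: skin occupies under one voxel, so the
  # compensated skin must contain body minus its 1-voxel erosion
  spec <- phantom_spec(n_slices = 16L, skin_thickness = 0.4,
                       fat_thickness = 4.6)
  vol <- build_phantom(spec)
  out <- compensate_thin_layers(vol, "skin", 1)
  body <- vol$labels > 0L
  rind <- body & !armstim:::erode6_lateral(body, 1L)
  expect_true(all(out$labels[rind] == tissue_codes()[["skin"]]))
  # fat loses exactly the converted voxels, nothing else changes
  changed <- out$labels != vol$labels
  expect_true(all(vol$labels[changed] == tissue_codes()[["fat"]]))
  expect_true(all(changed[rind] | vol$labels[rind] ==
                    tissue_codes()[["skin"]]))
  # silhouette preserved
  expect_identical(out$labels > 0L, body)
  # idempotence
  twice <- compensate_thin_layers(out, "skin", 1)
  expect_identical(twice$labels, out$labels)
  # already-thick skin: unchanged
  vol2 <- fix_truth_1mm()
  expect_identical(compensate_thin_layers(vol2, "skin", 1)$labels,
                   vol2$labels)
  expect_error(compensate_thin_layers(vol, "skin", 1e3), "radius")
})
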