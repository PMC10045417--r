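# arm_phantom: voxelization, gray rendering, invariants

test_that("single-tissue cylinder voxelizes to the discretized volume", {
  spec <- phantom_spec(n_slices = 10L, n_pixels = 24L, outer_radius = 10,
                       skin_thickness = 9.99, fat_thickness = 0.005,
                       bone_radius = 0, cortical_thickness = 0)
  vol <- build_phantom(spec)
  lab <- vol$labels
  expect_true(all(lab[lab > 0L] == tissue_codes()[["skin"]]))
  # independent count: voxel centers within 10 mm of the grid axis
  xc <- (seq_len(24) - 0.5) - 12
  inside <- sum(outer(xc^2, xc^2, `+`) <= 100)
  expect_identical(sum(lab > 0L), inside * 10L)
})

test_that("default phantom matches a brute-force point classifier", {
  spec <- phantom_spec()
  vol <- fix_truth_1mm()
  # scalar re-implementation of the region rules, checked on a sample
  classify_point <- function(x, y, k) {
    r_out <- spec$outer_radius_profile[k]
    r_fat <- r_out - spec$skin_thickness
    r_mus <- r_fat - spec$fat_thickness
    d <- sqrt(x^2 + y^2)
    db <- sqrt((x - spec$bone_center[1])^2 + (y - spec$bone_center[2])^2)
    if (d > r_out) return(0L)
    if (d > r_fat) return(tissue_codes()[["skin"]])
    if (d > r_mus) return(tissue_codes()[["fat"]])
    if (db <= spec$bone_radius - spec$cortical_thickness)
      return(tissue_codes()[["marrow"]])
    if (db <= spec$bone_radius) return(tissue_codes()[["bone"]])
    tissue_codes()[["muscle"]]
  }
  set.seed(99)
  idx <- cbind(sample(48, 4000, TRUE), sample(48, 4000, TRUE),
               sample(96, 4000, TRUE))
  got <- vol$labels[idx]
  ctr <- voxel_centers(vol, idx)
  want <- vapply(seq_len(nrow(idx)), function(q)
    classify_point(ctr[q, 1] - 24, ctr[q, 2] - 24, idx[q, 3]), integer(1))
  expect_identical(got, want)
})

test_that("phantom scales to the full 727-slice acquisition", {
  spec <- phantom_spec(n_slices = 727L)
  vol <- build_phantom(spec)
  expect_identical(dim(vol$labels)[3], 727L)
})

test_that("voxelized volume tracks the analytic arm volume within 2%", {
  spec <- phantom_spec()
  vol <- fix_truth_1mm()
  v_vox <- sum(vol$labels > 0L) * prod(vol$spacing)
  expect_lt(abs(v_vox - phantom_analytic_volume(spec)) /
              phantom_analytic_volume(spec), 0.02)
})

test_that("inconsistent phantom specs are rejected with a slice index", {
  expect_error(phantom_spec(outer_radius = c(20, 4), skin_thickness = 3,
                            fat_thickness = 3, bone_radius = 0,
                            cortical_thickness = 0),
               "slice")
  expect_error(phantom_spec(bone_center = c(12, 0)), "bone")
})

test_that("noiseless rendering is exact and seeded rendering reproducible", {
  vol <- build_phantom(phantom_spec(n_slices = 8L))
  gi0 <- gray_index(sds = 0)
  st <- render_slices(vol, gi0, seed = 5)
  expect_identical(unname(st$images[2, 2, 1]),
                   unname(gi0$means[["background"]]))
  expect_true(all(st$images == gi0$means[tissue_name(vol$labels)]))
  gi <- gray_index()
  s1 <- render_slices(vol, gi, seed = 11)
  s2 <- render_slices(vol, gi, seed = 11)
  expect_identical(s1$images, s2$images)
  expect_false(identical(s1$images, render_slices(vol, gi, seed = 12)$images))
})

test_that("per-tissue rendered means follow normal sampling theory", {
  vol <- build_phantom(phantom_spec(n_slices = 16L))
  gi <- gray_index(sds = 2)
  st <- render_slices(vol, gi, seed = 21)
  for (t in c("muscle", "fat", "skin")) {
    px <- st$images[vol$labels == tissue_codes()[[t]]]
    expect_lt(abs(mean(px) - gi$means[[t]]), 3 * 2 / sqrt(length(px)))
  }
})

test_that("rendering demands a gray entry for every present label", {
  vol <- build_phantom(phantom_spec(n_slices = 4L))
  gi <- gray_index(means = c(background = 10, muscle = 90, marrow = 135,
                             fat = 180, skin = 225))
  expect_error(render_slices(vol, gi, 1), "bone")
})

test_that("label volumes round-trip through voxel centers and files", {
  vol <- build_phantom(phantom_spec(n_slices = 6L, n_pixels = 16L,
                                    outer_radius = c(6, 5),
                                    skin_thickness = 1, fat_thickness = 1,
                                    bone_radius = 1.5,
                                    cortical_thickness = 0.75,
                                    bone_center = c(0.5, 0)))
  idx <- which(vol$labels > 0L, arr.ind = TRUE)
  ctr <- voxel_centers(vol, idx)
  back <- armstim:::point_to_voxel(vol, ctr)
  expect_identical(unname(back), unname(idx))
  path <- tempfile(fileext = ".json")
  write_label_volume(vol, path)
  vol2 <- read_label_volume(path)
  expect_identical(vol2$labels, vol$labels)
  expect_equal(vol2$spacing, vol$spacing)
})
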