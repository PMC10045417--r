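# postprocess: traces, profiles, effective depth, sections

test_that("effective depth follows the threshold-crossing rule", {
  prof <- function(pos, j) structure(
    data.frame(pos_mm = pos, j_mag = j,
               tissue = rep("muscle", length(pos))),
    class = c("line_profile", "data.frame"))
  # linear fall 25 -> 5 over 20 mm crosses 10 A/m^2 at 15 mm
  p <- prof(seq(0, 20, by = 0.5), 25 - seq(0, 20, by = 0.5))
  expect_identical(effective_depth(p, 10), 15)
  # everywhere above threshold: saturates at half the segment
  expect_identical(effective_depth(prof(seq(0, 30, 1), rep(50, 31)), 10), 15)
  # entry below threshold
  expect_identical(effective_depth(prof(0:10, rep(1, 11)), 10), 0)
  expect_error(effective_depth(p, -1), "threshold")
  # monotone non-increasing in threshold on a palindromic profile
  pos <- seq(0, 40, by = 0.25)
  jj <- 30 * exp(-((pos - 0) / 12)^2) + 30 * exp(-((pos - 40) / 12)^2) + 1
  pp <- prof(pos, jj)
  depths <- vapply(c(2, 5, 10, 20, 29), function(th)
    effective_depth(pp, th), numeric(1))
  expect_true(all(diff(depths) <= 0))
})

test_that("percent excess reproduces the printed tACS/tDCS comparisons", {
  expect_identical(percent_excess(24.96, 20.51), 21.7)
  expect_identical(percent_excess(25.72, 21.12), 21.8)
  expect_identical(percent_excess(27.223, 22.27), 22.2)
  expect_identical(percent_excess(7, 7), 0)
  expect_gt(percent_excess(8, 7), 0)
  expect_lt(percent_excess(6, 7), 0)
  expect_error(percent_excess(1, 0), "b must be")
})

test_that("probe traces behave like RC charging and phasor steady state", {
  slab <- fix_slab()
  tr0 <- solve_transient(slab$sys, slab$load,
                         stimulus_waveform("AC", 0, 1e3), t_end = 1e-3)
  expect_true(all(probe_trace(tr0, 1)$value_v == 0))
  trd <- solve_transient(slab$sys, slab$load, stimulus_waveform("DC", 0.01))
  td <- probe_trace(trd, 1)
  expect_true(all(diff(td$value_v) > -1e-9 * max(abs(td$value_v))))
  expect_identical(nrow(td), length(trd$times))
  tra <- solve_transient(slab$sys, slab$load,
                         stimulus_waveform("AC", 0.01, 1e3))
  ph <- solve_phasor(slab$sys, slab$load, f = 1e3)
  node <- tra$probe_nodes[1]
  # amplitude of the last recorded cycle vs phasor magnitude at that node
  amp <- ac_amplitude(tra)[node]
  expect_lt(abs(amp - Mod(ph$phi[node])) / Mod(ph$phi[node]), 0.01)
  expect_error(probe_trace(ph, 1), "transient")
})

test_that("line profiles sample the expected geometry", {
  slab <- fix_slab()
  dc <- solve_phasor(slab$sys, slab$load, f = 0)
  # homogeneous-column equivalent: uniform axial flux -> constant profile
  p <- line_profile(dc, slab$sys, slab$load, n = 50)
  expect_lt(diff(range(p$j_mag)) / mean(p$j_mag), 0.02)
  p2 <- line_profile(dc, slab$sys, slab$load, n = 2)
  expect_identical(nrow(p2), 2L)
  expect_equal(p2$pos_mm[2], vnorm(
    slab$sys$mesh$nodes[slab$load$electrodes[[2]]$contact_node, ] -
      slab$sys$mesh$nodes[slab$load$electrodes[[1]]$contact_node, ]),
    tolerance = 1e-9)
  # phantom: palindromic tissue sequence through the bone
  fs <- fix_solver()
  dcp <- fix_solver_dc()
  pp <- line_profile(dcp, fs$sys, fs$load, n = 200)
  seq_t <- rle(as.character(pp$tissue))$values
  expect_identical(seq_t, c("skin", "fat", "muscle", "bone", "marrow",
                            "bone", "muscle", "fat", "skin"))
})

test_that("sections interpolate the field and mask the silhouette", {
  slab <- fix_slab()
  dc <- solve_phasor(slab$sys, slab$load, f = 0)
  sec <- export_section(dc, slab$sys, axis = "z",
                        offset = 6.25, resolution = 0.5)
  # cross-section integral of |J| recovers the injected current within 5%
  cell <- (0.5e-3)^2
  I_sec <- sum(sec$j_mag[sec$mask]) * cell
  expect_lt(abs(I_sec - 0.01) / 0.01, 0.05)
  # constant phi -> constant sampled grid
  const <- structure(list(mode = "phasor", phi = rep(2 + 0i,
                            nrow(slab$sys$mesh$nodes)), f = 0,
                          gauge = "zero-mean", residual = 0),
                     class = "field_solution")
  sec2 <- export_section(const, slab$sys, axis = "z", offset = 6.25,
                         resolution = 1)
  expect_true(all(abs(sec2$phi[sec2$mask] - 2) < 1e-12))
  expect_true(all(sec2$j_mag[sec2$mask] < 1e-9))
  expect_error(export_section(dc, slab$sys, axis = "z", offset = 99),
               "intersect")
  # phantom: the no-data mask matches the body silhouette on that plane
  fs <- fix_solver()
  dcp <- fix_solver_dc()
  secp <- export_section(dcp, fs$sys, axis = "z", offset = 47,
                         resolution = 2)
  sil <- fs$vol$labels[, , 24] > 0L
  expect_gt(mean(secp$mask == sil), 0.98)
})
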