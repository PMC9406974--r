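test_that("CTP core segmentation recovers the phantom core", {
  ph <- make_phantom(small_spec(noise_sd = 0))
  run <- quiet_ctp(ph$series)
  expect_gte(dice(run$core_mask, ph$truth_core_mask), 0.95)

  # uniform-CBF brain: nothing below 30% of its own median
  ph0 <- make_phantom(small_spec(noise_sd = 0, core_region = NULL,
                                 penumbra_region = NULL))
  run0 <- quiet_ctp(ph0$series)
  expect_equal(sum(run0$core_mask), 0)
  expect_equal(run0$result$icv, 0)
})

test_that("lowering rcbf_frac never increases the core", {
  ph <- make_phantom(small_spec(noise_sd = 0))
  run <- quiet_ctp(ph$series)
  fracs <- c(0.6, 0.45, 0.3, 0.15)
  sizes <- vapply(fracs, function(f)
    sum(segment_core_ctp(run$maps, thresholds(rcbf_frac = f))), integer(1))
  expect_true(all(diff(sizes) <= 0))
})

test_that("ADC core segmentation: exact recovery, boundary and units", {
  ph <- make_phantom(small_spec(noise_sd = 0))
  sp <- small_spec()
  seg <- segment_core_adc(ph$truth_adc, ph$brain_mask, thresholds(),
                          sp$voxel_size)
  expect_identical(seg, ph$truth_core_mask)

  # everything above threshold -> empty core
  high <- array(800e-6, dim(ph$truth_adc))
  expect_equal(sum(segment_core_adc(high, ph$brain_mask, thresholds(),
                                    sp$voxel_size)), 0)

  # boundary value exactly 620e-6 is excluded (strict less-than)
  at <- array(620e-6, dim(ph$truth_adc))
  expect_equal(sum(segment_core_adc(at, ph$brain_mask, thresholds(),
                                    sp$voxel_size)), 0)

  # mis-scaled units are rejected
  expect_error(segment_core_adc(array(0.62, dim(ph$truth_adc)),
                                ph$brain_mask, thresholds(), sp$voxel_size),
               class = "perf_unit_error")
})

test_that("penumbra: matches truth, disjoint from core, empty when unperfused", {
  ph <- make_phantom(small_spec(noise_sd = 0))
  run <- quiet_ctp(ph$series)
  truth_pen <- ph$truth_penumbra_mask & !ph$truth_core_mask
  expect_gte(dice(run$penumbra_mask, truth_pen), 0.95)
  expect_false(any(run$penumbra_mask & run$core_mask))

  maps0 <- run$maps
  maps0$tmax[] <- 0
  expect_equal(sum(segment_penumbra(maps0, run$core_mask)), 0)
})

test_that("phantom monotonicity: lower core CBF and longer delay grow lesions", {
  v_core <- sapply(c(25, 15, 5), function(cbf) {
    ph <- make_phantom(small_spec(noise_sd = 0,
      core_region = list(center = c(12, 16, 4), semi_axes_mm = c(15, 12, 9),
                         cbf = cbf)))
    quiet_ctp(ph$series)$result$icv
  })
  expect_true(all(diff(v_core) >= 0))

  v_pen <- sapply(c(7, 9, 12), function(d) {
    ph <- make_phantom(small_spec(noise_sd = 0,
      penumbra_region = list(center = c(12, 16, 4),
                             semi_axes_mm = c(22, 18, 13), delay_s = d)))
    quiet_ctp(ph$series)$result$pv
  })
  expect_true(all(diff(v_pen) >= 0))
})

test_that("mask_volume arithmetic", {
  m <- array(FALSE, c(20, 10, 5))
  m[1:10, 1:10, 1:5] <- TRUE   # 500 voxels
  expect_equal(mask_volume(m, c(1, 1, 2)), 1.0)
  expect_equal(mask_volume(array(FALSE, c(4, 4, 4)), c(1, 1, 1)), 0)
  m2 <- array(FALSE, c(5, 5, 5)); m2[1:70] <- TRUE
  expect_equal(mask_volume(m2, c(10, 10, 10)), 70)
  expect_error(mask_volume(m, c(1, -1, 1)), class = "perf_parameter_error")
})

test_that("mismatch profile: worked volumes, zero-core and equal-volume cases", {
  r <- mismatch_profile(74, 164)
  expect_equal(r$mismatch_volume, 90)
  expect_equal(r$mismatch_ratio, 164 / 74, tolerance = 1e-12)
  expect_equal(round(r$mismatch_ratio, 3), 2.216)

  z <- mismatch_profile(0, 20)
  expect_identical(z$mismatch_ratio, Inf)
  expect_equal(z$mismatch_volume, 20)

  e <- mismatch_profile(10, 10)
  expect_equal(e$mismatch_volume, 0)
  expect_equal(e$mismatch_ratio, 1)

  b <- mismatch_profile(0, 0)
  expect_equal(b$mismatch_ratio, 0)

  expect_error(mismatch_profile(-1, 10), class = "perf_parameter_error")
})

test_that("DEFUSE3 triage: worked examples and criterion bookkeeping", {
  d1 <- triage_defuse3(mismatch_profile(74, 164))
  expect_false(d1$eligible)
  expect_identical(d1$failed_criteria, "icv")

  d2 <- triage_defuse3(mismatch_profile(67, 148))
  expect_true(d2$eligible)
  expect_identical(d2$failed_criteria, character(0))

  d3 <- triage_defuse3(mismatch_profile(10, 15))
  expect_false(d3$eligible)
  expect_true("volume" %in% d3$failed_criteria)

  # boundary cases fall on the printed side (strict inequalities)
  expect_false(triage_defuse3(mismatch_profile(70, 200))$eligible)  # icv = 70
  d4 <- triage_defuse3(mismatch_profile(10, 18))                    # ratio = 1.8
  expect_true("ratio" %in% d4$failed_criteria)

  # zero core, large penumbra: ratio Inf, eligible if the rest passes
  expect_true(triage_defuse3(mismatch_profile(0, 20))$eligible)
})

test_that("triage monotonicity: decreasing icv never revokes eligibility", {
  pv <- 60
  icvs <- seq(60, 0, by = -5)
  elig <- vapply(icvs, function(i) triage_defuse3(mismatch_profile(i, pv))$eligible,
                 logical(1))
  # once eligible while icv decreases, never flips back
  first <- which(elig)[1]
  expect_true(all(elig[first:length(elig)]))
})

test_that("small clusters are removed at the configured volume", {
  maps <- list(rcbf = array(60, c(20, 20, 6)), tmax = array(0, c(20, 20, 6)),
               brain_mask = array(TRUE, c(20, 20, 6)), voxel_size = c(3, 3, 6),
               dt = 1.5)
  class(maps) <- "perfusion_maps"
  maps$rcbv <- maps$rcbf * 4 / 60
  maps$mtt <- array(4, c(20, 20, 6))
  # one 2-voxel speck (0.108 mL) and one 5x4x2-voxel slab (2.16 mL) above 6 s
  maps$tmax[2, 2, 1] <- 8; maps$tmax[2, 3, 1] <- 8
  maps$tmax[10:14, 10:13, 3:4] <- 8
  pen <- segment_penumbra(maps, array(FALSE, c(20, 20, 6)), thresholds())
  expect_equal(sum(pen), 5 * 4 * 2)
})
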