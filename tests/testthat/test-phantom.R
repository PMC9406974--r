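test_that("gamma-variate curve: pre-arrival zero, closed-form mode, linearity", {
  p <- gamma_variate_params(amplitude = 2, t0 = 5, alpha = 3, beta = 1.2)
  expect_identical(gamma_variate_curve(p, c(0, 4)), c(0, 0))
  expect_identical(gamma_variate_curve(p, 5 - 1), 0)

  tg <- seq(0, 40, by = 0.01)
  y <- gamma_variate_curve(p, tg)
  expect_true(all(y >= 0))
  expect_lt(abs(tg[which.max(y)] - (5 + 3 * 1.2)), 0.011)

  p2 <- gamma_variate_params(amplitude = 4, t0 = 5, alpha = 3, beta = 1.2)
  expect_equal(gamma_variate_curve(p2, tg), 2 * y)
})

test_that("gamma-variate parameter validation", {
  expect_error(gamma_variate_params(alpha = 0), class = "perf_parameter_error")
  expect_error(gamma_variate_params(beta = -1), class = "perf_parameter_error")
  expect_error(gamma_variate_curve(gamma_variate_params(), c(1, 1, 2)),
               class = "perf_parameter_error")
})

test_that("tissue curve: zero flow, delay shift, linearity in CBF", {
  dt <- 1.5
  times <- (0:39) * dt
  ca <- gamma_variate_curve(gamma_variate_params(), times)
  expect_identical(synthesize_tissue_curve(ca, 0, 4, 0, dt), numeric(40))

  c0 <- synthesize_tissue_curve(ca, 60, 4, 0, dt)
  c3 <- synthesize_tissue_curve(ca, 60, 4, 3, dt)
  k <- round(3 / dt)
  expect_equal(c3[(k + 1):40], c0[1:(40 - k)], tolerance = 1e-12)
  expect_equal(c3[seq_len(k)], numeric(k))

  expect_equal(synthesize_tissue_curve(ca, 120, 4, 0, dt), 2 * c0, tolerance = 1e-12)
})

test_that("tissue curve satisfies the central-volume identity", {
  # oracle: the discrete areas must relate by the printed rCBV scaling
  # with CBV_true = CBF * MTT / 60; verified by direct numerical
  # integration of the generated curves (rectangle rule)
  cst <- scaling_constants()
  dt <- 1.5
  times <- (0:39) * dt
  ca <- gamma_variate_curve(gamma_variate_params(), times)
  for (mtt in c(3, 6, 12)) for (cbf in c(20, 60)) {
    ct <- synthesize_tissue_curve(ca, cbf, mtt, 0, dt, cst)
    ratio <- (sum(ct) * dt) / (sum(ca) * dt)
    expected <- (cst$rho / (100 * cst$k_av)) *
      ((1 - cst$h_lv) / (1 - cst$h_sv)) * (cbf * mtt / 60)
    expect_lt(abs(ratio - expected) / expected, 0.02)
  }
})

test_that("make_phantom is deterministic and respects the noise model", {
  sp <- small_spec(noise_sd = 0.5)
  a <- make_phantom(sp)
  b <- make_phantom(sp)
  expect_identical(a$series$data, b$series$data)
  expect_identical(a$truth_adc, b$truth_adc)

  # different seed changes the noise
  sp2 <- small_spec(noise_sd = 0.5, seed = 7L)
  expect_false(identical(make_phantom(sp2)$series$data, a$series$data))

  # noiseless core voxel equals the forward-model curve exactly
  sp0 <- small_spec(noise_sd = 0)
  ph <- make_phantom(sp0)
  vox <- which(ph$truth_core_mask, arr.ind = TRUE)[1, ]
  curve <- ph$series$data[vox[1], vox[2], vox[3], ]
  times <- ph$series$frame_times
  ca <- gamma_variate_curve(sp0$aif, times)
  expected <- 40 + synthesize_tissue_curve(ca, sp0$core_region$cbf,
    sp0$tissue_mtt_normal, sp0$penumbra_region$delay_s, sp0$dt, sp0$constants)
  expect_equal(curve, expected, tolerance = 1e-12)
})

test_that("truth masks: geometry, subset relation and volume oracle", {
  sp <- small_spec()
  ph <- make_phantom(sp)
  expect_false(any(ph$truth_core_mask & !ph$truth_penumbra_mask))
  expect_false(any(ph$truth_core_mask & !ph$brain_mask))

  # brute-force voxel enumeration oracle for the core volume
  g <- sp$grid_shape
  cnt <- 0L
  ctr <- (sp$core_region$center - 0.5) * sp$voxel_size
  ax <- sp$core_region$semi_axes_mm
  for (i in seq_len(g[1])) for (j in seq_len(g[2])) for (k in seq_len(g[3])) {
    pos <- (c(i, j, k) - 0.5) * sp$voxel_size
    if (sum(((pos - ctr) / ax)^2) <= 1) cnt <- cnt + 1L
  }
  expect_equal(ph$manifest$truth_core_ml, cnt * prod(sp$voxel_size) / 1000)
})

test_that("phantom linearity: doubling tissue CBF doubles the noiseless curve", {
  dt <- 1.5
  times <- (0:39) * dt
  ca <- gamma_variate_curve(gamma_variate_params(), times)
  expect_equal(synthesize_tissue_curve(ca, 80, 6, 2, dt),
               2 * synthesize_tissue_curve(ca, 40, 6, 2, dt), tolerance = 1e-12)
})

test_that("phantom geometry errors", {
  expect_error(make_phantom(small_spec(core_region = list(
    center = c(2, 2, 2), semi_axes_mm = c(50, 50, 50), cbf = 10))),
    class = "perf_geometry_error")
  expect_error(small_spec(core_region = list(center = c(12, 16, 4),
    semi_axes_mm = c(10, 10, 8), cbf = 70)), class = "perf_parameter_error")
})

test_that("ADC phantom: thresholds hold by construction; spec errors caught", {
  sp <- small_spec()
  adc <- make_adc_phantom(sp)
  ph <- make_phantom(sp)
  expect_true(all(adc[ph$truth_core_mask] < 620e-6))
  brain_non_core <- ph$brain_mask & !ph$truth_core_mask
  expect_true(all(adc[brain_non_core] >= 620e-6))
  expect_true(all(adc[!ph$brain_mask] == 0))

  expect_error(phantom_spec(adc_core = 700e-6), class = "perf_parameter_error")

  # pipeline round trip: ADC segmentation recovers exactly the truth core
  seg <- segment_core_adc(adc, ph$brain_mask, thresholds(), sp$voxel_size)
  expect_identical(seg, ph$truth_core_mask)
})

test_that("write_phantom produces readable NIfTI volumes and a manifest", {
  dir <- withr::local_tempdir()
  ph <- make_phantom(small_spec())
  write_phantom(ph, dir)
  expect_true(file.exists(file.path(dir, "manifest.json")))
  rt <- read_nifti(file.path(dir, "truth_rcbf.nii.gz"))
  expect_equal(rt$data, ph$truth_maps$rcbf, tolerance = 1e-6)
  man <- jsonlite::read_json(file.path(dir, "manifest.json"), simplifyVector = TRUE)
  expect_equal(man$truth_core_ml, ph$manifest$truth_core_ml)
  back <- read_series(file.path(dir, "series.nii.gz"))
  expect_equal(back$data, ph$series$data, tolerance = 1e-12)
  expect_equal(back$frame_times, ph$series$frame_times)
})
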