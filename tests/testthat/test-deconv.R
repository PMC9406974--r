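test_that("convolution matrix: Toeplitz structure, circulant shifts, delta", {
  dt <- 2
  ca <- c(0, 1, 3, 2, 0.5)
  aif <- aif_from_curve(ca, (0:4) * dt)
  A <- build_convolution_matrix(aif, dt)
  expect_equal(A[, 1], dt * ca)
  expect_true(all(A[upper.tri(A)] == 0))
  expect_equal(A[3:5, 3], dt * ca[1:3])

  C <- build_convolution_matrix(aif, dt, circulant = TRUE)
  expect_equal(dim(C), c(10L, 10L))
  for (j in 2:10)
    expect_equal(C[, j], C[c((10 - j + 2):10, 1:(10 - j + 1)), 1])

  delta <- aif_from_curve(c(1 / dt, 0, 0, 0), (0:3) * dt)
  expect_equal(build_convolution_matrix(delta, dt), diag(4), tolerance = 1e-12)

  irr <- aif_from_curve(ca, c(0, 1, 3, 7, 9))
  expect_error(build_convolution_matrix(irr, 1), class = "perf_parameter_error")
})

test_that("deconvolve: identity under a delta AIF, linearity", {
  dt <- 1
  n <- 16
  times <- (0:(n - 1)) * dt
  delta <- aif_from_curve(c(1 / dt, numeric(n - 1)), times)
  ct <- exp(-(0:(n - 1)) / 4) * 5
  conc <- conc_from_curves(rbind(ct, 2 * ct), times)
  res <- deconvolve(conc, delta, circulant = FALSE)
  expect_equal(res$data[1, 1, 1, ], ct, tolerance = 1e-10)
  expect_equal(res$data[2, 1, 1, ], 2 * res$data[1, 1, 1, ], tolerance = 1e-10)

  res_c <- deconvolve(conc, delta, circulant = TRUE)
  expect_equal(res_c$data[1, 1, 1, 1:n], ct, tolerance = 1e-8)

  zero <- aif_from_curve(numeric(n), times)
  expect_error(deconvolve(conc, zero), class = "perf_deconv_error")
})

test_that("truncated SVD matches an independent eigendecomposition oracle", {
  # oracle: pseudo-inverse from eigen(A^T A): V, sigma^2; U = A V / sigma;
  # truncate at the same threshold; solve r = V S^+ U^T ct
  set.seed(11)
  dt <- 1.2
  n <- 10
  times <- (0:(n - 1)) * dt
  ca <- gamma_variate_curve(gamma_variate_params(amplitude = 5, t0 = 1,
                                                 alpha = 2, beta = 1.5), times)
  ct <- synthesize_tissue_curve(ca, 50, 5, 0, dt) + 0.01 * rnorm(n)
  for (circ in c(FALSE, TRUE)) {
    aif <- aif_from_curve(ca, times)
    A <- build_convolution_matrix(aif, dt, circulant = circ)
    b <- if (circ) c(ct, numeric(n)) else ct
    eg <- eigen(crossprod(A), symmetric = TRUE)
    sig <- sqrt(pmax(eg$values, 0))
    keep <- sig >= 0.10 * sig[1]
    U <- A %*% eg$vectors[, keep] %*% diag(1 / sig[keep], sum(keep))
    r_oracle <- eg$vectors[, keep] %*% diag(1 / sig[keep], sum(keep)) %*%
      (t(U) %*% b)
    conc <- conc_from_curves(ct, times)
    res <- deconvolve(conc, aif, threshold_frac = 0.10, circulant = circ)
    expect_equal(as.vector(res$data[1, 1, 1, ]), as.vector(r_oracle),
                 tolerance = 1e-8)
  }
})

test_that("noiseless recovery: flow within 5%, Tmax at the delay", {
  cst <- scaling_constants()
  dt <- 1.5
  times <- (0:39) * dt
  ca <- gamma_variate_curve(gamma_variate_params(), times)
  aif <- aif_from_curve(ca, times)
  ct <- synthesize_tissue_curve(ca, 60, 4, 0, dt, cst)
  conc <- conc_from_curves(ct, times)
  res <- deconvolve(conc, aif)
  maps <- compute_maps(res, conc, aif, cst)
  expect_lt(abs(maps$rcbf[1, 1, 1] - 60) / 60, 0.05)
  expect_lt(abs(maps$rcbv[1, 1, 1] - 4) / 4, 0.02)
  expect_equal(maps$tmax[1, 1, 1], 0)

  # delay insensitivity in circulant mode: 2*dt delay
  ct_d <- synthesize_tissue_curve(ca, 60, 4, 2 * dt, dt, cst)
  conc_d <- conc_from_curves(ct_d, times)
  res_d <- deconvolve(conc_d, aif)
  maps_d <- compute_maps(res_d, conc_d, aif, cst)
  pk0 <- max(res$data[1, 1, 1, ])
  pkd <- max(res_d$data[1, 1, 1, ])
  expect_lt(abs(pkd - pk0) / pk0, 0.05)
  expect_lte(abs(maps_d$tmax[1, 1, 1] - 2 * dt), dt)
})

test_that("compute_maps implements the printed equations", {
  # hand-evaluated rCBV: equal areas, defaults -> 100*(1/1.04)*(0.75/0.55)
  dt <- 1
  times <- 0:9
  ca <- c(0, 2, 5, 3, 1, 0.5, 0, 0, 0, 0)
  aif <- aif_from_curve(ca, times)
  conc <- conc_from_curves(ca, times)        # ct identical to ca
  res <- deconvolve(conc, aif)
  maps <- compute_maps(res, conc, aif)
  expect_equal(maps$rcbv[1, 1, 1], 100 * (1 / 1.04) * (0.75 / 0.55),
               tolerance = 1e-9)

  # MTT arithmetic: CBV 4 mL/100 g at CBF 60 -> 4 s
  expect_equal(60 * 4 / 60, 4)
  # Tmax: residue peaking at frame k -> k*dt (0-based frames)
  delta <- aif_from_curve(c(1, numeric(9)), times)
  ct <- c(0, 0, 0, 1, 0.5, 0.2, 0, 0, 0, 0)
  conc2 <- conc_from_curves(ct, times)
  res2 <- deconvolve(conc2, delta, circulant = TRUE)
  maps2 <- compute_maps(res2, conc2, delta)
  expect_equal(maps2$tmax[1, 1, 1], 3 * dt)
})

test_that("MTT identity holds on every computed map", {
  ph <- make_phantom(small_spec(noise_sd = 0.3))
  run <- quiet_ctp(ph$series)
  m <- run$maps
  sel <- m$brain_mask & m$rcbf > 0
  dev <- abs(m$mtt[sel] * m$rcbf[sel] - 60 * m$rcbv[sel]) /
    pmax(60 * abs(m$rcbv[sel]), 1e-12)
  expect_lt(max(dev), 1e-6)
  expect_true(all(m$rcbf[m$brain_mask] >= 0))
  expect_true(all(m$rcbv[m$brain_mask] >= 0))
  frames <- m$tmax[m$brain_mask] / m$dt
  expect_true(all(abs(frames - round(frames)) < 1e-9))
})

test_that("non-uniform frame times are resampled before deconvolution", {
  cst <- scaling_constants()
  dt <- 1.5
  times_u <- (0:39) * dt
  ca_par <- gamma_variate_params()
  ca_u <- gamma_variate_curve(ca_par, times_u)
  ct_u <- synthesize_tissue_curve(ca_u, 60, 4, 0, dt, cst)
  # sample the same curves on an uneven grid
  times_n <- sort(c(times_u[1:30], times_u[31:40] + 0.5))
  ca_n <- approx(times_u, ca_u, xout = times_n, rule = 2)$y
  ct_n <- approx(times_u, ct_u, xout = times_n, rule = 2)$y
  conc <- conc_from_curves(ct_n, times_n)
  aif <- aif_from_curve(ca_n, times_n)
  res <- deconvolve(conc, aif)
  maps <- compute_maps(res, conc, aif, cst)
  expect_lt(abs(maps$rcbf[1, 1, 1] - 60) / 60, 0.10)
})

test_that("map writing produces one NIfTI per parameter", {
  dir <- withr::local_tempdir()
  ph <- make_phantom(small_spec(noise_sd = 0))
  run <- quiet_ctp(ph$series)
  write_maps(run$maps, dir)
  for (m in c("rcbf", "rcbv", "mtt", "tmax")) {
    f <- file.path(dir, sprintf("%s.nii.gz", m))
    expect_true(file.exists(f))
    expect_equal(read_nifti(f)$data, run$maps[[m]], tolerance = 1e-12)
  }
})
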