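# Digital perfusion phantom: a head-sized 4D series whose voxel curves
# follow gamma-variate-AIF (x) exponential-residue kinetics, with planted
# core (low CBF, low ADC) and penumbra (delayed Tmax) lesions and known
# ground-truth parameter maps.

#' Gamma-variate parameters for the arterial input function
#'
#' The arterial concentration-time curve is modelled as
#' `A * (t - t0)^alpha * exp(-(t - t0) / beta)` for `t > t0` and 0 before
#' bolus arrival. Its mode is at `t0 + alpha * beta`.
#'
#' @param amplitude concentration scale (> 0, arbitrary linear units).
#' @param t0 bolus arrival time (s).
#' @param alpha shape parameter (> 0).
#' @param beta scale parameter (s, > 0).
#' @export
gamma_variate_params <- function(amplitude = 440, t0 = 6, alpha = 3, beta = 0.8) {
  assert_scalar_num(amplitude, "amplitude", positive = TRUE)
  assert_scalar_num(t0, "t0")
  assert_scalar_num(alpha, "alpha", positive = TRUE)
  assert_scalar_num(beta, "beta", positive = TRUE)
  structure(list(amplitude = amplitude, t0 = t0, alpha = alpha, beta = beta),
            class = "gamma_variate_params")
}

#' Evaluate a gamma-variate curve on a time grid
#'
#' @param params a [gamma_variate_params()] object.
#' @param times strictly increasing time grid (s).
#' @return concentration at each time; 0 for `t <= t0`.
#' @export
gamma_variate_curve <- function(params, times) {
  if (!inherits(params, "gamma_variate_params"))
    params <- do.call(gamma_variate_params, params)
  if (any(diff(times) <= 0))
    stop_parameter("times must be strictly increasing")
  s <- times - params$t0
  out <- numeric(length(times))
  pos <- s > 0
  out[pos] <- params$amplitude * s[pos]^params$alpha * exp(-s[pos] / params$beta)
  out
}

#' Forward-model a tissue concentration curve
#'
#' Discrete convolution (rectangle rule, step `dt`) of the delayed arterial
#' curve with the flow-scaled mono-exponential residue
#' `F * exp(-s / mtt)`, where the flow scale `F` carries the brain density
#' and small/large-vessel hematocrit corrections so that the standard
#' perfusion-map equations recover `cbf` and `cbv = cbf * mtt / 60`
#' exactly (up to discretization).
#'
#' @param aif_curve arterial concentration samples on a uniform grid.
#' @param cbf tissue blood flow (mL/100 g/min, >= 0).
#' @param mtt mean transit time (s, > 0).
#' @param delay bolus delay of the tissue relative to the artery (s, >= 0);
#'   applied as a shift of `round(delay/dt)` frames.
#' @param dt frame interval (s).
#' @param constants a [scaling_constants()] object.
#' @return tissue concentration curve, same length as `aif_curve`.
#' @export
synthesize_tissue_curve <- function(aif_curve, cbf, mtt, delay = 0, dt = 1.0,
                                    constants = scaling_constants()) {
  assert_scalar_num(cbf, "cbf", nonneg = TRUE)
  assert_scalar_num(mtt, "mtt", positive = TRUE)
  assert_scalar_num(delay, "delay", nonneg = TRUE)
  assert_scalar_num(dt, "dt", positive = TRUE)
  n <- length(aif_curve)
  if (n < 2L) stop_dimension("aif_curve must have at least 2 samples")
  if (cbf == 0) return(numeric(n))
  ca <- shift_curve(aif_curve, round(delay / dt))
  fs <- flow_scale(cbf, constants)
  # Rectangle-rule-consistent mono-exponential washout: the discrete
  # solution of dr/ds = -r/mtt with step dt. Peak = fs and
  # sum(r) * dt = fs * mtt hold exactly, so the discrete central-volume
  # identity is exact (continuum-sampled exp(-s/mtt) would bias the
  # rectangle-rule area by up to dt/(2*mtt)).
  q <- max(0, 1 - dt / mtt)
  r <- fs * q^(seq_len(n) - 1)
  ct <- convolve(ca, rev(r), type = "open")[seq_len(n)] * dt
  ct
}

# Flow scale of the residue (1/s): includes density and hematocrit
# corrections, the inverse of the map-equation scaling in compute_maps().
flow_scale <- function(cbf, constants) {
  kH <- (1 - constants$h_sv) / (1 - constants$h_lv)
  cbf * constants$rho / (100 * 60 * constants$k_av * kH)
}

shift_curve <- function(x, k) {
  n <- length(x)
  if (k == 0) return(x)
  if (k >= n) return(numeric(n))
  c(numeric(k), x[seq_len(n - k)])
}

#' Specify a digital perfusion phantom
#'
#' Defaults describe a head-sized CT-perfusion acquisition: a
#' 64 x 64 x 16 grid of 3 x 3 x 6 mm voxels, 40 frames at 1.5 s, an
#' ellipsoidal "brain" with normal flow 60 mL/100 g/min and MTT 4 s, a
#' ~30 mL ischemic core (CBF 10 mL/100 g/min, ADC 450e-6 mm^2/s) nested
#' inside a ~90 mL hypoperfused region with an 8 s bolus delay, a 5-voxel
#' arterial plug carrying the pure AIF, and additive Gaussian noise of
#' 1 signal unit.
#'
#' @param grid_shape voxels per axis (x, y, z).
#' @param voxel_size mm per axis.
#' @param n_frames number of time frames.
#' @param dt frame interval (s).
#' @param aif [gamma_variate_params()] for the arterial curve.
#' @param tissue_cbf_normal,tissue_mtt_normal normal-tissue CBF
#'   (mL/100 g/min) and MTT (s).
#' @param core_region list(center, semi_axes_mm, cbf): ellipsoid centre in
#'   1-based voxel coordinates, semi-axes in mm, and core CBF.
#' @param penumbra_region list(center, semi_axes_mm, delay_s): hypoperfused
#'   ellipsoid (must contain the core) and its bolus delay in seconds.
#' @param adc_normal,adc_core ADC values (mm^2/s); `adc_core` must be
#'   below the 620e-6 core threshold and `adc_normal` at or above it.
#' @param noise_sd additive Gaussian noise SD in signal units.
#' @param adc_noise_sd optional noise SD for the ADC phantom (mm^2/s).
#' @param modality `"CTP"` or `"DSC-MRI"`.
#' @param echo_time echo time TE (s), used only for DSC-MRI.
#' @param seed integer RNG seed; equal specs (incl. seed) give
#'   bit-identical phantoms.
#' @param constants [scaling_constants()] used by the forward model.
#' @export
phantom_spec <- function(grid_shape = c(64L, 64L, 16L),
                         voxel_size = c(3, 3, 6),
                         n_frames = 40L,
                         dt = 1.5,
                         aif = NULL,
                         tissue_cbf_normal = 60,
                         tissue_mtt_normal = 4,
                         core_region = list(center = c(22, 32, 8),
                                            semi_axes_mm = c(24, 20, 15),
                                            cbf = 10),
                         penumbra_region = list(center = c(22, 32, 8),
                                                semi_axes_mm = c(35, 30, 20.5),
                                                delay_s = 8),
                         adc_normal = 800e-6,
                         adc_core = 450e-6,
                         noise_sd = 1,
                         adc_noise_sd = 0,
                         modality = c("CTP", "DSC-MRI"),
                         echo_time = 0.032,
                         seed = 42L,
                         constants = scaling_constants()) {
  modality <- match.arg(modality)
  if (is.null(aif)) {
    # arterial peak ~300 HU (CTP, iodine) or ~60 1/s Delta-R2* (DSC-MRI)
    aif <- if (modality == "CTP") gamma_variate_params(amplitude = 440)
           else gamma_variate_params(amplitude = 90)
  }
  assert_scalar_num(dt, "dt", positive = TRUE)
  assert_scalar_num(noise_sd, "noise_sd", nonneg = TRUE)
  assert_scalar_num(adc_noise_sd, "adc_noise_sd", nonneg = TRUE)
  assert_scalar_num(tissue_cbf_normal, "tissue_cbf_normal", positive = TRUE)
  assert_scalar_num(tissue_mtt_normal, "tissue_mtt_normal", positive = TRUE)
  if (length(grid_shape) != 3L || any(grid_shape < 8))
    stop_parameter("grid_shape must be 3 axis sizes, each >= 8")
  if (length(voxel_size) != 3L || any(voxel_size <= 0))
    stop_parameter("voxel_size must be 3 positive spacings (mm)")
  if (!is.null(core_region)) {
    if (core_region$cbf >= tissue_cbf_normal)
      stop_parameter("core CBF must be below normal tissue CBF")
    if (adc_core >= 620e-6)
      stop_parameter("adc_core must be < 620e-6 mm^2/s")
    if (adc_normal < 620e-6)
      stop_parameter("adc_normal must be >= 620e-6 mm^2/s")
  }
  spec <- list(grid_shape = as.integer(grid_shape), voxel_size = voxel_size,
               n_frames = as.integer(n_frames), dt = dt, aif = aif,
               tissue_cbf_normal = tissue_cbf_normal,
               tissue_mtt_normal = tissue_mtt_normal,
               core_region = core_region, penumbra_region = penumbra_region,
               adc_normal = adc_normal, adc_core = adc_core,
               noise_sd = noise_sd, adc_noise_sd = adc_noise_sd,
               modality = modality, echo_time = echo_time,
               seed = as.integer(seed), constants = constants)
  class(spec) <- "phantom_spec"
  spec
}

# Brain ellipsoid: 90% of the half field of view per axis, grid-centred.
phantom_brain_mask <- function(spec) {
  fov <- spec$grid_shape * spec$voxel_size
  ellipsoid_mask(spec$grid_shape, spec$voxel_size,
                 center_vox = (spec$grid_shape + 1) / 2,
                 semi_axes_mm = 0.45 * fov)
}

check_region_in_grid <- function(region, spec, name) {
  if (is.null(region)) return(invisible(NULL))
  fov <- spec$grid_shape * spec$voxel_size
  cmm <- (region$center - 0.5) * spec$voxel_size
  lo <- cmm - region$semi_axes_mm
  hi <- cmm + region$semi_axes_mm
  if (any(lo < 0) || any(hi > fov))
    stop_geometry(sprintf("%s ellipsoid extends outside the grid", name))
  invisible(NULL)
}

# Fixed 5-voxel arterial plug (a + shape in the x-y plane) placed
# anteriorly inside the brain, recorded in the manifest.
phantom_aif_voxels <- function(spec) {
  g <- spec$grid_shape
  c0 <- c(round(g[1] / 2), round(g[2] * 0.22), round(g[3] / 2))
  offs <- rbind(c(0, 0, 0), c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0))
  sweep(offs, 2, c0, `+`)
}

#' Generate a phantom 4D perfusion dataset with ground truth
#'
#' Every brain voxel carries a forward-modelled tissue curve for its
#' region's (CBF, MTT, delay); a 5-voxel arterial plug carries the pure
#' AIF. Concentration is mapped to signal (CTP: baseline 40 HU plus
#' concentration; DSC-MRI: `100 * exp(-TE * c)`), then Gaussian noise of
#' `noise_sd` is added. Ground-truth maps hold the generating parameters.
#'
#' @param spec a [phantom_spec()].
#' @return a `phantom_dataset`: `series` ([perfusion_series()]),
#'   `truth_maps`, `truth_core_mask`, `truth_penumbra_mask`, `truth_adc`,
#'   `brain_mask`, `manifest`.
#' @export
make_phantom <- function(spec = phantom_spec()) {
  stopifnot(inherits(spec, "phantom_spec"))
  check_region_in_grid(spec$core_region, spec, "core")
  check_region_in_grid(spec$penumbra_region, spec, "penumbra")
  g <- spec$grid_shape
  times <- (seq_len(spec$n_frames) - 1) * spec$dt
  brain <- phantom_brain_mask(spec)

  core <- pen <- array(FALSE, g)
  if (!is.null(spec$core_region))
    core <- ellipsoid_mask(g, spec$voxel_size, spec$core_region$center,
                           spec$core_region$semi_axes_mm) & brain
  if (!is.null(spec$penumbra_region))
    pen <- ellipsoid_mask(g, spec$voxel_size, spec$penumbra_region$center,
                          spec$penumbra_region$semi_axes_mm) & brain
  if (any(core & !pen))
    stop_geometry("core region must be contained in the penumbra region")

  delay_pen <- if (is.null(spec$penumbra_region)) 0 else spec$penumbra_region$delay_s
  cbf_core <- if (is.null(spec$core_region)) spec$tissue_cbf_normal else spec$core_region$cbf

  aif_curve <- gamma_variate_curve(spec$aif, times)
  curve_normal <- synthesize_tissue_curve(aif_curve, spec$tissue_cbf_normal,
    spec$tissue_mtt_normal, 0, spec$dt, spec$constants)
  curve_pen <- synthesize_tissue_curve(aif_curve, spec$tissue_cbf_normal,
    spec$tissue_mtt_normal, delay_pen, spec$dt, spec$constants)
  curve_core <- synthesize_tissue_curve(aif_curve, cbf_core,
    spec$tissue_mtt_normal, delay_pen, spec$dt, spec$constants)

  nvox <- prod(g)
  conc <- matrix(0, nvox, spec$n_frames)
  i_norm <- which(brain & !pen)
  i_pen <- which(pen & !core)
  i_core <- which(core)
  fill <- function(idx, curve) {
    if (length(idx))
      conc[idx, ] <<- matrix(curve, length(idx), spec$n_frames, byrow = TRUE)
  }
  fill(i_norm, curve_normal)
  fill(i_pen, curve_pen)
  fill(i_core, curve_core)

  aif_vox <- phantom_aif_voxels(spec)
  aif_lin <- aif_vox[, 1] + (aif_vox[, 2] - 1) * g[1] + (aif_vox[, 3] - 1) * g[1] * g[2]
  if (any(!brain[aif_lin]))
    stop_geometry("arterial plug falls outside the brain ellipsoid")
  conc[aif_lin, ] <- matrix(aif_curve, length(aif_lin), spec$n_frames, byrow = TRUE)

  # concentration -> signal
  if (spec$modality == "CTP") {
    signal <- conc
    signal[brain, ] <- signal[brain, ] + 40
  } else {
    signal <- matrix(0, nvox, spec$n_frames)
    signal[brain, ] <- 100 * exp(-spec$echo_time * conc[brain, ])
  }
  if (spec$noise_sd > 0) {
    signal <- signal + with_phantom_seed(spec$seed, {
      matrix(stats::rnorm(nvox * spec$n_frames, 0, spec$noise_sd),
             nvox, spec$n_frames)
    })
  }

  series <- perfusion_series(array(signal, c(g, spec$n_frames)),
                             voxel_size = spec$voxel_size,
                             frame_times = times, modality = spec$modality,
                             echo_time = if (spec$modality == "DSC-MRI") spec$echo_time)

  truth <- phantom_truth_maps(spec, brain, core, pen)
  vox_ml <- prod(spec$voxel_size) / 1000
  manifest <- list(spec = spec, aif_voxels = aif_vox,
                   truth_core_ml = sum(core) * vox_ml,
                   truth_penumbra_ml = sum(pen & !core) * vox_ml,
                   truth_hypoperfused_ml = sum(pen) * vox_ml)
  structure(list(series = series, truth_maps = truth,
                 truth_core_mask = core, truth_penumbra_mask = pen,
                 truth_adc = make_adc_phantom(spec),
                 brain_mask = brain, manifest = manifest),
            class = "phantom_dataset")
}

phantom_truth_maps <- function(spec, brain, core, pen) {
  g <- spec$grid_shape
  rcbf <- array(0, g); mtt <- array(0, g); tmax <- array(0, g)
  rcbf[brain] <- spec$tissue_cbf_normal
  if (!is.null(spec$core_region)) rcbf[core] <- spec$core_region$cbf
  mtt[brain] <- spec$tissue_mtt_normal
  if (!is.null(spec$penumbra_region)) tmax[pen] <- spec$penumbra_region$delay_s
  rcbv <- rcbf * mtt / 60
  structure(list(rcbf = rcbf, rcbv = rcbv, mtt = mtt, tmax = tmax,
                 brain_mask = brain, voxel_size = spec$voxel_size,
                 dt = spec$dt),
            class = "perfusion_maps")
}

# Run expr with a private, restored RNG stream derived from seed.
with_phantom_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Generate the matching ADC phantom volume
#'
#' Core voxels take `adc_core`, other brain voxels `adc_normal`,
#' background 0; optional seeded Gaussian noise (`adc_noise_sd`).
#'
#' @param spec a [phantom_spec()] with the ADC fields set.
#' @return 3D array of ADC values (mm^2/s).
#' @export
make_adc_phantom <- function(spec = phantom_spec()) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (!is.null(spec$core_region) && spec$adc_core >= 620e-6)
    stop_parameter("adc_core must be < 620e-6 mm^2/s")
  g <- spec$grid_shape
  brain <- phantom_brain_mask(spec)
  adc <- array(0, g)
  adc[brain] <- spec$adc_normal
  if (!is.null(spec$core_region)) {
    core <- ellipsoid_mask(g, spec$voxel_size, spec$core_region$center,
                           spec$core_region$semi_axes_mm) & brain
    adc[core] <- spec$adc_core
  }
  if (spec$adc_noise_sd > 0) {
    noise <- with_phantom_seed(spec$seed + 1L, {
      array(stats::rnorm(prod(g), 0, spec$adc_noise_sd), g)
    })
    adc[brain] <- adc[brain] + noise[brain]
  }
  adc
}

#' Write a phantom dataset to disk
#'
#' Writes the 4D series, ground-truth maps, truth masks and ADC volume as
#' NIfTI plus a JSON manifest (spec echo, seed, arterial-plug location,
#' ground-truth volumes in mL) and the timing sidecar for [read_series()].
#'
#' @param phantom a [make_phantom()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_phantom <- function(phantom, dir) {
  stopifnot(inherits(phantom, "phantom_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sp <- phantom$manifest$spec
  write_series(phantom$series, file.path(dir, "series.nii.gz"))
  write_nifti(phantom$truth_adc, file.path(dir, "truth_adc.nii.gz"),
              sp$voxel_size, datatype = "float64")
  write_nifti(phantom$truth_core_mask, file.path(dir, "truth_core_mask.nii.gz"),
              sp$voxel_size)
  write_nifti(phantom$truth_penumbra_mask,
              file.path(dir, "truth_penumbra_mask.nii.gz"), sp$voxel_size)
  write_nifti(phantom$brain_mask, file.path(dir, "brain_mask.nii.gz"),
              sp$voxel_size)
  for (m in c("rcbf", "rcbv", "mtt", "tmax"))
    write_nifti(phantom$truth_maps[[m]],
                file.path(dir, sprintf("truth_%s.nii.gz", m)), sp$voxel_size)
  manifest <- phantom$manifest
  manifest$spec$constants <- unclass(manifest$spec$constants)
  manifest$spec$aif <- unclass(manifest$spec$aif)
  manifest$spec <- unclass(manifest$spec)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
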