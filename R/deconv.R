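# Truncated-SVD deconvolution of tissue curves by the AIF and computation
# of the four perfusion parameter maps (rCBF, rCBV, MTT, Tmax).

#' Scaling constants for the perfusion-map equations
#'
#' @param k_av dimensionless calibration factor (> 0).
#' @param rho brain tissue density (g/mL, > 0).
#' @param h_sv,h_lv small-vessel and large-vessel hematocrit fractions
#'   (each in \[0, 1)). The ratio `(1 - h_sv) / (1 - h_lv)` converts
#'   large-vessel (arterial) to small-vessel plasma concentration scale.
#' @export
scaling_constants <- function(k_av = 1.0, rho = 1.04, h_sv = 0.25, h_lv = 0.45) {
  assert_scalar_num(k_av, "k_av", positive = TRUE)
  assert_scalar_num(rho, "rho", positive = TRUE)
  assert_scalar_num(h_sv, "h_sv", nonneg = TRUE)
  assert_scalar_num(h_lv, "h_lv", nonneg = TRUE)
  if (h_sv >= 1 || h_lv >= 1)
    stop_parameter("hematocrit fractions must be < 1")
  structure(list(k_av = k_av, rho = rho, h_sv = h_sv, h_lv = h_lv),
            class = "scaling_constants")
}

#' Build the discrete convolution matrix from an AIF
#'
#' Standard mode: the N x N lower-triangular Toeplitz matrix with first
#' column `dt * ca`. Circulant mode: the 2N x 2N block-circulant matrix
#' from the zero-padded AIF, which makes the deconvolution insensitive to
#' bolus delay (the residue of delayed tissue wraps instead of being
#' clipped).
#'
#' @param aif an `aif` object or a list with `times` and `concentration`.
#' @param dt uniform sampling step (s); the AIF must already be sampled
#'   at this step (see [resample_uniform()]).
#' @param circulant logical.
#' @return the convolution matrix.
#' @export
build_convolution_matrix <- function(aif, dt, circulant = FALSE) {
  ca <- aif$concentration
  tms <- aif$times
  if (length(tms) > 1L) {
    steps <- diff(tms)
    if (max(abs(steps - dt)) > 1e-6 * dt)
      stop_parameter("AIF is not sampled uniformly at dt; resample first")
  }
  n <- length(ca)
  if (circulant) {
    L <- 2L * n
    cap <- c(ca, numeric(n))
    idx <- outer(seq_len(L), seq_len(L), function(i, j) ((i - j) %% L) + 1L)
    matrix(dt * cap[idx], L, L)
  } else {
    idx <- outer(seq_len(n), seq_len(n), `-`) + 1L
    A <- matrix(0, n, n)
    pos <- idx >= 1L
    A[pos] <- dt * ca[idx[pos]]
    A
  }
}

#' Resample a concentration series and AIF to a uniform grid
#'
#' Linear interpolation to step `dt = min(diff(frame_times))`. A no-op
#' for already-uniform timing.
#' @param times frame times (s).
#' @param mat matrix of curves (rows = voxels).
#' @return list(times, mat)
#' @keywords internal
resample_uniform <- function(times, mat) {
  steps <- diff(times)
  if (max(steps) - min(steps) < 1e-9 * max(steps))
    return(list(times = times, mat = mat))
  dt <- min(steps)
  new_t <- seq(times[1], times[length(times)], by = dt)
  out <- t(apply(mat, 1, function(y)
    stats::approx(times, y, xout = new_t, rule = 2)$y))
  list(times = new_t, mat = out)
}

#' Deconvolve tissue curves by the AIF (truncated SVD)
#'
#' Solves `A r = ct` per voxel, keeping singular values at or above
#' `threshold_frac` of the largest. In circulant mode (default) both the
#' matrix and the tissue curves are zero-padded to length 2N, making the
#' recovered residue insensitive to bolus delay.
#'
#' @param conc a [to_concentration()] result.
#' @param aif a [detect_aif()] result.
#' @param threshold_frac singular-value cutoff as a fraction of the
#'   largest (0 < frac <= 1; default 0.10).
#' @param circulant logical (default TRUE).
#' @return a `residue_map`: `data` (4D flow-scaled residue, 1/s), `dt`,
#'   `n_frames` (original frame count), `circulant`, `brain_mask`.
#' @export
deconvolve <- function(conc, aif, threshold_frac = 0.10, circulant = TRUE) {
  stopifnot(inherits(conc, "concentration_series"))
  if (threshold_frac <= 0 || threshold_frac > 1)
    stop_parameter("threshold_frac must be in (0, 1]")
  dm <- dim(conc$data)
  bm <- as.vector(conc$brain_mask)
  ctm <- matrix(conc$data, prod(dm[1:3]), dm[4])[bm, , drop = FALSE]

  rs_t <- resample_uniform(conc$frame_times, rbind(aif$concentration, ctm))
  ca <- rs_t$mat[1, ]
  ctm <- rs_t$mat[-1, , drop = FALSE]
  times <- rs_t$times
  dt <- if (length(times) > 1) times[2] - times[1] else stop_dimension("need >= 2 frames")
  n <- length(ca)
  if (sum(ca) * dt <= 0) stop_deconv("AIF integral is zero")

  tsvd_inverse <- function(A) {
    sv <- svd(A)
    dinv <- ifelse(sv$d >= threshold_frac * sv$d[1], 1 / sv$d, 0)
    sv$v %*% (dinv * t(sv$u))
  }
  A <- build_convolution_matrix(list(times = times, concentration = ca),
                                dt, circulant = circulant)
  rhs <- t(ctm)
  if (circulant) rhs <- rbind(rhs, matrix(0, n, ncol(rhs)))
  R <- tsvd_inverse(A) %*% rhs            # L x nvox_brain

  L <- nrow(R)
  out <- matrix(0, prod(dm[1:3]), L)
  out[bm, ] <- t(R)

  # The circulant solution smears the residue discontinuity at s = 0 and
  # underestimates its peak; solve the standard Toeplitz system as well
  # and keep it for the flow estimate (Tmax stays with the
  # delay-insensitive circulant residue).
  data_standard <- NULL
  if (circulant) {
    As <- build_convolution_matrix(list(times = times, concentration = ca),
                                   dt, circulant = FALSE)
    Rs <- tsvd_inverse(As) %*% t(ctm)
    outs <- matrix(0, prod(dm[1:3]), n)
    outs[bm, ] <- t(Rs)
    data_standard <- array(outs, c(dm[1:3], n))
  }
  structure(list(data = array(out, c(dm[1:3], L)), dt = dt, n_frames = n,
                 circulant = circulant, data_standard = data_standard,
                 brain_mask = conc$brain_mask,
                 voxel_size = conc$voxel_size),
            class = "residue_map")
}

#' Compute the four perfusion parameter maps
#'
#' Implements the standard deconvolution map equations:
#' * `rCBV = 100 (kAV/rho) ((1-HSV)/(1-HLV)) * int(ct) / int(ca)` (mL/100 g)
#' * `rCBF = 100 * 60 (kAV/rho) ((1-HSV)/(1-HLV)) * max(r)` (mL/100 g/min)
#' * `MTT = 60 CBV / CBF` (s; 0 where CBF = 0)
#' * `Tmax = argmax(r) * dt` (s)
#'
#' Integrals use the rectangle rule with step `dt`. The hematocrit
#' correction is applied to both CBV and CBF (it rescales the arterial
#' concentration axis, which enters both); with `h_sv == h_lv` the rCBF
#' equation reduces to the uncorrected `100 * 60 (kAV/rho) max(r)` form.
#'
#' @param residue a [deconvolve()] result.
#' @param conc the matching [to_concentration()] result.
#' @param aif the [detect_aif()] result used for deconvolution.
#' @param constants a [scaling_constants()] object.
#' @return a `perfusion_maps` object: 3D `rcbf`, `rcbv`, `mtt`, `tmax`,
#'   plus `brain_mask`, `voxel_size`, `dt`.
#' @export
compute_maps <- function(residue, conc, aif, constants = scaling_constants()) {
  stopifnot(inherits(residue, "residue_map"),
            inherits(conc, "concentration_series"))
  dm3 <- dim(conc$data)[1:3]
  if (!all(dim(residue$data)[1:3] == dm3))
    stop_dimension("residue and concentration grids differ")
  bm <- as.vector(residue$brain_mask)
  L <- dim(residue$data)[4]
  rm_ <- matrix(residue$data, prod(dm3), L)[bm, , drop = FALSE]
  if (any(!is.finite(rm_))) {
    bad <- which(!is.finite(rowSums(rm_)))
    stop_map(sprintf("non-finite residue inside brain mask at %d voxels (e.g. brain voxel #%d)",
                     length(bad), bad[1]))
  }
  n <- residue$n_frames
  dt <- residue$dt
  kH <- (1 - constants$h_sv) / (1 - constants$h_lv)
  scale_flow <- 100 * 60 * (constants$k_av / constants$rho) * kH
  scale_vol <- 100 * (constants$k_av / constants$rho) * kH

  # Tmax search window: the first n frames (acquisition window); in
  # circulant mode the padded half holds wrap-around, not physical delay.
  rsub <- rm_[, seq_len(n), drop = FALSE]
  pk_idx <- max.col(rsub, ties.method = "first")
  # Flow peak: prefer the standard-Toeplitz residue (no discontinuity
  # smearing); Tmax keeps the delay-insensitive circulant argmax.
  if (!is.null(residue$data_standard)) {
    rstd <- matrix(residue$data_standard, prod(dm3), n)[bm, , drop = FALSE]
    pk <- apply(rstd, 1, max)
  } else {
    pk <- rsub[cbind(seq_len(nrow(rsub)), pk_idx)]
  }
  pk <- pmax(pk, 0)

  ctm <- matrix(conc$data, prod(dm3), dim(conc$data)[4])[bm, , drop = FALSE]
  # areas on the original grid (rectangle rule)
  dts <- diff(conc$frame_times)
  w <- c(dts, dts[length(dts)])
  area_ct <- as.vector(ctm %*% w)
  area_ca <- sum(aif$concentration * c(diff(aif$times),
                                       diff(aif$times)[length(aif$times) - 1]))
  if (area_ca <= 0) stop_deconv("AIF integral is zero")

  rcbf_v <- scale_flow * pk
  rcbv_v <- pmax(scale_vol * area_ct / area_ca, 0)
  mtt_v <- ifelse(rcbf_v > 0, 60 * rcbv_v / rcbf_v, 0)
  tmax_v <- (pk_idx - 1) * dt

  mk <- function(v) {
    a <- array(0, dm3)
    a[bm] <- v
    a
  }
  structure(list(rcbf = mk(rcbf_v), rcbv = mk(rcbv_v), mtt = mk(mtt_v),
                 tmax = mk(tmax_v), brain_mask = residue$brain_mask,
                 voxel_size = conc$voxel_size, dt = dt),
            class = "perfusion_maps")
}

#' Write perfusion maps as one NIfTI per parameter
#'
#' @param maps a [compute_maps()] result.
#' @param dir output directory; writes `rcbf.nii.gz`, `rcbv.nii.gz`,
#'   `mtt.nii.gz`, `tmax.nii.gz`.
#' @export
write_maps <- function(maps, dir) {
  stopifnot(inherits(maps, "perfusion_maps"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (m in c("rcbf", "rcbv", "mtt", "tmax"))
    write_nifti(maps[[m]], file.path(dir, sprintf("%s.nii.gz", m)),
                maps$voxel_size, datatype = "float64")
  invisible(dir)
}
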