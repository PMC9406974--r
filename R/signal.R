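# Preprocessing of raw 4D perfusion series: brain masking, rigid
# (translation) motion correction, Gaussian smoothing and conversion of
# signal to contrast-agent concentration.

#' Construct a 4D perfusion series
#'
#' @param data 4D array (x, y, z, t) of signal units (HU for CTP,
#'   arbitrary MR units for DSC-MRI).
#' @param voxel_size mm per axis (length 3).
#' @param frame_times strictly increasing frame times (s), frame 1 at t = 0
#'   by convention.
#' @param modality `"CTP"` or `"DSC-MRI"`.
#' @param echo_time echo time TE (s); required for DSC-MRI.
#' @export
perfusion_series <- function(data, voxel_size, frame_times,
                             modality = c("CTP", "DSC-MRI"),
                             echo_time = NULL) {
  modality <- match.arg(modality)
  if (length(dim(data)) != 4L)
    stop_format(sprintf("perfusion series must be 4D (x,y,z,t); got %dD",
                        length(dim(data))))
  if (length(voxel_size) != 3L || any(voxel_size <= 0))
    stop_format("voxel_size must be 3 positive spacings (mm)")
  if (length(frame_times) != dim(data)[4])
    stop_format(sprintf("frame_times length (%d) != frame count (%d)",
                        length(frame_times), dim(data)[4]))
  if (any(diff(frame_times) <= 0))
    stop_format("frame_times must be strictly increasing")
  if (modality == "DSC-MRI") {
    if (is.null(echo_time) || !is.numeric(echo_time) || echo_time <= 0)
      stop_format("echo_time (> 0, seconds) is required for DSC-MRI")
  }
  structure(list(data = data, voxel_size = as.numeric(voxel_size),
                 frame_times = as.numeric(frame_times), modality = modality,
                 echo_time = echo_time),
            class = "perfusion_series")
}

#' @export
print.perfusion_series <- function(x, ...) {
  dm <- dim(x$data)
  cat(sprintf("<perfusion_series> %s  %dx%dx%d voxels x %d frames\n",
              x$modality, dm[1], dm[2], dm[3], dm[4]))
  cat(sprintf("  voxel %.3g x %.3g x %.3g mm, t = %.3g..%.3g s\n",
              x$voxel_size[1], x$voxel_size[2], x$voxel_size[3],
              min(x$frame_times), max(x$frame_times)))
  invisible(x)
}

#' Compute a brain mask from the time-mean volume
#'
#' Thresholds the temporal mean with a modality-specific intensity window
#' (CTP: soft-tissue window 20-80 HU; DSC-MRI: above 20% of the maximum
#' mean signal), keeps the largest 6-connected component and fills
#' interior holes. Deterministic.
#'
#' @param series a [perfusion_series()].
#' @return logical 3D array.
#' @export
compute_brain_mask <- function(series) {
  stopifnot(inherits(series, "perfusion_series"))
  mu <- apply(series$data, 1:3, mean)
  raw <- if (series$modality == "CTP") {
    mu > 20 & mu < 80
  } else {
    mu > 0.2 * max(mu)
  }
  if (!any(raw)) stop_masking("brain mask is empty (no voxels in intensity window)")
  fill_holes(largest_component(raw, 6L))
}

#' Rigid (translation-only) motion correction
#'
#' Aligns every frame to frame 1 by cross-correlation: the integer shift
#' maximizing the FFT cross-correlation is refined to subvoxel precision
#' by a parabolic fit, then applied by trilinear interpolation. Frame
#' times are never resampled.
#'
#' @param series a [perfusion_series()] with at least 2 frames.
#' @return a [perfusion_series()]; attribute `"shifts"` holds the applied
#'   per-frame translations (voxels).
#' @export
motion_correct <- function(series) {
  stopifnot(inherits(series, "perfusion_series"))
  dm <- dim(series$data)
  if (dm[4] < 2L) stop_dimension("motion correction needs >= 2 frames")
  ref <- series$data[, , , 1]
  if (stats::sd(ref) == 0) {
    warning("reference frame is constant; returning series unchanged")
    return(series)
  }
  out <- series$data
  shifts <- matrix(0, dm[4], 3)
  fr <- stats::fft(ref)
  for (t in 2:dm[4]) {
    frame <- series$data[, , , t]
    if (stats::sd(frame) == 0) next
    sh <- estimate_shift_3d(fr, frame)
    if (all(abs(sh) < 0.01)) next
    out[, , , t] <- shift_volume(frame, -sh)
    shifts[t, ] <- -sh
  }
  res <- series
  res$data <- out
  attr(res, "shifts") <- shifts
  res
}

# Displacement d such that frame(x) ~ ref(x - d); fft_ref = fft(ref).
estimate_shift_3d <- function(fft_ref, frame) {
  dm <- dim(frame)
  cc <- Re(stats::fft(stats::fft(frame) * Conj(fft_ref), inverse = TRUE))
  pk <- arrayInd(which.max(cc), dm)
  sh <- numeric(3)
  for (ax in 1:3) {
    i <- pk[ax]
    # wrapped neighbours for parabolic refinement
    im <- ((i - 2) %% dm[ax]) + 1L
    ip <- (i %% dm[ax]) + 1L
    idx <- function(j) {
      co <- pk; co[ax] <- j
      cc[co[1], co[2], co[3]]
    }
    y0 <- idx(im); y1 <- idx(i); y2 <- idx(ip)
    denom <- y0 - 2 * y1 + y2
    frac <- if (abs(denom) > .Machine$double.eps * max(abs(c(y0, y1, y2))))
      0.5 * (y0 - y2) / denom else 0
    frac <- max(min(frac, 0.5), -0.5)
    s <- (i - 1) + frac
    if (s > dm[ax] / 2) s <- s - dm[ax]
    sh[ax] <- s
  }
  sh
}

# Translate a 3D volume by a (possibly fractional) voxel shift with
# trilinear interpolation and zero fill.
shift_volume <- function(vol, shift) {
  out <- vol
  for (ax in 1:3) {
    s <- shift[ax]
    if (abs(s) < 1e-12) next
    out <- shift_axis(out, ax, s)
  }
  out
}

shift_axis <- function(vol, ax, s) {
  n <- dim(vol)[ax]
  i0 <- floor(s)
  f <- s - i0
  src_a <- seq_len(n) - i0       # integer part
  src_b <- src_a - 1
  take <- function(idx) {
    ok <- idx >= 1 & idx <= n
    idx[!ok] <- 1L
    sl <- switch(ax,
                 vol[idx, , , drop = FALSE],
                 vol[, idx, , drop = FALSE],
                 vol[, , idx, drop = FALSE])
    if (any(!ok)) {
      zero <- switch(ax,
                     sl[!ok, , ] <- 0,
                     sl[, !ok, ] <- 0,
                     sl[, , !ok] <- 0)
    }
    sl
  }
  if (f < 1e-12) take(src_a) else (1 - f) * take(src_a) + f * take(src_b)
}

#' Per-frame Gaussian spatial smoothing
#'
#' Kernel sigma is `fwhm_mm / (2 * sqrt(2 * log(2)))` converted to voxels
#' per axis; `fwhm_mm = 0` is the identity.
#'
#' @param series a [perfusion_series()].
#' @param fwhm_mm full width at half maximum of the kernel (mm, >= 0).
#' @return a smoothed [perfusion_series()].
#' @export
smooth_series <- function(series, fwhm_mm) {
  stopifnot(inherits(series, "perfusion_series"))
  assert_scalar_num(fwhm_mm, "fwhm_mm", nonneg = TRUE)
  if (fwhm_mm == 0) return(series)
  sigma_vox <- fwhm_mm / (2 * sqrt(2 * log(2))) / series$voxel_size
  out <- series$data
  for (t in seq_len(dim(out)[4]))
    out[, , , t] <- gauss_smooth_3d(out[, , , t], sigma_vox)
  series$data <- out
  series
}

gauss_kernel <- function(sigma) {
  r <- max(1L, ceiling(3 * sigma))
  x <- (-r):r
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

# Separable Gaussian filter implemented as banded-matrix products.
gauss_smooth_3d <- function(vol, sigma_vox) {
  dm <- dim(vol)
  for (ax in 1:3) {
    s <- sigma_vox[ax]
    if (s < 1e-8) next
    k <- gauss_kernel(s)
    r <- (length(k) - 1L) / 2L
    n <- dm[ax]
    K <- matrix(0, n, n)
    for (j in seq_len(n)) {
      rows <- (j - r):(j + r)
      ok <- rows >= 1 & rows <= n
      K[rows[ok], j] <- K[rows[ok], j] + k[ok]
    }
    vol <- switch(ax,
      array(K %*% matrix(vol, dm[1]), dm),
      aperm(array(K %*% matrix(aperm(vol, c(2, 1, 3)), dm[2]),
                  dm[c(2, 1, 3)]), c(2, 1, 3)),
      aperm(array(K %*% matrix(aperm(vol, c(3, 1, 2)), dm[3]),
                  dm[c(3, 1, 2)]), c(2, 3, 1)))
  }
  vol
}

#' Convert a signal series to contrast-agent concentration
#'
#' The pre-bolus baseline window is auto-detected from the mean brain
#' signal: starting from 3 frames, the window grows until a frame deviates
#' from the running baseline mean by more than 3 baseline SDs. CTP
#' concentration is baseline-subtracted signal; DSC-MRI uses
#' `-log(s / s0) / TE`. Negative and non-finite concentrations are set to
#' 0 (count recorded in field `n_clipped`); voxels outside the mask are 0.
#'
#' @param series a [perfusion_series()].
#' @param brain_mask logical 3D array (see [compute_brain_mask()]).
#' @param baseline_window optional explicit frame-index range overriding
#'   auto-detection.
#' @return a `concentration_series`: `data` (4D), `baseline_window`,
#'   `brain_mask`, `frame_times`, `voxel_size`, `n_clipped`.
#' @export
to_concentration <- function(series, brain_mask, baseline_window = NULL) {
  stopifnot(inherits(series, "perfusion_series"))
  if (!any(brain_mask)) stop_masking("brain mask is empty")
  dm <- dim(series$data)
  n <- dm[4]
  sig <- matrix(series$data, prod(dm[1:3]), n)
  bm <- as.vector(brain_mask)
  if (is.null(baseline_window)) {
    m <- colMeans(sig[bm, , drop = FALSE])
    baseline_window <- detect_baseline(m)
  } else {
    baseline_window <- as.integer(baseline_window)
    if (length(baseline_window) < 1L || any(baseline_window < 1L | baseline_window > n))
      stop_parameter("baseline_window indices out of range")
  }
  b0 <- rowMeans(sig[, baseline_window, drop = FALSE])
  conc <- matrix(0, nrow(sig), n)
  if (series$modality == "CTP") {
    conc[bm, ] <- sig[bm, ] - b0[bm]
  } else {
    ratio <- sig[bm, , drop = FALSE] / b0[bm]
    conc[bm, ] <- -log(ratio) / series$echo_time
  }
  bad <- !is.finite(conc) | conc < 0
  n_clipped <- sum(bad)
  conc[bad] <- 0
  structure(list(data = array(conc, dm),
                 baseline_window = baseline_window,
                 brain_mask = brain_mask,
                 frame_times = series$frame_times,
                 voxel_size = series$voxel_size,
                 n_clipped = n_clipped),
            class = "concentration_series")
}

# First frame whose mean brain signal departs from the running baseline
# by > 3 baseline SDs (plus a tiny absolute floor so noiseless series
# trigger on the first true change). Minimum 3 baseline frames.
detect_baseline <- function(m) {
  n <- length(m)
  if (n < 4L) stop_bolus("too few frames to detect bolus arrival")
  for (f in 4:n) {
    base <- m[1:(f - 1)]
    thr <- 3 * stats::sd(base) + max(1e-9, 1e-7 * abs(mean(base)))
    if (abs(m[f] - mean(base)) > thr) return(1:(f - 1))
  }
  stop_bolus("bolus arrival not detected in mean brain signal")
}
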