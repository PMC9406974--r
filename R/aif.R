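# Automatic arterial input function detection and optional gamma-variate
# refit (recirculation suppression).

#' Automatically detect the arterial input function
#'
#' Every brain voxel is scored by equally weighted z-scores of the three
#' classic arterial-curve properties: high peak, early first moment and
#' narrow FWHM. The `top_k` highest-scoring voxels (ties broken by
#' lexicographic voxel coordinate) are averaged into ca(t).
#'
#' @param conc a [to_concentration()] result.
#' @param top_k number of voxels to average (default 5).
#' @return an `aif` object: `times`, `concentration`, `source_voxels`
#'   (`top_k` x 3 matrix of voxel coordinates), `fit` (NULL until
#'   [fit_gamma_variate()] is applied).
#' @export
detect_aif <- function(conc, top_k = 5L) {
  stopifnot(inherits(conc, "concentration_series"))
  if (!any(conc$brain_mask)) stop_masking("brain mask is empty")
  nfr <- dim(conc$data)[4]
  if (nfr < 8L) stop_dimension("AIF detection needs >= 8 frames")
  dm <- dim(conc$data)[1:3]
  cm <- matrix(conc$data, prod(dm), nfr)
  idx <- which(as.vector(conc$brain_mask))
  cmat <- cm[idx, , drop = FALSE]
  times <- conc$frame_times

  peak <- apply(cmat, 1, max)
  area <- rowSums(cmat)
  fm <- as.vector(cmat %*% times) / area        # first moment
  fwhm <- apply(cmat, 1, curve_fwhm, times = times)

  ok <- is.finite(peak) & is.finite(fm) & is.finite(fwhm) & peak > 0
  if (sum(ok) < top_k)
    stop_aif(sprintf("only %d voxels with finite AIF scores (need %d)",
                     sum(ok), top_k))
  z <- function(v) {
    s <- stats::sd(v[ok])
    if (s == 0) rep(0, length(v)) else (v - mean(v[ok])) / s
  }
  score <- z(peak) - z(fm) - z(fwhm)
  score[!ok] <- -Inf
  ord <- order(-score, idx)          # linear index is lexicographic (x,y,z)
  sel <- idx[ord[seq_len(top_k)]]
  ca <- colMeans(cm[sel, , drop = FALSE])
  structure(list(times = times, concentration = ca,
                 source_voxels = arrayInd(sel, dm), fit = NULL),
            class = "aif")
}

# Full width at half maximum by linear interpolation of the half-peak
# crossings around the peak.
curve_fwhm <- function(y, times) {
  p <- which.max(y)
  half <- y[p] / 2
  if (y[p] <= 0) return(NA_real_)
  left <- NA_real_
  if (p > 1) for (i in p:2) {
    if (y[i - 1] <= half) {
      left <- times[i - 1] + (times[i] - times[i - 1]) *
        (half - y[i - 1]) / (y[i] - y[i - 1])
      break
    }
  }
  right <- NA_real_
  n <- length(y)
  if (p < n) for (i in p:(n - 1)) {
    if (y[i + 1] <= half) {
      right <- times[i] + (times[i + 1] - times[i]) *
        (half - y[i]) / (y[i + 1] - y[i])
      break
    }
  }
  if (is.na(left)) left <- times[1]
  if (is.na(right)) right <- times[n]   # unresolved tail: penalize as wide
  right - left
}

#' Fit a gamma-variate model to a concentration curve
#'
#' Least-squares fit of `A (t-t0)^alpha exp(-(t-t0)/beta)` to the samples
#' up to 1.5x the time-to-peak (suppressing recirculation). Initial
#' values come from a log-linearization; the fit is refined by
#' Nelder-Mead on (log A, t0, log alpha, log beta).
#'
#' @param curve concentration samples (positive peak required).
#' @param times matching time grid (s).
#' @return [gamma_variate_params()] with attribute `"rmse"`.
#' @export
fit_gamma_variate <- function(curve, times) {
  if (length(curve) != length(times))
    stop_dimension("curve and times lengths differ")
  pk <- max(curve)
  if (!is.finite(pk) || pk <= 0) stop_fit("curve has no positive peak")
  ttp <- times[which.max(curve)]
  use <- times <= 1.5 * ttp
  y <- curve[use]; tt <- times[use]
  above <- which(y > 0.05 * pk)
  if (length(above) < 4L) stop_fit("too few samples above 5% of peak to fit")
  t0_init <- if (above[1] > 1) tt[above[1] - 1] else tt[1] - (tt[2] - tt[1])

  loglin <- function(t0) {
    sel <- tt > t0 & y > 0.02 * pk
    if (sum(sel) < 3L) return(NULL)
    X <- cbind(1, log(tt[sel] - t0), -(tt[sel] - t0))
    co <- tryCatch(stats::lsfit(X, log(y[sel]), intercept = FALSE)$coefficients,
                   error = function(e) NULL)
    if (is.null(co) || co[2] <= 0 || co[3] <= 0) return(NULL)
    c(A = exp(unname(co[1])), t0 = t0, alpha = unname(co[2]),
      beta = 1 / unname(co[3]))
  }
  init <- NULL
  for (t0 in unique(c(t0_init, t0_init + c(-0.5, 0.5) * (tt[2] - tt[1]), 0)))
    if (t0 < ttp && !is.null(init <- loglin(t0))) break
  if (is.null(init)) init <- c(A = pk, t0 = max(0, t0_init), alpha = 2,
                               beta = max((ttp - t0_init) / 2, 0.5))

  obj <- function(p) {
    pr <- list(amplitude = exp(p[1]), t0 = p[2],
               alpha = exp(p[3]), beta = exp(p[4]))
    if (pr$t0 >= ttp) return(1e12)
    yy <- pr$amplitude * ifelse(tt > pr$t0,
      (pmax(tt - pr$t0, 0))^pr$alpha * exp(-pmax(tt - pr$t0, 0) / pr$beta), 0)
    v <- sum((yy - y)^2)
    if (!is.finite(v)) 1e12 else v
  }
  p0 <- c(log(init["A"]), init["t0"], log(init["alpha"]), log(init["beta"]))
  fit <- stats::optim(p0, obj, method = "Nelder-Mead",
                      control = list(maxit = 4000, reltol = 1e-14))
  if (!is.finite(fit$value))
    stop_fit("gamma-variate fit did not converge (non-finite objective)")
  params <- gamma_variate_params(amplitude = exp(fit$par[1]), t0 = fit$par[2],
                                 alpha = exp(fit$par[3]), beta = exp(fit$par[4]))
  rmse <- sqrt(fit$value / length(y))
  if (rmse > 0.25 * pk)
    stop_fit(sprintf("gamma-variate fit failed to converge (RMSE %.3g vs peak %.3g)",
                     rmse, pk))
  attr(params, "rmse") <- rmse
  params
}

#' Export an AIF as a two-column CSV
#'
#' @param aif a [detect_aif()] result.
#' @param path output path; columns `time_s`, `concentration`.
#' @export
write_aif_csv <- function(aif, path) {
  stopifnot(inherits(aif, "aif"))
  utils::write.csv(data.frame(time_s = aif$times,
                              concentration = aif$concentration),
                   path, row.names = FALSE)
  invisible(path)
}
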