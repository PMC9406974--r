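# Series I/O (NIfTI + JSON sidecar) and pipeline configuration.

#' Read a 4D perfusion series from NIfTI plus JSON sidecar
#'
#' The sidecar supplies acquisition metadata the NIfTI header cannot
#' carry reliably: `frame_times` (s), `modality` ("CTP" or "DSC-MRI")
#' and, for DSC-MRI, `echo_time` (s).
#'
#' @param path NIfTI file (.nii or .nii.gz).
#' @param sidecar JSON path; defaults to `path` with the NIfTI extension
#'   replaced by `.json`.
#' @return a [perfusion_series()].
#' @export
read_series <- function(path, sidecar = NULL) {
  if (is.null(sidecar))
    sidecar <- paste0(sub("\\.nii(\\.gz)?$", "", path), ".json")
  if (!file.exists(sidecar))
    stop_format(sprintf("sidecar JSON not found: %s", sidecar))
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  for (f in c("frame_times", "modality"))
    if (is.null(meta[[f]]))
      stop_format(sprintf("sidecar is missing required field '%s'", f))
  nii <- read_nifti(path)
  if (length(dim(nii$data)) != 4L)
    stop_format(sprintf("expected a 4D series, got a %dD volume",
                        length(dim(nii$data))))
  perfusion_series(nii$data, voxel_size = nii$voxel_size,
                   frame_times = meta$frame_times, modality = meta$modality,
                   echo_time = meta$echo_time)
}

#' Write a perfusion series as NIfTI plus JSON sidecar
#'
#' @param series a [perfusion_series()].
#' @param path output NIfTI path.
#' @export
write_series <- function(series, path) {
  stopifnot(inherits(series, "perfusion_series"))
  dts <- diff(series$frame_times)
  write_nifti(series$data, path, series$voxel_size, dt = dts[1],
              datatype = "float64")
  sidecar <- paste0(sub("\\.nii(\\.gz)?$", "", path), ".json")
  meta <- list(frame_times = series$frame_times, modality = series$modality)
  if (!is.null(series$echo_time)) meta$echo_time <- series$echo_time
  jsonlite::write_json(meta, sidecar, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Pipeline configuration
#'
#' Collects every tunable of the post-processing chain in one
#' JSON-serializable object: segmentation [thresholds()], map
#' [scaling_constants()], deconvolution options, preprocessing options
#' and the RNG seed.
#'
#' @param thresholds a [thresholds()] object.
#' @param constants a [scaling_constants()] object.
#' @param deconv list(threshold_frac, circulant).
#' @param preproc list(fwhm_mm_ctp, fwhm_mm_mr, motion_correct): Gaussian
#'   FWHM defaults 2 mm for CTP and 0 for MR (see the methods vignette
#'   for the partial-volume bias of heavier kernels).
#' @param aif list(top_k, gamma_fit): gamma-variate refit of the detected
#'   AIF is off by default.
#' @param seed integer seed for any randomized step.
#' @param out_dir default output directory for the CLI.
#' @export
pipeline_config <- function(thresholds = perfstroke::thresholds(),
                            constants = scaling_constants(),
                            deconv = list(threshold_frac = 0.10, circulant = TRUE),
                            preproc = list(fwhm_mm_ctp = 2, fwhm_mm_mr = 0,
                                           motion_correct = TRUE),
                            aif = list(top_k = 5L, gamma_fit = FALSE),
                            seed = 1L, out_dir = ".") {
  cfg <- list(thresholds = thresholds, constants = constants,
              deconv = deconv, preproc = preproc, aif = aif,
              seed = as.integer(seed), out_dir = out_dir)
  validate_config(cfg)
  class(cfg) <- "pipeline_config"
  cfg
}

config_known_keys <- list(
  top = c("thresholds", "constants", "deconv", "preproc", "aif", "seed", "out_dir"),
  thresholds = c("rcbf_frac", "adc_max", "tmax_min", "min_cluster_ml"),
  constants = c("k_av", "rho", "h_sv", "h_lv"),
  deconv = c("threshold_frac", "circulant"),
  preproc = c("fwhm_mm_ctp", "fwhm_mm_mr", "motion_correct"),
  aif = c("top_k", "gamma_fit"))

validate_config <- function(cfg) {
  extra <- setdiff(names(cfg), config_known_keys$top)
  if (length(extra))
    stop_format(sprintf("unknown config key(s): %s", paste(extra, collapse = ", ")))
  for (sec in c("thresholds", "constants", "deconv", "preproc", "aif")) {
    extra <- setdiff(names(cfg[[sec]]), config_known_keys[[sec]])
    if (length(extra))
      stop_format(sprintf("unknown config key(s) in '%s': %s", sec,
                          paste(extra, collapse = ", ")))
  }
  tf <- cfg$deconv$threshold_frac
  if (!is.numeric(tf) || tf <= 0 || tf > 1)
    stop_format("deconv$threshold_frac must be in (0, 1]")
  invisible(cfg)
}

#' Read / write a pipeline configuration as JSON
#'
#' Unknown keys are rejected so silent misconfiguration cannot happen.
#'
#' @param path JSON file path.
#' @return a [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  base <- pipeline_config()
  for (sec in c("thresholds", "constants", "deconv", "preproc", "aif")) {
    if (!is.null(raw[[sec]])) {
      extra <- setdiff(names(raw[[sec]]), config_known_keys[[sec]])
      if (length(extra))
        stop_format(sprintf("unknown config key(s) in '%s': %s", sec,
                            paste(extra, collapse = ", ")))
      for (k in names(raw[[sec]])) base[[sec]][[k]] <- raw[[sec]][[k]]
    }
  }
  extra <- setdiff(names(raw), config_known_keys$top)
  if (length(extra))
    stop_format(sprintf("unknown config key(s): %s", paste(extra, collapse = ", ")))
  if (!is.null(raw$seed)) base$seed <- as.integer(raw$seed)
  if (!is.null(raw$out_dir)) base$out_dir <- raw$out_dir
  validate_config(base)
  base
}

#' @rdname read_pipeline_config
#' @param config a [pipeline_config()] to serialize.
#' @export
write_pipeline_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- lapply(unclass(config), function(x) if (is.list(x)) unclass(x) else x)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

# Stable hash of a config for provenance blocks (no external digest dep).
config_hash <- function(config) {
  s <- jsonlite::toJSON(lapply(unclass(config), unclass), auto_unbox = TRUE,
                        digits = NA)
  # FNV-1a 32-bit over the JSON bytes (double arithmetic, kept exact by
  # splitting the 32x24-bit product into 16-bit halves)
  mulmod32 <- function(a, b) {
    a_lo <- a %% 65536
    a_hi <- (a - a_lo) / 65536
    (((a_hi * b) %% 65536) * 65536 + a_lo * b) %% 4294967296
  }
  h <- 2166136261
  for (b in as.integer(charToRaw(s))) {
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), b)
    h <- mulmod32(h, 16777619)
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

provenance_block <- function(config) {
  list(software = "perfstroke",
       version = as.character(utils::packageVersion("perfstroke")),
       config_hash = config_hash(config),
       seed = config$seed)
}
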