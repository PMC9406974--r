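# End-to-end pipeline runners tying the stages together, with per-stage
# logging and deterministic output, plus cohort comparison from CSV.

log_stage <- function(stage, ...) {
  message(sprintf("[perfstroke] %s: %s", stage, sprintf(...)))
}

# Shared perfusion chain: preprocess -> concentration -> AIF -> residue -> maps.
perfusion_chain <- function(series, config, fwhm) {
  with_stage <- function(stage, expr) {
    tryCatch(expr, perf_error = function(e) {
      e$message <- sprintf("[stage %s] %s", stage, e$message)
      stop(e)
    })
  }
  if (isTRUE(config$preproc$motion_correct)) {
    log_stage("motion_correct", "aligning %d frames to frame 1",
              dim(series$data)[4])
    series <- with_stage("motion_correct", motion_correct(series))
  }
  log_stage("smooth", "Gaussian FWHM %.3g mm", fwhm)
  series <- with_stage("smooth", smooth_series(series, fwhm))
  log_stage("brain_mask", "modality %s", series$modality)
  mask <- with_stage("brain_mask", compute_brain_mask(series))
  log_stage("to_concentration", "%d brain voxels", sum(mask))
  conc <- with_stage("to_concentration", to_concentration(series, mask))
  if (conc$n_clipped > 0)
    log_stage("to_concentration", "clipped %d negative/non-finite values",
              conc$n_clipped)
  log_stage("detect_aif", "top_k = %d", config$aif$top_k)
  aif <- with_stage("detect_aif", detect_aif(conc, top_k = config$aif$top_k))
  if (isTRUE(config$aif$gamma_fit)) {
    fit <- with_stage("fit_gamma_variate",
                      fit_gamma_variate(aif$concentration, aif$times))
    aif$fit <- fit
    aif$concentration <- gamma_variate_curve(fit, aif$times)
    log_stage("fit_gamma_variate", "RMSE %.4g", attr(fit, "rmse"))
  }
  log_stage("deconvolve", "threshold_frac %.3g, circulant %s",
            config$deconv$threshold_frac, config$deconv$circulant)
  residue <- with_stage("deconvolve",
    deconvolve(conc, aif, threshold_frac = config$deconv$threshold_frac,
               circulant = config$deconv$circulant))
  log_stage("compute_maps", "kAV %.3g rho %.3g HSV %.3g HLV %.3g",
            config$constants$k_av, config$constants$rho,
            config$constants$h_sv, config$constants$h_lv)
  maps <- with_stage("compute_maps",
                     compute_maps(residue, conc, aif, config$constants))
  list(series = series, mask = mask, conc = conc, aif = aif, maps = maps)
}

#' Run the full CTP post-processing pipeline
#'
#' motion correction, smoothing, brain masking, signal-to-concentration,
#' AIF detection, deconvolution, map computation, core/penumbra
#' segmentation, volumetrics and DEFUSE3 triage. Deterministic for a
#' given config.
#'
#' @param series a CTP [perfusion_series()].
#' @param config a [pipeline_config()].
#' @param case_id identifier carried into the result row.
#' @return list: `result` ([mismatch_profile()]), `decision`
#'   ([triage_defuse3()]), `maps`, `core_mask`, `penumbra_mask`, `aif`,
#'   `brain_mask`, `provenance`.
#' @export
run_ctp_pipeline <- function(series, config = pipeline_config(),
                             case_id = "case") {
  stopifnot(inherits(series, "perfusion_series"))
  if (series$modality != "CTP")
    stop_format("run_ctp_pipeline expects a CTP series")
  ch <- perfusion_chain(series, config, config$preproc$fwhm_mm_ctp)
  core <- segment_core_ctp(ch$maps, config$thresholds)
  pen <- segment_penumbra(ch$maps, core, config$thresholds)
  icv <- mask_volume(core, series$voxel_size)
  pv <- mask_volume(pen, series$voxel_size)
  result <- mismatch_profile(icv, pv, "CTP")
  decision <- triage_defuse3(result)
  log_stage("triage", "ICV %.1f mL, PV %.1f mL -> %s", icv, pv,
            if (decision$eligible) "eligible" else "not eligible")
  list(case_id = case_id, result = result, decision = decision,
       maps = ch$maps, core_mask = core, penumbra_mask = pen,
       aif = ch$aif, brain_mask = ch$mask,
       provenance = provenance_block(config))
}

#' Run the MRI (DWI + PWI) post-processing pipeline
#'
#' The ischemic core comes from the ADC map (threshold 620e-6 mm^2/s);
#' the penumbra from the PWI Tmax map via the deconvolution chain.
#'
#' @param pwi_series a DSC-MRI [perfusion_series()].
#' @param adc_volume 3D ADC array (mm^2/s) on the PWI grid.
#' @param config a [pipeline_config()].
#' @param case_id identifier carried into the result row.
#' @return as [run_ctp_pipeline()].
#' @export
run_mri_pipeline <- function(pwi_series, adc_volume,
                             config = pipeline_config(), case_id = "case") {
  stopifnot(inherits(pwi_series, "perfusion_series"))
  if (pwi_series$modality != "DSC-MRI")
    stop_format("run_mri_pipeline expects a DSC-MRI series")
  if (!all(dim(adc_volume) == dim(pwi_series$data)[1:3]))
    stop_geometry(sprintf(
      "ADC grid (%s) does not match PWI grid (%s); resampling is out of scope",
      paste(dim(adc_volume), collapse = "x"),
      paste(dim(pwi_series$data)[1:3], collapse = "x")))
  ch <- perfusion_chain(pwi_series, config, config$preproc$fwhm_mm_mr)
  core <- segment_core_adc(adc_volume, ch$mask, config$thresholds,
                           pwi_series$voxel_size)
  pen <- segment_penumbra(ch$maps, core, config$thresholds)
  icv <- mask_volume(core, pwi_series$voxel_size)
  pv <- mask_volume(pen, pwi_series$voxel_size)
  result <- mismatch_profile(icv, pv, "MRI")
  decision <- triage_defuse3(result)
  log_stage("triage", "ICV %.1f mL, PV %.1f mL -> %s", icv, pv,
            if (decision$eligible) "eligible" else "not eligible")
  list(case_id = case_id, result = result, decision = decision,
       maps = ch$maps, core_mask = core, penumbra_mask = pen,
       aif = ch$aif, brain_mask = ch$mask,
       provenance = provenance_block(config))
}

#' One-row data frame for a pipeline result
#'
#' Matches the per-case CSV layout used by [compare_cohort()].
#' @param run a [run_ctp_pipeline()] / [run_mri_pipeline()] result.
#' @export
result_row <- function(run) {
  data.frame(case_id = run$case_id, modality = run$result$modality,
             icv_ml = run$result$icv, pv_ml = run$result$pv,
             mismatch_volume_ml = run$result$mismatch_volume,
             mismatch_ratio = run$result$mismatch_ratio,
             eligible = run$decision$eligible,
             failed_criteria = paste(run$decision$failed_criteria,
                                     collapse = ";"))
}

#' Compare two per-case volumetric CSV files
#'
#' Each CSV needs columns `case_id`, `icv_ml`, `pv_ml` (the layout
#' written by the CLI / [result_row()]). Cases are joined on `case_id`;
#' unmatched ids are an error. Produces the agreement report (ICC,
#' Bland-Altman, Wilcoxon for ICV and PV, direction A minus B) and the
#' triage concordance table with 70-mL subgroups.
#'
#' @param csv_a,csv_b per-case result files for packages A and B.
#' @param out_dir optional directory; if given, writes `agreement.json`
#'   and `concordance.csv` (plus `bland_altman_{icv,pv}.csv` scatter
#'   data).
#' @param config a [pipeline_config()] (for the provenance block).
#' @return the [agreement_report()] list (invisibly if written).
#' @export
compare_cohort <- function(csv_a, csv_b, out_dir = NULL,
                           config = pipeline_config()) {
  a <- utils::read.csv(csv_a, stringsAsFactors = FALSE)
  b <- utils::read.csv(csv_b, stringsAsFactors = FALSE)
  for (nm in c("case_id", "icv_ml", "pv_ml")) {
    if (!nm %in% names(a)) stop_format(sprintf("%s: missing column '%s'", csv_a, nm))
    if (!nm %in% names(b)) stop_format(sprintf("%s: missing column '%s'", csv_b, nm))
  }
  only_a <- setdiff(a$case_id, b$case_id)
  only_b <- setdiff(b$case_id, a$case_id)
  if (length(only_a) || length(only_b))
    stop_join(sprintf("unmatched case ids: %s",
                      paste(c(only_a, only_b), collapse = ", ")))
  b <- b[match(a$case_id, b$case_id), ]
  mk <- function(df) lapply(seq_len(nrow(df)), function(i)
    mismatch_profile(df$icv_ml[i], df$pv_ml[i]))
  cohort <- paired_cohort(a$case_id, mk(a), mk(b))
  rep <- agreement_report(cohort)
  rep$provenance <- provenance_block(config)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    json <- rep
    json$icv$bland_altman$means <- NULL; json$icv$bland_altman$diffs <- NULL
    json$pv$bland_altman$means <- NULL; json$pv$bland_altman$diffs <- NULL
    jsonlite::write_json(json, file.path(out_dir, "agreement.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         dataframe = "rows")
    utils::write.csv(rep$triage$table, file.path(out_dir, "concordance.csv"),
                     row.names = FALSE)
    for (f in c("icv", "pv")) {
      ba <- rep[[f]]$bland_altman
      utils::write.csv(data.frame(case_id = a$case_id, mean = ba$means,
                                  diff = ba$diffs),
                       file.path(out_dir, sprintf("bland_altman_%s.csv", f)),
                       row.names = FALSE)
    }
    return(invisible(rep))
  }
  rep
}
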