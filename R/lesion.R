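# Ischemic core / penumbra segmentation, volumetrics, mismatch profile
# and DEFUSE3 thrombectomy triage.

#' Lesion segmentation thresholds
#'
#' Defaults are the standard clinical operating points: core at relative
#' CBF below 30% of the normally-perfused reference (CTP) or ADC below
#' 620e-6 mm^2/s (MRI); penumbra at Tmax above 6 s. All strict
#' inequalities. Connected components smaller than `min_cluster_ml` are
#' discarded (26-connectivity).
#'
#' @param rcbf_frac core rCBF fraction of the reference (default 0.30).
#' @param adc_max core ADC ceiling in mm^2/s (default 620e-6).
#' @param tmax_min penumbra Tmax floor in seconds (default 6).
#' @param min_cluster_ml minimum cluster size in mL (default 1).
#' @export
thresholds <- function(rcbf_frac = 0.30, adc_max = 620e-6,
                       tmax_min = 6.0, min_cluster_ml = 1.0) {
  assert_scalar_num(rcbf_frac, "rcbf_frac", positive = TRUE)
  assert_scalar_num(adc_max, "adc_max", positive = TRUE)
  assert_scalar_num(tmax_min, "tmax_min", positive = TRUE)
  assert_scalar_num(min_cluster_ml, "min_cluster_ml", positive = TRUE)
  if (rcbf_frac >= 1) stop_parameter("rcbf_frac must be < 1")
  structure(list(rcbf_frac = rcbf_frac, adc_max = adc_max,
                 tmax_min = tmax_min, min_cluster_ml = min_cluster_ml),
            class = "thresholds")
}

#' Segment the ischemic core from CTP perfusion maps
#'
#' The rCBF reference is the median rCBF over normally-perfused brain
#' (Tmax <= 4 s), falling back to the whole-brain median if that set is
#' empty. Core voxels have `rcbf < rcbf_frac * reference` and (by
#' default) `tmax > tmax_min`, restricting core to hypoperfused tissue;
#' clusters below `min_cluster_ml` are removed.
#'
#' @param maps a [compute_maps()] result.
#' @param thr a [thresholds()] object.
#' @param gate_by_tmax require core voxels to also be hypoperfused
#'   (default TRUE).
#' @return logical 3D core mask.
#' @export
segment_core_ctp <- function(maps, thr = thresholds(), gate_by_tmax = TRUE) {
  stopifnot(inherits(maps, "perfusion_maps"))
  bm <- maps$brain_mask
  ref_set <- bm & maps$tmax <= 4
  if (!any(ref_set)) ref_set <- bm
  if (!any(ref_set)) stop_segmentation("reference region for rCBF normalization is empty")
  ref <- stats::median(maps$rcbf[ref_set])
  if (!is.finite(ref) || ref <= 0)
    stop_segmentation("rCBF reference is non-positive; cannot normalize")
  core <- bm & maps$rcbf < thr$rcbf_frac * ref
  if (gate_by_tmax) core <- core & maps$tmax > thr$tmax_min
  filter_small_clusters(core, maps$voxel_size, thr$min_cluster_ml)
}

#' Segment the ischemic core from an ADC map
#'
#' Core voxels are brain voxels with `adc < adc_max` (strict), small
#' clusters removed. ADC must be in mm^2/s; a median brain ADC above 0.1
#' indicates mis-scaled units and raises an error.
#'
#' @param adc 3D ADC volume (mm^2/s).
#' @param brain_mask logical 3D array.
#' @param thr a [thresholds()] object.
#' @param voxel_size mm per axis (for the cluster filter).
#' @return logical 3D core mask.
#' @export
segment_core_adc <- function(adc, brain_mask, thr = thresholds(),
                             voxel_size = c(1, 1, 1)) {
  if (!all(dim(adc) == dim(brain_mask)))
    stop_dimension("ADC and brain mask grids differ")
  med <- stats::median(adc[brain_mask])
  if (is.finite(med) && med > 0.1)
    stop_unit(sprintf(
      "median brain ADC is %.3g; expected mm^2/s (~1e-3). Values look mis-scaled", med))
  core <- brain_mask & adc < thr$adc_max
  filter_small_clusters(core, voxel_size, thr$min_cluster_ml)
}

#' Segment the penumbra from Tmax
#'
#' Hypoperfused tissue is `tmax > tmax_min` (strict) within the brain,
#' small clusters removed; the penumbra is hypoperfused tissue minus the
#' core.
#'
#' @param maps a [compute_maps()] result.
#' @param core logical core mask (same grid).
#' @param thr a [thresholds()] object.
#' @return logical 3D penumbra mask, disjoint from `core`.
#' @export
segment_penumbra <- function(maps, core, thr = thresholds()) {
  stopifnot(inherits(maps, "perfusion_maps"))
  if (!all(dim(core) == dim(maps$tmax)))
    stop_dimension("core mask and maps grids differ")
  hypo <- maps$brain_mask & maps$tmax > thr$tmax_min
  hypo <- filter_small_clusters(hypo, maps$voxel_size, thr$min_cluster_ml)
  hypo & !core
}

#' Volume of a binary mask in millilitres
#'
#' @param mask logical array.
#' @param voxel_size mm per axis.
#' @export
mask_volume <- function(mask, voxel_size) {
  if (length(voxel_size) != 3L || any(voxel_size <= 0))
    stop_parameter("voxel_size must be 3 positive spacings (mm)")
  sum(mask) * prod(voxel_size) / 1000
}

#' Mismatch profile from core and penumbra volumes
#'
#' Mismatch volume is penumbra minus core; mismatch ratio is penumbra
#' over core (+Inf when the core is empty but penumbra is not; 0 when
#' both are empty).
#'
#' @param icv ischemic core volume (mL, >= 0).
#' @param pv penumbra volume (mL, >= 0).
#' @param modality `"CTP"` or `"MRI"` (annotation only).
#' @return a `volumetric_result`: `icv`, `pv`, `mismatch_volume`,
#'   `mismatch_ratio`, `modality`.
#' @export
mismatch_profile <- function(icv, pv, modality = c("CTP", "MRI")) {
  modality <- match.arg(modality)
  assert_scalar_num(icv, "icv", nonneg = TRUE)
  assert_scalar_num(pv, "pv", nonneg = TRUE)
  ratio <- if (icv > 0) pv / icv else if (pv > 0) Inf else 0
  structure(list(icv = icv, pv = pv, mismatch_volume = pv - icv,
                 mismatch_ratio = ratio, modality = modality),
            class = "volumetric_result")
}

#' @export
print.volumetric_result <- function(x, ...) {
  cat(sprintf("<volumetric_result> %s  ICV %.1f mL, PV %.1f mL, mismatch %.1f mL, ratio %s\n",
              x$modality, x$icv, x$pv, x$mismatch_volume,
              if (is.finite(x$mismatch_ratio)) sprintf("%.2f", x$mismatch_ratio) else "Inf"))
  invisible(x)
}

#' DEFUSE3 thrombectomy eligibility triage
#'
#' Eligible iff ischemic core volume < 70 mL AND mismatch ratio > 1.8
#' AND mismatch volume > 15 mL (all strict). `failed_criteria` lists
#' every violated condition as a subset of `c("icv", "ratio", "volume")`.
#'
#' @param result a [mismatch_profile()] result.
#' @return a `triage_decision`: `eligible`, `failed_criteria`.
#' @export
triage_defuse3 <- function(result) {
  stopifnot(inherits(result, "volumetric_result"))
  failed <- character()
  if (!(result$icv < 70)) failed <- c(failed, "icv")
  if (!(result$mismatch_ratio > 1.8)) failed <- c(failed, "ratio")
  if (!(result$mismatch_volume > 15)) failed <- c(failed, "volume")
  structure(list(eligible = length(failed) == 0L, failed_criteria = failed),
            class = "triage_decision")
}

#' @export
print.triage_decision <- function(x, ...) {
  if (x$eligible) cat("<triage_decision> ELIGIBLE for mechanical thrombectomy\n")
  else cat(sprintf("<triage_decision> NOT eligible (failed: %s)\n",
                   paste(x$failed_criteria, collapse = ", ")))
  invisible(x)
}
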