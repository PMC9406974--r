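# Shared fixtures: a small, fast phantom world for unit tests. The
# acceptance tests build the full-size 64x64x16 phantom themselves.

small_spec <- function(noise_sd = 0, modality = "CTP", ...) {
  args <- list(grid_shape = c(32L, 32L, 8L),
               voxel_size = c(3, 3, 6),
               core_region = list(center = c(12, 16, 4),
                                  semi_axes_mm = c(15, 12, 9),
                                  cbf = 10),
               penumbra_region = list(center = c(12, 16, 4),
                                      semi_axes_mm = c(25, 20, 15),
                                      delay_s = 8),
               noise_sd = noise_sd, modality = modality)
  over <- list(...)
  for (k in names(over)) args[k] <- list(over[[k]])
  do.call(phantom_spec, args)
}

quiet_ctp <- function(series, config = pipeline_config(), ...)
  suppressMessages(run_ctp_pipeline(series, config, ...))

quiet_mri <- function(series, adc, config = pipeline_config(), ...)
  suppressMessages(run_mri_pipeline(series, adc, config, ...))

# Minimal hand-built concentration series around a matrix of curves
# (rows = voxels), bypassing the preprocessing chain.
conc_from_curves <- function(curves, times, voxel_size = c(1, 1, 1)) {
  if (is.null(dim(curves))) curves <- matrix(curves, nrow = 1)
  nv <- nrow(curves)
  a <- array(0, c(nv, 1, 1, ncol(curves)))
  a[, 1, 1, ] <- curves
  structure(list(data = a, baseline_window = 1:3,
                 brain_mask = array(TRUE, c(nv, 1, 1)),
                 frame_times = times, voxel_size = voxel_size,
                 n_clipped = 0L),
            class = "concentration_series")
}

aif_from_curve <- function(curve, times)
  structure(list(times = times, concentration = curve,
                 source_voxels = matrix(1L, 1, 3), fit = NULL),
            class = "aif")

dice <- perfstroke:::dice_coefficient
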