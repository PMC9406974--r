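# Internal helpers: condition classes, array geometry, connected components.

`%||%` <- function(a, b) if (is.null(a)) b else a

# All package errors derive from "perf_error"; validation-type errors
# additionally carry "perf_validation_error" so the CLI can map them to
# exit code 2 (runtime failures exit 1).
perf_stop <- function(msg, class, validation = TRUE, call = sys.call(-1)) {
  classes <- c(class, if (validation) "perf_validation_error",
               "perf_error", "error", "condition")
  stop(structure(class = classes,
                 list(message = msg, call = call)))
}

stop_parameter   <- function(msg) perf_stop(msg, "perf_parameter_error")
stop_dimension   <- function(msg) perf_stop(msg, "perf_dimension_error")
stop_geometry    <- function(msg) perf_stop(msg, "perf_geometry_error")
stop_format      <- function(msg) perf_stop(msg, "perf_format_error")
stop_masking     <- function(msg) perf_stop(msg, "perf_masking_error", validation = FALSE)
stop_bolus       <- function(msg) perf_stop(msg, "perf_bolus_error", validation = FALSE)
stop_aif         <- function(msg) perf_stop(msg, "perf_aif_error", validation = FALSE)
stop_fit         <- function(msg) perf_stop(msg, "perf_fit_error", validation = FALSE)
stop_deconv      <- function(msg) perf_stop(msg, "perf_deconv_error", validation = FALSE)
stop_map         <- function(msg) perf_stop(msg, "perf_map_error", validation = FALSE)
stop_segmentation<- function(msg) perf_stop(msg, "perf_segmentation_error", validation = FALSE)
stop_unit        <- function(msg) perf_stop(msg, "perf_unit_error")
stop_sample_size <- function(msg) perf_stop(msg, "perf_sample_size_error")
stop_degenerate  <- function(msg) perf_stop(msg, "perf_degenerate_error", validation = FALSE)
stop_join        <- function(msg) perf_stop(msg, "perf_join_error")

assert_scalar_num <- function(x, name, positive = FALSE, nonneg = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_parameter(sprintf("'%s' must be a finite numeric scalar", name))
  if (positive && x <= 0)
    stop_parameter(sprintf("'%s' must be > 0 (got %g)", name, x))
  if (nonneg && x < 0)
    stop_parameter(sprintf("'%s' must be >= 0 (got %g)", name, x))
  invisible(x)
}

# Voxel-centre coordinates (mm) along one axis: centre of voxel i is (i-1/2)*h.
axis_coords_mm <- function(n, h) (seq_len(n) - 0.5) * h

# Logical 3D array of voxels inside an ellipsoid.
# center_vox: 1-based voxel coordinates of the centre; semi_axes_mm per axis.
ellipsoid_mask <- function(dim3, voxel_size, center_vox, semi_axes_mm) {
  cx <- (center_vox - 0.5) * voxel_size
  xs <- (axis_coords_mm(dim3[1], voxel_size[1]) - cx[1]) / semi_axes_mm[1]
  ys <- (axis_coords_mm(dim3[2], voxel_size[2]) - cx[2]) / semi_axes_mm[2]
  zs <- (axis_coords_mm(dim3[3], voxel_size[3]) - cx[3]) / semi_axes_mm[3]
  d2 <- outer(outer(xs^2, ys^2, `+`), zs^2, `+`)
  d2 <= 1
}

# Connected-component labelling on a logical 3D array.
# connectivity: 6 (faces) or 26 (faces+edges+corners).
label_components <- function(mask, connectivity = 26L) {
  stopifnot(is.logical(mask), length(dim(mask)) == 3L)
  dm <- dim(mask)
  offs <- neighbour_offsets(connectivity)
  labels <- array(0L, dm)
  todo <- which(mask)
  lab <- 0L
  visited <- !mask  # treat FALSE voxels as visited
  for (seed in todo) {
    if (visited[seed]) next
    lab <- lab + 1L
    frontier <- seed
    visited[seed] <- TRUE
    labels[seed] <- lab
    while (length(frontier)) {
      nb <- neighbours_of(frontier, dm, offs)
      nb <- nb[!visited[nb]]
      nb <- unique(nb)
      if (!length(nb)) break
      visited[nb] <- TRUE
      labels[nb] <- lab
      frontier <- nb
    }
  }
  labels
}

neighbour_offsets <- function(connectivity) {
  if (connectivity == 6L) {
    d <- rbind(c(-1, 0, 0), c(1, 0, 0), c(0, -1, 0),
               c(0, 1, 0), c(0, 0, -1), c(0, 0, 1))
  } else if (connectivity == 26L) {
    d <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
    d <- d[rowSums(abs(d)) > 0, , drop = FALSE]
  } else stop_parameter("connectivity must be 6 or 26")
  unname(d)
}

# Valid in-grid neighbours (linear indices) of a set of linear indices.
neighbours_of <- function(idx, dm, offs) {
  ai <- arrayInd(idx, dm)
  out <- vector("list", nrow(offs))
  for (k in seq_len(nrow(offs))) {
    co <- ai + matrix(offs[k, ], nrow(ai), 3, byrow = TRUE)
    ok <- co[, 1] >= 1L & co[, 1] <= dm[1] &
          co[, 2] >= 1L & co[, 2] <= dm[2] &
          co[, 3] >= 1L & co[, 3] <= dm[3]
    co <- co[ok, , drop = FALSE]
    out[[k]] <- co[, 1] + (co[, 2] - 1L) * dm[1] + (co[, 3] - 1L) * dm[1] * dm[2]
  }
  unlist(out, use.names = FALSE)
}

largest_component <- function(mask, connectivity = 6L) {
  lab <- label_components(mask, connectivity)
  if (!any(lab > 0L)) return(mask & FALSE)
  tab <- tabulate(lab)
  lab == which.max(tab)
}

# Fill interior holes: background is everything 6-connected to the volume border.
fill_holes <- function(mask) {
  dm <- dim(mask)
  inv <- !mask
  border <- array(FALSE, dm)
  border[c(1, dm[1]), , ] <- TRUE
  border[, c(1, dm[2]), ] <- TRUE
  border[, , c(1, dm[3])] <- TRUE
  seeds <- which(inv & border)
  if (!length(seeds)) return(array(TRUE, dm))
  offs <- neighbour_offsets(6L)
  reach <- array(FALSE, dm)
  reach[seeds] <- TRUE
  frontier <- seeds
  while (length(frontier)) {
    nb <- neighbours_of(frontier, dm, offs)
    nb <- unique(nb[inv[nb] & !reach[nb]])
    if (!length(nb)) break
    reach[nb] <- TRUE
    frontier <- nb
  }
  mask | (!reach & inv)
}

# Drop connected components smaller than min_ml millilitres.
filter_small_clusters <- function(mask, voxel_size, min_ml, connectivity = 26L) {
  if (!any(mask)) return(mask)
  vox_ml <- prod(voxel_size) / 1000
  lab <- label_components(mask, connectivity)
  sizes <- tabulate(lab)
  keep <- which(sizes * vox_ml >= min_ml)
  out <- array(lab %in% keep & mask, dim(mask))
  out
}

dice_coefficient <- function(a, b) {
  2 * sum(a & b) / (sum(a) + sum(b))
}
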