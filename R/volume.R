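#' Volumetric scalar maps
#'
#' A `volume_map` is a 3D scalar field on a regular voxel grid: either a
#' binary lesion mask (`kind = "mask"`) or a tumour frequency map in percent
#' (`kind = "frequency_percent"`). All maps taking part in one analysis must
#' share grid shape and voxel size.
#'
#' @param values 3D numeric array.
#' @param voxel_size_mm numeric length-3, voxel edge lengths in mm.
#' @param kind `"mask"` or `"frequency_percent"`.
#' @return A `volume_map` object.
#' @export
volume_map <- function(values, voxel_size_mm = c(2, 2, 2),
                       kind = c("frequency_percent", "mask")) {
  kind <- match.arg(kind)
  if (length(dim(values)) != 3L) stop("`values` must be a 3D array")
  voxel_size_mm <- rep_len(as.numeric(voxel_size_mm), 3L)
  if (any(voxel_size_mm <= 0)) stop("voxel sizes must be positive")
  if (kind == "mask" && !all(values %in% c(0, 1)))
    stop("mask values must be 0/1")
  if (kind == "frequency_percent" &&
      (min(values) < -1e-9 || max(values) > 100 + 1e-9))
    stop("frequency values must lie in [0, 100]")
  structure(list(values = values, voxel_size_mm = voxel_size_mm, kind = kind),
            class = "volume_map")
}

#' @export
print.volume_map <- function(x, ...) {
  cat(sprintf("<volume_map> %s, grid %s, voxel %s mm, range [%.3g, %.3g]\n",
              x$kind, paste(dim(x$values), collapse = "x"),
              paste(x$voxel_size_mm, collapse = "x"),
              min(x$values), max(x$values)))
  invisible(x)
}

stop_if_grid_mismatch <- function(a, b) {
  if (!identical(dim(a$values), dim(b$values)) ||
      max(abs(a$voxel_size_mm - b$voxel_size_mm)) > 1e-9)
    stop("geometry error: maps do not share grid shape and voxel size")
  invisible(NULL)
}

## separable 1D convolution along one array axis, with kernel renormalization
## at the edges so that constant fields are preserved exactly.
conv_axis <- function(arr, kernel, axis) {
  r <- (length(kernel) - 1L) / 2L
  if (r == 0L) return(arr * kernel)
  d <- dim(arr)
  out <- array(0, d)
  norm <- array(0, d)
  n <- d[axis]
  for (k in seq_along(kernel)) {
    off <- k - r - 1L
    src <- seq_len(n) + off
    keep <- src >= 1L & src <= n
    if (!any(keep)) next
    idx_dst <- idx_src <- list(seq_len(d[1]), seq_len(d[2]), seq_len(d[3]))
    idx_dst[[axis]] <- which(keep)
    idx_src[[axis]] <- src[keep]
    slab <- do.call(`[`, c(list(arr), idx_src, list(drop = FALSE)))
    out[idx_dst[[1]], idx_dst[[2]], idx_dst[[3]]] <-
      out[idx_dst[[1]], idx_dst[[2]], idx_dst[[3]]] + kernel[k] * slab
    norm[idx_dst[[1]], idx_dst[[2]], idx_dst[[3]]] <-
      norm[idx_dst[[1]], idx_dst[[2]], idx_dst[[3]]] + kernel[k]
  }
  out / norm
}

gaussian_kernel <- function(sigma_vox) {
  if (sigma_vox <= 0) return(1)
  r <- max(1L, ceiling(4 * sigma_vox))
  x <- (-r):r
  k <- exp(-x^2 / (2 * sigma_vox^2))
  k / sum(k)
}

gaussian_smooth_array <- function(values, voxel_size_mm, fwhm_mm) {
  if (fwhm_mm == 0) return(values)
  sigma_mm <- fwhm_mm / (2 * sqrt(2 * log(2)))
  for (axis in 1:3) {
    k <- gaussian_kernel(sigma_mm / voxel_size_mm[axis])
    if (length(k) > 1L) values <- conv_axis(values, k, axis)
  }
  values
}

## voxel centre coordinates in mm along one axis
axis_mm <- function(n, vox) (seq_len(n) - 0.5) * vox

## mm coordinate -> voxel index (clamped to grid)
mm_to_voxel <- function(x_mm, n, vox) {
  pmin(pmax(as.integer(ceiling(x_mm / vox)), 1L), n)
}
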