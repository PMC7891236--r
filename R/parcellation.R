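#' Symmetric synthetic brain parcellation
#'
#' Builds a mirror-symmetric labelled volume emulating a bilateral
#' parcellation with homotopic left/right parcel pairs, seven canonical
#' network affiliations, a cortical/subcortical split, and unit-sphere
#' centroids for cortical parcels (required by the spin test). Parcels are
#' carved as contiguous runs of a boustrophedon (snake) scan through each
#' hemisphere zone, so every parcel is face-connected by construction. A
#' one-voxel unlabelled margin and a two-voxel unlabelled midline corridor
#' play the role of white matter / background for the label-dilation step.
#'
#' Two designated subcortical parcels per hemisphere act as stand-ins for the
#' hippocampus and caudate (the neural-stem-cell niche regions); their ids
#' are recorded in the `niche` element.
#'
#' @param cfg A [synthetic_config()].
#' @return A `parcellation`: `labels` (3D integer array, 0 = unlabelled),
#'   `voxel_size_mm`, `table` (one row per parcel: `parcel_id`, `hemisphere`,
#'   `homotopic_id`, `network`, `is_cortical`, sphere centroid `cx,cy,cz`,
#'   volumetric centroid `vx,vy,vz` in mm), `niche` (named parcel ids) and
#'   `n_left` (parcels per hemisphere).
#' @export
make_parcellation <- function(cfg) {
  d <- cfg$grid_shape
  vox <- cfg$voxel_size_mm
  n_per <- cfg$n_parcels_per_hemisphere
  n_sub <- cfg$n_subcortical
  n_cort <- n_per - n_sub
  if (n_cort < 1L) stop("sizing error: need at least one cortical parcel")
  if (d[1] %% 2L != 0L) stop("geometry error: first axis must be even (midline)")

  xs_left <- 2L:(d[1] / 2L - 1L)
  ys <- 2L:(d[2] - 1L)
  zs <- 2L:(d[3] - 1L)
  if (length(xs_left) < 1L || length(ys) < 1L || length(zs) < 1L)
    stop("sizing error: grid too small for margins")

  ## subcortical zone = bottom z-slab of the hemisphere box, area-proportional
  h <- max(1L, round(n_sub / n_per * length(zs)))
  if (h >= length(zs)) stop("sizing error: no room left for cortical parcels")
  zs_sub <- zs[seq_len(h)]
  zs_cort <- zs[(h + 1L):length(zs)]

  n_vox_sub <- length(xs_left) * length(ys) * length(zs_sub)
  n_vox_cort <- length(xs_left) * length(ys) * length(zs_cort)
  if (n_vox_sub < 2L * n_sub || n_vox_cort < 2L * n_cort)
    stop("sizing error: infeasible parcel count for grid")

  labels <- array(0L, d)
  carve <- function(xs, ys, zs, ids) {
    ord <- snake_order(xs, ys, zs)
    n <- nrow(ord)
    cuts <- round(seq_len(length(ids)) * n / length(ids))
    start <- 1L
    for (i in seq_along(ids)) {
      rows <- start:cuts[i]
      labels[ord[rows, , drop = FALSE]] <<- ids[i]
      start <- cuts[i] + 1L
    }
  }
  carve(xs_left, ys, zs_cort, seq_len(n_cort))
  carve(xs_left, ys, zs_sub, n_cort + seq_len(n_sub))
  ## mirror to the right hemisphere: homotopic partner = id + n_per
  left_lab <- labels[xs_left, , , drop = FALSE]
  labels[d[1] + 1L - xs_left, , ] <- ifelse(left_lab > 0L, left_lab + n_per, 0L)

  networks <- c("visual", "somatomotor", "dorsal_attention",
                "ventral_attention", "limbic", "frontoparietal", "default")
  net_cort <- networks[pmin(7L, ceiling(seq_len(n_cort) / n_cort * 7))]
  net_sub <- networks[(seq_len(n_sub) - 1L) %% 7L + 1L]
  net_left <- c(net_cort, net_sub)

  ids <- seq_len(2L * n_per)
  tab <- data.frame(
    parcel_id = ids,
    hemisphere = rep(c("L", "R"), each = n_per),
    homotopic_id = c(ids[seq_len(n_per)] + n_per, ids[seq_len(n_per)]),
    network = rep(net_left, 2L),
    is_cortical = rep(c(rep(TRUE, n_cort), rep(FALSE, n_sub)), 2L),
    stringsAsFactors = FALSE
  )

  ## volumetric centroids (mm) and per-hemisphere unit-sphere projections
  cm <- parcel_centroids_mm(labels, vox, ids)
  tab$vx <- cm[, 1]; tab$vy <- cm[, 2]; tab$vz <- cm[, 3]
  centres <- rbind(
    c(mean(axis_mm(d[1], vox[1])[xs_left]), mean(axis_mm(d[2], vox[2])[ys]),
      mean(axis_mm(d[3], vox[3])[zs])),
    c(mean(axis_mm(d[1], vox[1])[d[1] + 1L - xs_left]),
      mean(axis_mm(d[2], vox[2])[ys]), mean(axis_mm(d[3], vox[3])[zs]))
  )
  hemi_idx <- ifelse(tab$hemisphere == "L", 1L, 2L)
  v <- cm - centres[hemi_idx, , drop = FALSE]
  nrm <- sqrt(rowSums(v^2))
  nrm[nrm < 1e-9] <- 1
  sph <- v / nrm
  ## snap projected centroids onto a uniform Fibonacci lattice per
  ## hemisphere (greedy nearest match): a rotation of a uniform lattice can
  ## be matched back onto it almost isometrically, which is what the spin
  ## test's null relies on; raw box projections are too non-uniform
  for (hemi in c("L", "R")) {
    ic <- which(tab$hemisphere == hemi & tab$is_cortical)
    sph[ic, ] <- snap_to_fibonacci(sph[ic, , drop = FALSE])
  }
  sph[!tab$is_cortical, ] <- NA_real_
  tab$cx <- sph[, 1]; tab$cy <- sph[, 2]; tab$cz <- sph[, 3]

  niche <- c(hippocampus = n_cort + 1L,
             caudate = n_cort + min(2L, n_sub))
  structure(list(labels = labels, voxel_size_mm = vox, table = tab,
                 niche = niche, n_left = n_per, cache = new.env()),
            class = "parcellation")
}

#' @export
print.parcellation <- function(x, ...) {
  cat(sprintf(
    "<parcellation> %d parcels (%d per hemisphere; %d cortical, %d subcortical per hemisphere), grid %s\n",
    nrow(x$table), x$n_left, sum(x$table$is_cortical) / 2L,
    sum(!x$table$is_cortical) / 2L, paste(dim(x$labels), collapse = "x")))
  invisible(x)
}

## boustrophedon scan of a box: consecutive rows are face-adjacent voxels
snake_order <- function(xs, ys, zs) {
  out <- matrix(0L, length(xs) * length(ys) * length(zs), 3L)
  row <- 1L
  for (iz in seq_along(zs)) {
    ys_i <- if (iz %% 2L == 1L) seq_along(ys) else rev(seq_along(ys))
    for (iy in ys_i) {
      xs_i <- if ((iz + iy) %% 2L == 0L) seq_along(xs) else rev(seq_along(xs))
      n <- length(xs_i)
      out[row:(row + n - 1L), ] <- cbind(xs[xs_i], ys[iy], zs[iz])
      row <- row + n
    }
  }
  out
}

## n near-uniform points on the unit sphere (golden-angle spiral)
fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  phi <- pi * (1 + sqrt(5)) * i
  cbind(r * cos(phi), r * sin(phi), z)
}

## greedy bijective match of points to a same-size Fibonacci lattice,
## best-matched pairs first
snap_to_fibonacci <- function(pts) {
  n <- nrow(pts)
  lat <- fibonacci_sphere(n)
  sim <- pts %*% t(lat)
  out <- matrix(0, n, 3L)
  free_p <- rep(TRUE, n)
  free_l <- rep(TRUE, n)
  for (step in seq_len(n)) {
    m <- which(sim == max(sim[free_p, free_l, drop = FALSE]) &
                 outer(free_p, free_l), arr.ind = TRUE)[1, , drop = FALSE]
    out[m[1], ] <- lat[m[2], ]
    free_p[m[1]] <- FALSE
    free_l[m[2]] <- FALSE
  }
  out
}

parcel_centroids_mm <- function(labels, vox, ids) {
  idx <- which(labels > 0L)
  lab <- labels[idx]
  co <- arrayInd(idx, dim(labels))
  mm <- sweep(co - 0.5, 2L, vox, `*`)
  t(vapply(ids, function(i) colMeans(mm[lab == i, , drop = FALSE]),
           numeric(3)))
}

## shift a 3D array by an integer offset, filling exposed cells with `fill`
shift_array <- function(arr, off, fill = 0L) {
  d <- dim(arr)
  out <- array(fill, d)
  src <- dst <- vector("list", 3L)
  for (a in 1:3) {
    dst[[a]] <- max(1L, 1L + off[a]):min(d[a], d[a] + off[a])
    src[[a]] <- dst[[a]] - off[a]
    if (length(dst[[a]]) == 0L) return(out)
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- arr[src[[1]], src[[2]], src[[3]]]
  out
}

#' Dilate parcel labels into unlabelled voxels
#'
#' Extends each parcel by up to `max_mm` (Euclidean, in mm) into unlabelled
#' voxels, emulating the extension of grey-matter parcels into adjacent white
#' matter. Each unlabelled voxel is claimed by the parcel whose labelled
#' voxel is nearest; ties at identical distance go to the lower parcel id.
#'
#' @param labels 3D integer label array (0 = unlabelled).
#' @param voxel_size_mm voxel edge lengths (mm).
#' @param max_mm maximum extension distance in mm.
#' @return Dilated 3D integer label array.
#' @export
dilate_labels <- function(labels, voxel_size_mm, max_mm) {
  if (max_mm <= 0) return(labels)
  r <- floor(max_mm / voxel_size_mm)
  offs <- as.matrix(expand.grid(x = -r[1]:r[1], y = -r[2]:r[2], z = -r[3]:r[3]))
  dmm <- sqrt(colSums((t(offs) * voxel_size_mm)^2))
  keep <- dmm > 1e-9 & dmm <= max_mm + 1e-9
  offs <- offs[keep, , drop = FALSE]
  dmm <- dmm[keep]
  out <- labels
  unassigned <- labels == 0L
  for (d0 in sort(unique(round(dmm, 9)))) {
    if (!any(unassigned)) break
    cand <- NULL
    for (i in which(abs(dmm - d0) < 1e-8)) {
      sh <- shift_array(labels, offs[i, ])
      sh[sh == 0L] <- NA_integer_
      cand <- if (is.null(cand)) sh else pmin(cand, sh, na.rm = TRUE)
    }
    take <- unassigned & !is.na(cand)
    out[take] <- cand[take]
    unassigned[take] <- FALSE
  }
  out
}

#' Assign point coordinates to their nearest parcel
#'
#' Points falling inside a labelled voxel take that voxel's parcel; points in
#' unlabelled voxels are assigned to the parcel owning the nearest labelled
#' voxel (Euclidean distance in mm, ties to the lower parcel id).
#'
#' @param coords_mm n x 3 matrix of point coordinates (mm).
#' @param parc A [make_parcellation()] object.
#' @return Integer vector of parcel ids.
#' @export
nearest_parcel_assignment <- function(coords_mm, parc) {
  d <- dim(parc$labels)
  vox <- parc$voxel_size_mm
  vi <- cbind(mm_to_voxel(coords_mm[, 1], d[1], vox[1]),
              mm_to_voxel(coords_mm[, 2], d[2], vox[2]),
              mm_to_voxel(coords_mm[, 3], d[3], vox[3]))
  lab <- parc$labels[vi]
  miss <- which(lab == 0L)
  if (length(miss)) {
    idx <- which(parc$labels > 0L)
    lv <- parc$labels[idx]
    co <- sweep(arrayInd(idx, d) - 0.5, 2L, vox, `*`)
    for (m in miss) {
      dd <- colSums((t(co) - coords_mm[m, ])^2)
      best <- which(dd == min(dd))
      lab[m] <- min(lv[best])
    }
  }
  lab
}
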