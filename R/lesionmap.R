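#' Build a tumour frequency map from binary lesion masks
#'
#' The value at each voxel is the percentage of masks in the cohort that
#' overlap that voxel.
#'
#' @param masks list of mask [volume_map()]s on one common grid, or a
#'   `lesion_cohort`.
#' @return A frequency [volume_map()] (percent, in \[0, 100\]).
#' @export
build_frequency_map <- function(masks) {
  if (inherits(masks, "lesion_cohort")) masks <- masks$masks
  if (length(masks) == 0L) stop("empty-cohort error: no masks")
  for (m in masks) stop_if_grid_mismatch(masks[[1]], m)
  acc <- Reduce(`+`, lapply(masks, function(m) m$values))
  volume_map(100 * acc / length(masks), masks[[1]]$voxel_size_mm,
             kind = "frequency_percent")
}

#' Gaussian smoothing of a volume map
#'
#' Separable Gaussian kernel with `sigma = fwhm / (2 sqrt(2 log 2))` per
#' axis (in mm); kernels are renormalized at grid edges so constant fields
#' are preserved. Output is clipped to \[0, 100\].
#'
#' @param map a frequency [volume_map()].
#' @param fwhm_mm full-width at half-maximum in mm (0 = identity).
#' @return Smoothed [volume_map()].
#' @export
smooth_map <- function(map, fwhm_mm = 2) {
  if (fwhm_mm < 0) stop("parameter error: fwhm must be >= 0")
  v <- gaussian_smooth_array(map$values, map$voxel_size_mm, fwhm_mm)
  volume_map(pmin(pmax(v, 0), 100), map$voxel_size_mm,
             kind = "frequency_percent")
}

#' Mirror a map onto one hemisphere
#'
#' The target-hemisphere value at each voxel becomes the mean of its own
#' value and the value at the homotopically reflected voxel; the source
#' hemisphere is retained unchanged for reference. The midline must split
#' the first axis evenly.
#'
#' @param map a [volume_map()].
#' @param to `"left"` (default) target hemisphere.
#' @return Mirrored [volume_map()].
#' @export
mirror_map <- function(map, to = c("left", "right")) {
  to <- match.arg(to)
  d <- dim(map$values)
  if (d[1] %% 2L != 0L) stop("geometry error: no midline plane on odd grid")
  v <- map$values
  xs <- seq_len(d[1] / 2L)
  refl <- d[1] + 1L - xs
  if (to == "left") {
    v[xs, , ] <- (map$values[xs, , ] + map$values[refl, , ]) / 2
  } else {
    v[refl, , ] <- (map$values[refl, , ] + map$values[xs, , ]) / 2
  }
  volume_map(v, map$voxel_size_mm, kind = map$kind)
}

#' Aggregate a voxel map to parcel means
#'
#' Averages map values within each parcel after extending parcel labels
#' `wm_extension_mm` into unlabelled (white-matter) voxels via
#' [dilate_labels()] (nearest parcel boundary wins contested voxels, then
#' lower parcel id). Parcels that end up with no voxels are reported as
#' `NA`, never silently zero.
#'
#' @param map a [volume_map()].
#' @param parc a [make_parcellation()].
#' @param scope `"left"` (167 left-hemisphere parcels) or `"bilateral"`.
#' @param wm_extension_mm extension distance into unlabelled voxels (mm).
#' @return Named numeric vector of parcel means (names = parcel ids).
#' @export
parcel_aggregate <- function(map, parc, scope = c("left", "bilateral"),
                             wm_extension_mm = 4) {
  scope <- match.arg(scope)
  if (!identical(dim(map$values), dim(parc$labels)))
    stop("geometry error: map and parcellation grids differ")
  key <- paste0("dilated_", wm_extension_mm)
  lab <- if (!is.null(parc$cache) && !is.null(parc$cache[[key]])) {
    parc$cache[[key]]
  } else {
    l <- dilate_labels(parc$labels, parc$voxel_size_mm, wm_extension_mm)
    if (!is.null(parc$cache)) parc$cache[[key]] <- l
    l
  }
  ids <- parc$table$parcel_id
  if (scope == "left") ids <- ids[parc$table$hemisphere == "L"]
  sums <- tapply(map$values[lab > 0L], lab[lab > 0L], mean)
  out <- as.numeric(sums[as.character(ids)])
  names(out) <- ids
  out
}

## grade-stratified split into two disjoint halves whose LGG fractions
## approximate multiplier x cohort fraction and (2 - multiplier) x
split_cohort <- function(grade, multiplier) {
  n <- length(grade)
  lgg <- which(grade == "LGG")
  hgg <- which(grade == "HGG")
  if (length(lgg) < 2L || length(hgg) < 2L)
    stop("split error: need >= 2 patients per grade")
  n1 <- floor(n / 2)
  f <- length(lgg) / n
  n1_lgg <- min(length(lgg) - 1L, max(1L, round(multiplier * f * n1)))
  n1_hgg <- n1 - n1_lgg
  g1 <- c(sample(lgg, n1_lgg), sample(hgg, n1_hgg))
  g2 <- setdiff(seq_len(n), g1)
  list(group1 = g1, group2 = g2,
       lgg_fractions = c(mean(grade[g1] == "LGG"), mean(grade[g2] == "LGG")))
}

#' Split-half replicability of the tumour frequency map
#'
#' Repeatedly assigns patients to two disjoint halves with deliberately
#' unbalanced grade mixes (Group 1's low-grade fraction is
#' `lgg_ratio_multiplier` times the cohort's, Group 2's the complement),
#' rebuilds both frequency maps end-to-end (build, smooth, mirror,
#' aggregate to left-hemisphere parcels) and correlates them across
#' parcels. Returns the first repeat's Pearson r and the 2.5/97.5
#' percentile interval over repeats.
#'
#' @param cohort a `lesion_cohort` (or list with `masks` and `grade`).
#' @param parc a [make_parcellation()].
#' @param n_repeats number of random splits (>= 2).
#' @param lgg_ratio_multiplier grade imbalance of Group 1 relative to the
#'   cohort (default 1.5, i.e. a 50% higher low-grade proportion).
#' @param fwhm_mm,wm_extension_mm pipeline parameters.
#' @param seed optional seed for the split assignment.
#' @return List with `r_point`, `ci` (length-2), `r_all`, and the per-split
#'   grade fractions of the first split.
#' @export
split_half_replicability <- function(cohort, parc, n_repeats = 100L,
                                     lgg_ratio_multiplier = 1.5,
                                     fwhm_mm = 2, wm_extension_mm = 4,
                                     seed = NULL) {
  if (n_repeats < 2L) stop("n_repeats must be >= 2")
  if (!is.null(seed)) set.seed(seed)
  half_map <- function(idx) {
    fm <- build_frequency_map(cohort$masks[idx])
    parcel_aggregate(mirror_map(smooth_map(fm, fwhm_mm)), parc,
                     scope = "left", wm_extension_mm = wm_extension_mm)
  }
  r_all <- numeric(n_repeats)
  first_split <- NULL
  for (i in seq_len(n_repeats)) {
    sp <- split_cohort(cohort$grade, lgg_ratio_multiplier)
    if (i == 1L) first_split <- sp
    v1 <- half_map(sp$group1)
    v2 <- half_map(sp$group2)
    ok <- !is.na(v1) & !is.na(v2)
    r_all[i] <- stats::cor(v1[ok], v2[ok])
  }
  list(r_point = r_all[1],
       ci = stats::quantile(r_all, c(0.025, 0.975), names = FALSE),
       r_all = r_all, lgg_fractions = first_split$lgg_fractions)
}

#' Tumour frequency summaries by canonical network
#'
#' Computes, per canonical network and per primary/association grouping,
#' the mean voxel frequency and the distribution of non-zero voxel values
#' (exported for raincloud-style plotting). Voxels are attributed to
#' networks through the (undilated) parcel labels. The primary grouping
#' covers visual and somatomotor cortex; the association grouping covers
#' the dorsal/ventral attention, frontoparietal and default networks; the
#' limbic network belongs to neither.
#'
#' @param map a frequency [volume_map()].
#' @param parc a [make_parcellation()].
#' @return List with `by_network` and `by_class` data frames (network /
#'   class, mean_percent, n_voxels) and `nonzero_values` (named list of
#'   non-zero voxel values per network).
#' @export
network_summaries <- function(map, parc) {
  if (!identical(dim(map$values), dim(parc$labels)))
    stop("geometry error: map and parcellation grids differ")
  known <- c("visual", "somatomotor", "dorsal_attention", "ventral_attention",
             "limbic", "frontoparietal", "default")
  if (!all(parc$table$network %in% known))
    stop("labelling error: unknown network label in parcel table")
  lab <- parc$labels
  net_of_vox <- parc$table$network[match(lab[lab > 0L], parc$table$parcel_id)]
  vals <- map$values[lab > 0L]
  by_network <- data.frame(
    network = known,
    mean_percent = as.numeric(tapply(vals, factor(net_of_vox, known), mean)),
    n_voxels = as.integer(table(factor(net_of_vox, known))))
  cls <- ifelse(net_of_vox %in% c("visual", "somatomotor"), "primary",
                ifelse(net_of_vox == "limbic", NA_character_, "association"))
  keep <- !is.na(cls)
  by_class <- data.frame(
    class = c("primary", "association"),
    mean_percent = as.numeric(tapply(vals[keep],
                                     factor(cls[keep],
                                            c("primary", "association")),
                                     mean)),
    n_voxels = as.integer(table(factor(cls[keep],
                                       c("primary", "association")))))
  nz <- split(vals[vals > 0], factor(net_of_vox[vals > 0], known))
  list(by_network = by_network, by_class = by_class, nonzero_values = nz)
}
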