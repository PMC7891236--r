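#' Align expression samples to the tumour frequency map
#'
#' Takes the raw (unsmoothed, unmirrored) tumour frequency map, applies the
#' same smoothing and left-mirroring as the main map pipeline, reflects
#' right-hemisphere sample locations to their homotopic left-hemisphere
#' coordinates, and reads off the per-sample response
#' `y = sqrt(frequency at the sample's voxel)` (square root to reduce the
#' skew of the frequency distribution). Gene expression is z-scored per
#' gene; zero-variance genes are dropped with a message, as are samples
#' falling outside the grid.
#'
#' @param atlas a [make_expression_atlas()].
#' @param raw_map the raw frequency [volume_map()].
#' @param parc optional [make_parcellation()] for nearest-parcel sample
#'   assignment (used by loading maps).
#' @param fwhm_mm smoothing kernel (default 2 mm).
#' @return An `aligned_dataset`: `X` (samples x genes, z-scored), `y`,
#'   `sample_coords`, `sample_parcel`.
#' @export
align_samples_to_frequency <- function(atlas, raw_map, parc = NULL,
                                       fwhm_mm = 2) {
  map <- mirror_map(smooth_map(raw_map, fwhm_mm), to = "left")
  d <- dim(map$values)
  vox <- map$voxel_size_mm
  co <- as.matrix(atlas$coords[, c("x", "y", "z")])
  lims <- d * vox
  inside <- co[, 1] >= 0 & co[, 1] <= lims[1] &
    co[, 2] >= 0 & co[, 2] <= lims[2] & co[, 3] >= 0 & co[, 3] <= lims[3]
  if (!all(inside))
    message(sprintf("dropping %d samples outside the brain grid",
                    sum(!inside)))
  co <- co[inside, , drop = FALSE]
  mid <- lims[1] / 2
  right <- co[, 1] > mid
  co[right, 1] <- lims[1] - co[right, 1]  # reflect to homotopic position
  vi <- cbind(mm_to_voxel(co[, 1], d[1], vox[1]),
              mm_to_voxel(co[, 2], d[2], vox[2]),
              mm_to_voxel(co[, 3], d[3], vox[3]))
  y <- sqrt(map$values[vi])
  x <- atlas$expr[inside, , drop = FALSE]
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0))
    message(sprintf("dropping %d zero-variance genes", sum(sds == 0)))
  x <- scale(x[, sds > 0, drop = FALSE])
  attr(x, "scaled:center") <- attr(x, "scaled:scale") <- NULL
  sp <- atlas$sample_parcel[inside]
  if (is.null(sp) && !is.null(parc)) sp <- nearest_parcel_assignment(co, parc)
  structure(list(X = x, y = as.numeric(y),
                 sample_coords = co, sample_parcel = sp),
            class = "aligned_dataset")
}

## single-response NIPALS PLS with X deflation; returns unit-norm weight
## vectors, orthogonal scores, and per-component y-variance increments
pls1_core <- function(x, y, n_components) {
  n <- nrow(x); p <- ncol(x)
  yc <- y - mean(y)
  ssy <- sum(yc^2)
  if (ssy == 0) stop("degenerate error: constant response")
  w <- matrix(0, p, n_components)
  tt <- matrix(0, n, n_components)
  q <- numeric(n_components)
  varexp <- numeric(n_components)
  xd <- x
  for (k in seq_len(n_components)) {
    wk <- crossprod(xd, yc)
    nw <- sqrt(sum(wk^2))
    if (nw < 1e-12) {
      n_components <- k - 1L
      break
    }
    wk <- wk / nw
    tk <- xd %*% wk
    t2 <- sum(tk^2)
    pk <- crossprod(xd, tk) / t2
    qk <- sum(yc * tk) / t2
    xd <- xd - tk %*% t(pk)
    yc <- yc - qk * tk
    w[, k] <- wk
    tt[, k] <- tk
    q[k] <- qk
    varexp[k] <- qk^2 * t2 / ssy
  }
  list(weights = w[, seq_len(n_components), drop = FALSE],
       scores = tt[, seq_len(n_components), drop = FALSE],
       y_loadings = q[seq_len(n_components)],
       variance_explained_y = varexp[seq_len(n_components)],
       n_components = n_components)
}

#' Fit a PLS regression of tumour frequency on gene expression
#'
#' Successive components maximize the covariance between linear
#' combinations of the gene expression matrix and the response (deflated
#' NIPALS, single response). Reported `variance_explained_y` are deflated
#' per-component increments of response variance; `scree` carries the
#' increments of additional components to support the choice of stopping
#' at two.
#'
#' @param d an [align_samples_to_frequency()] dataset.
#' @param n_components components to retain (default 2).
#' @param n_scree extra components computed for the scree only.
#' @return A `pls_fit`: `weights` (genes x components, unit norm),
#'   `scores` (sample scores, the per-sample "loadings" used for
#'   visualization), `y_loadings`, `variance_explained_y`, `scree`,
#'   `n_components`, `gene_ids`.
#' @export
fit_pls <- function(d, n_components = 2L, n_scree = 3L) {
  if (nrow(d$X) < n_components + 1L)
    stop("need more samples than components")
  if (all(d$X == 0)) stop("degenerate error: all-zero predictor matrix")
  full <- pls1_core(d$X, d$y, n_components + n_scree)
  keep <- seq_len(min(n_components, full$n_components))
  structure(list(weights = full$weights[, keep, drop = FALSE],
                 scores = full$scores[, keep, drop = FALSE],
                 y_loadings = full$y_loadings[keep],
                 variance_explained_y = full$variance_explained_y[keep],
                 scree = full$variance_explained_y,
                 n_components = length(keep),
                 gene_ids = colnames(d$X)),
            class = "pls_fit")
}

#' @export
print.pls_fit <- function(x, ...) {
  cat(sprintf("<pls_fit> %d components; y-variance explained: %s\n",
              x$n_components,
              paste(sprintf("%.1f%%", 100 * x$variance_explained_y),
                    collapse = ", ")))
  invisible(x)
}

#' Permutation significance of the PLS model
#'
#' The statistic is the total response variance explained by the retained
#' components; the null refits the model after randomly shuffling the
#' sample labels linking expression to the response.
#'
#' @param d an [align_samples_to_frequency()] dataset.
#' @param fit the observed [fit_pls()].
#' @param n_perm permutations (default 1000).
#' @param seed optional seed.
#' @return List with `p`, `observed`, `null`.
#' @export
permute_pls_significance <- function(d, fit, n_perm = 1000L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  obs <- sum(fit$variance_explained_y)
  k <- fit$n_components
  null <- vapply(seq_len(n_perm), function(i) {
    yp <- d$y[sample.int(length(d$y))]
    sum(pls1_core(d$X, yp, k)$variance_explained_y)
  }, numeric(1))
  list(p = (1 + sum(null >= obs)) / (1 + n_perm), observed = obs, null = null)
}

#' Bootstrap z-statistics and gene rankings for PLS weights
#'
#' Resamples samples with replacement, refits the PLS, aligns each
#' bootstrap component's sign to the original fit (sign of the
#' weight-vector dot product), and returns `z = original weight /
#' bootstrap SD of the weight` per gene and component. Genes are ranked in
#' descending z (rank 1 = strongest positive weight); ties break by gene
#' id. Draws in which a component collapses (zero cross-covariance) are
#' redrawn and counted.
#'
#' @param d an [align_samples_to_frequency()] dataset.
#' @param n_boot bootstrap iterations (default 1000).
#' @param seed optional seed.
#' @param n_components components (default 2).
#' @return A `gene_ranking` data frame: `gene_id`, `z_pls1`, `z_pls2`,
#'   `rank1`, `rank2`; attribute `n_redrawn`.
#' @export
bootstrap_gene_z <- function(d, n_boot = 1000L, seed = NULL,
                             n_components = 2L) {
  if (!is.null(seed)) set.seed(seed)
  orig <- pls1_core(d$X, d$y, n_components)
  if (orig$n_components < n_components)
    stop("degenerate error: original fit has fewer components than requested")
  p <- ncol(d$X)
  n <- nrow(d$X)
  acc <- array(0, c(p, n_components, 2L))  # sums and sums of squares
  redrawn <- 0L
  b <- 0L
  while (b < n_boot) {
    idx <- sample.int(n, n, replace = TRUE)
    fb <- tryCatch(pls1_core(d$X[idx, , drop = FALSE], d$y[idx],
                             n_components),
                   error = function(e) NULL)
    if (is.null(fb) || fb$n_components < n_components) {
      redrawn <- redrawn + 1L
      if (redrawn > 10L * n_boot) stop("too many collapsed bootstrap draws")
      next
    }
    s <- sign(colSums(fb$weights * orig$weights))
    s[s == 0] <- 1
    wb <- sweep(fb$weights, 2L, s, `*`)
    acc[, , 1] <- acc[, , 1] + wb
    acc[, , 2] <- acc[, , 2] + wb^2
    b <- b + 1L
  }
  sd_b <- sqrt(pmax(0, acc[, , 2] / n_boot - (acc[, , 1] / n_boot)^2) *
                 n_boot / (n_boot - 1))
  z <- orig$weights / sd_b
  z[!is.finite(z)] <- 0
  ids <- colnames(d$X)
  rank_of <- function(zz) {
    ord <- order(-zz, ids)
    r <- integer(p); r[ord] <- seq_len(p); r
  }
  out <- data.frame(gene_id = ids, z_pls1 = z[, 1],
                    z_pls2 = if (n_components >= 2L) z[, 2] else NA_real_,
                    rank1 = rank_of(z[, 1]),
                    rank2 = if (n_components >= 2L) rank_of(z[, 2]) else
                      NA_integer_,
                    row.names = NULL)
  attr(out, "n_redrawn") <- redrawn
  class(out) <- c("gene_ranking", "data.frame")
  out
}

#' Median-rank enrichment of a gene set in a PLS ranking
#'
#' The statistic is the median rank of the set's genes in the chosen
#' component's ranking (small ranks = enriched at the top); the null is the
#' median rank of random same-size gene sets, so
#' `p = (1 + #\{null <= observed\}) / (1 + n_null)`.
#'
#' @param r a [bootstrap_gene_z()] ranking.
#' @param set a [gene_set()] or character vector (typically pre-filtered
#'   via [filter_gene_set()]).
#' @param component 1 or 2.
#' @param n_null random sets (default 10000).
#' @param seed optional seed.
#' @param exhaustive if `TRUE`, enumerate all same-size subsets (toy sizes
#'   only).
#' @return List with `median_rank`, `p`, `null`, `n_genes`.
#' @export
rank_enrichment_test <- function(r, set, component = 1L, n_null = 10000L,
                                 seed = NULL, exhaustive = FALSE) {
  ids <- if (is.character(set)) set else set$gene_ids
  found <- ids %in% r$gene_id
  if (!all(found))
    message(sprintf("dropping %d set genes absent from ranking", sum(!found)))
  ids <- ids[found]
  if (length(ids) == 0L) stop("no set genes present in the ranking")
  ranks <- if (component == 1L) r$rank1 else r$rank2
  obs <- stats::median(ranks[match(ids, r$gene_id)])
  k <- length(ids)
  if (exhaustive) {
    sets <- utils::combn(length(ranks), k)
    null <- apply(sets, 2L, function(i) stats::median(ranks[i]))
  } else {
    if (!is.null(seed)) set.seed(seed)
    null <- vapply(seq_len(n_null), function(i)
      stats::median(sample(ranks, k)), numeric(1))
  }
  list(median_rank = obs, p = (1 + sum(null <= obs)) / (1 + length(null)),
       null = null, n_genes = k)
}

#' Map per-sample PLS scores onto parcels
#'
#' Parcel loading = median sample score among samples assigned to the
#' parcel (nearest-parcel mapping); parcels receiving zero samples take
#' the mean sample score of the whole group. Reports per-parcel sample
#' counts with a cortical/subcortical summary.
#'
#' @param fit a [fit_pls()].
#' @param d the matching [align_samples_to_frequency()] dataset (must carry
#'   `sample_parcel`, or pass `parc` to derive it).
#' @param parc a [make_parcellation()].
#' @return List with `loadings` (parcels x components matrix over
#'   left-hemisphere parcels, rownames = parcel ids), `n_samples`
#'   (per-parcel counts), `empty_parcels`, `count_summary`.
#' @export
map_loadings_to_parcels <- function(fit, d, parc) {
  sp <- d$sample_parcel
  if (is.null(sp)) sp <- nearest_parcel_assignment(d$sample_coords, parc)
  tab <- parc$table
  left <- tab[tab$hemisphere == "L", ]
  ids <- left$parcel_id
  loadings <- matrix(NA_real_, length(ids), fit$n_components,
                     dimnames = list(ids, paste0("PLS", seq_len(fit$n_components))))
  counts <- integer(length(ids))
  for (k in seq_len(fit$n_components)) {
    med <- tapply(fit$scores[, k], sp, stats::median)
    loadings[, k] <- as.numeric(med[as.character(ids)])
  }
  counts <- as.integer(table(factor(sp, levels = ids)))
  empty <- ids[counts == 0L]
  for (k in seq_len(fit$n_components))
    loadings[counts == 0L, k] <- mean(fit$scores[, k])
  cs <- data.frame(
    class = c("cortical", "subcortical"),
    n_parcels = c(sum(left$is_cortical), sum(!left$is_cortical)),
    mean_samples = c(mean(counts[left$is_cortical]),
                     mean(counts[!left$is_cortical])),
    sd_samples = c(stats::sd(counts[left$is_cortical]),
                   stats::sd(counts[!left$is_cortical])))
  list(loadings = loadings, n_samples = stats::setNames(counts, ids),
       empty_parcels = empty, count_summary = cs)
}
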