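#' Gene set
#'
#' A named collection of gene identifiers (e.g. cell-type markers or
#' proto-oncogenes). Identifiers absent from an expression atlas are
#' reported and dropped at resolution time, never silently.
#'
#' @param name set name.
#' @param gene_ids character vector of unique identifiers.
#' @param note free-text provenance note.
#' @return A `gene_set` object.
#' @export
gene_set <- function(name, gene_ids, note = "") {
  gene_ids <- as.character(gene_ids)
  if (anyDuplicated(gene_ids)) stop("gene ids must be unique")
  structure(list(name = name, gene_ids = gene_ids, note = note),
            class = "gene_set")
}

resolve_gene_set <- function(set, atlas) {
  if (is.character(set)) set <- gene_set("adhoc", set)
  found <- set$gene_ids %in% colnames(atlas$expr)
  if (!all(found))
    message(sprintf("dropping %d unresolvable ids from '%s'",
                    sum(!found), set$name))
  set$gene_ids <- set$gene_ids[found]
  set
}

#' Tumour frequency in neural-stem-cell niche parcels vs random parcel pairs
#'
#' Compares the mean parcel frequency over the two niche parcels (defaults
#' to the parcellation's designated hippocampus and caudate stand-ins) with
#' the mean frequency of random parcel pairs drawn from the whole
#' parcellation (distinct within a pair; pairs may repeat across draws and
#' may include the niche parcels).
#'
#' @param freq parcel frequency vector named by parcel id (any scope that
#'   covers the niche parcels).
#' @param niche_parcels pair of parcel ids; defaults to `parc$niche`.
#' @param parc optional [make_parcellation()] supplying the default niche.
#' @param n_null number of random pairs (default 10000).
#' @param seed optional seed.
#' @param exhaustive if `TRUE`, enumerate every unordered parcel pair
#'   instead of sampling (exact null).
#' @return List with `mean_freq`, `p`, `null`, `n_null`.
#' @export
nsc_niche_test <- function(freq, niche_parcels = NULL, parc = NULL,
                           n_null = 10000L, seed = NULL, exhaustive = FALSE) {
  if (is.null(niche_parcels)) {
    if (is.null(parc)) stop("supply niche_parcels or parc")
    niche_parcels <- parc$niche
  }
  if (is.null(names(freq))) stop("freq must be named by parcel id")
  key <- as.character(niche_parcels)
  if (!all(key %in% names(freq)))
    stop("lookup error: unknown niche parcel ids")
  obs <- mean(freq[key])
  v <- as.numeric(freq)
  n <- length(v)
  if (exhaustive) {
    prs <- utils::combn(n, 2L)
    null <- (v[prs[1, ]] + v[prs[2, ]]) / 2
  } else {
    if (!is.null(seed)) set.seed(seed)
    i <- sample.int(n, n_null, replace = TRUE)
    j <- sample.int(n - 1L, n_null, replace = TRUE)
    j <- ifelse(j >= i, j + 1L, j)  # distinct within a pair
    null <- (v[i] + v[j]) / 2
  }
  list(mean_freq = obs, p = (1 + sum(null >= obs)) / (1 + length(null)),
       null = null, n_null = length(null))
}

set_coexpression_stat <- function(gene_ids, atlas) {
  e <- atlas$expr[, gene_ids, drop = FALSE]
  cm <- stats::cor(e)
  mean(cm[upper.tri(cm)])
}

#' Spatial co-expression specificity of a gene set
#'
#' Tests whether the genes of a set are more mutually co-expressed across
#' sample locations than random same-size gene sets: the statistic is the
#' mean pairwise Pearson correlation among the set's spatial expression
#' profiles, and the null draws random sets of the same size from the
#' atlas.
#'
#' @param set a [gene_set()] or character vector of ids.
#' @param atlas a [make_expression_atlas()].
#' @param n_null random sets (default 1000; the figure-style 10000 variant
#'   is a parameter away).
#' @param seed optional seed.
#' @return List with `statistic`, `p`, `null`, `n_genes`.
#' @export
coexpression_specificity <- function(set, atlas, n_null = 1000L, seed = NULL) {
  set <- resolve_gene_set(set, atlas)
  ids <- set$gene_ids
  sds <- apply(atlas$expr[, ids, drop = FALSE], 2, stats::sd)
  if (any(sds == 0)) {
    message(sprintf("excluding %d zero-variance genes", sum(sds == 0)))
    ids <- ids[sds > 0]
  }
  if (length(ids) < 2L) stop("set size must be >= 2 after exclusions")
  obs <- set_coexpression_stat(ids, atlas)
  if (!is.null(seed)) set.seed(seed)
  pool <- colnames(atlas$expr)
  null <- vapply(seq_len(n_null), function(k)
    set_coexpression_stat(sample(pool, length(ids)), atlas), numeric(1))
  list(statistic = obs, p = (1 + sum(null >= obs)) / (1 + n_null),
       null = null, n_genes = length(ids))
}

#' Filter genes with discordant co-expression from a set
#'
#' Single pass: every gene whose mean Pearson correlation with the other
#' set members (across sample locations) is non-positive is removed.
#' Removals are recorded in the `removed` attribute.
#'
#' @param set a [gene_set()] or character vector.
#' @param atlas a [make_expression_atlas()].
#' @return The filtered `gene_set` (attribute `removed` lists exclusions).
#' @export
filter_gene_set <- function(set, atlas) {
  set <- resolve_gene_set(set, atlas)
  ids <- set$gene_ids
  if (length(ids) < 2L) stop("set size must be >= 2")
  cm <- stats::cor(atlas$expr[, ids, drop = FALSE])
  diag(cm) <- NA
  mean_cor <- rowMeans(cm, na.rm = TRUE)
  removed <- ids[mean_cor <= 0]
  keep <- setdiff(ids, removed)
  if (length(keep) == 0L) stop("empty-set error: all genes removed")
  out <- gene_set(set$name, keep, set$note)
  attr(out, "removed") <- removed
  out
}

#' Regional marker-enrichment score map
#'
#' Scores each sample as the median z-scored expression of the gene set,
#' then aggregates sample scores to parcels (median over the samples
#' assigned to each parcel by nearest-parcel mapping). Only cortical
#' parcels are scored; parcels without samples are `NA` and excluded from
#' downstream correlations.
#'
#' @param set a (filtered) [gene_set()] or character vector.
#' @param atlas a [make_expression_atlas()].
#' @param parc a [make_parcellation()].
#' @return An `enrichment_result`: `score_map` (named vector over
#'   left-hemisphere cortical parcels), `sample_score`, `removed_genes`.
#' @export
marker_score_map <- function(set, atlas, parc) {
  set <- resolve_gene_set(set, atlas)
  e <- atlas$expr[, set$gene_ids, drop = FALSE]
  sds <- apply(e, 2, stats::sd)
  z <- scale(e[, sds > 0, drop = FALSE])
  ## a set of constant genes carries no spatial signal: score 0 everywhere
  sample_score <- if (ncol(z) == 0L) rep(0, nrow(e)) else
    apply(z, 1, stats::median)
  sp <- atlas$sample_parcel
  if (is.null(sp))
    sp <- nearest_parcel_assignment(as.matrix(atlas$coords[, c("x", "y", "z")]),
                                    parc)
  tab <- parc$table
  cort_left <- tab$parcel_id[tab$hemisphere == "L" & tab$is_cortical]
  med <- tapply(sample_score, sp, stats::median)
  score_map <- as.numeric(med[as.character(cort_left)])
  names(score_map) <- cort_left
  structure(list(score_map = score_map, sample_score = sample_score,
                 removed_genes = attr(set, "removed") %||% character(0)),
            class = "enrichment_result")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
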