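#' Build the parcellated weighted functional connectome
#'
#' Correlates per-parcel component-loading vectors (analogous to mean
#' regional time series) between parcels to obtain edge weights; negative
#' correlations and the diagonal are set to zero. When voxel-level loadings
#' are supplied they are first averaged within each parcel. Community
#' affiliation of each node is its parcel's canonical network.
#'
#' @param loadings numeric matrix of loading vectors: either one row per
#'   parcel (rownames = parcel ids, optional) or one row per voxel with
#'   `voxel_parcel` giving each row's parcel id.
#' @param parc a [make_parcellation()].
#' @param voxel_parcel optional integer vector (one per loading row) for
#'   voxel-level input.
#' @return A `connectome`: `weights` (symmetric non-negative matrix, zero
#'   diagonal), `parcel_ids`, `community`.
#' @export
build_parcel_connectome <- function(loadings, parc, voxel_parcel = NULL) {
  if (ncol(loadings) < 2L) stop("dimension error: need >= 2 components")
  ids <- parc$table$parcel_id
  if (!is.null(voxel_parcel)) {
    if (length(voxel_parcel) != nrow(loadings))
      stop("voxel_parcel length must match loading rows")
    got <- ids %in% voxel_parcel
    if (!all(got))
      stop("missing node error: parcels without voxels: ",
           paste(ids[!got], collapse = ", "))
    loadings <- do.call(rbind, lapply(ids, function(i)
      colMeans(loadings[voxel_parcel == i, , drop = FALSE])))
  }
  if (nrow(loadings) != length(ids))
    stop("missing node error: one loading row per parcel required")
  w <- stats::cor(t(loadings))
  w[w < 0] <- 0
  diag(w) <- 0
  w <- (w + t(w)) / 2
  dimnames(w) <- list(ids, ids)
  structure(list(weights = w, parcel_ids = ids,
                 community = parc$table$network),
            class = "connectome")
}

#' Weighted hub metrics per node
#'
#' Computes the standard weighted hubness metrics on a connectome:
#' nodal strength (row sums), betweenness centrality on edge lengths
#' `1/weight` normalized by `(n-1)(n-2)` (fraction of shortest paths through
#' the node, co-minimal paths counted fractionally), participation
#' coefficient `P_i = 1 - sum_m (kappa_im / k_i)^2` over community modules,
#' within-module strength z-score, weighted clustering coefficient
#' (geometric-mean triangle form on max-normalized weights), nodal
#' efficiency (mean inverse shortest-path length to all other nodes) and
#' eigenvector centrality. Isolated nodes get strength, betweenness and
#' participation 0.
#'
#' @param c a [build_parcel_connectome()] connectome.
#' @return A `hub_table` data frame with one row per node and columns
#'   `parcel_id`, `strength`, `betweenness`, `participation`,
#'   `within_module_z`, `clustering`, `local_efficiency`, `eigenvector`;
#'   the `screened_out` attribute starts empty.
#' @export
hub_metrics <- function(c) {
  w <- c$weights
  n <- nrow(w)
  strength <- rowSums(w)
  g <- igraph::graph_from_adjacency_matrix(w, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  len <- 1 / igraph::E(g)$weight
  btw <- igraph::betweenness(g, weights = len, directed = FALSE)
  betweenness <- if (n > 2L) 2 * btw / ((n - 1) * (n - 2)) else rep(0, n)
  comm <- factor(c$community)
  kappa <- t(rowsum(t(w), comm))          # node x module strength
  participation <- ifelse(strength > 0,
                          1 - rowSums((kappa / pmax(strength, .Machine$double.eps))^2),
                          0)
  own <- kappa[cbind(seq_len(n), match(c$community, levels(comm)))]
  wmz <- numeric(n)
  for (m in levels(comm)) {
    i <- which(c$community == m)
    mu <- mean(own[i]); s <- stats::sd(own[i])
    wmz[i] <- if (is.na(s) || s == 0) 0 else (own[i] - mu) / s
  }
  wmax <- max(w)
  wh <- if (wmax > 0) (w / wmax)^(1 / 3) else w
  tri <- diag(wh %*% wh %*% wh)
  deg <- rowSums(w > 0)
  clustering <- ifelse(deg > 1, tri / (deg * (deg - 1)), 0)
  dmat <- igraph::distances(g, weights = len)
  inv <- 1 / dmat
  diag(inv) <- 0
  local_efficiency <- rowSums(inv) / (n - 1)
  eigenvector <- if (sum(w) > 0)
    igraph::eigen_centrality(g, weights = igraph::E(g)$weight)$vector
  else rep(0, n)
  out <- data.frame(parcel_id = c$parcel_ids, strength = strength,
                    betweenness = betweenness, participation = participation,
                    within_module_z = wmz, clustering = clustering,
                    local_efficiency = local_efficiency,
                    eigenvector = eigenvector, row.names = NULL)
  attr(out, "screened_out") <- character(0)
  class(out) <- c("hub_table", "data.frame")
  out
}

hub_metric_names <- function(h)
  setdiff(names(h), c("parcel_id"))

#' Average hub metrics over homotopic parcel pairs
#'
#' @param h a [hub_metrics()] table on the bilateral parcel set.
#' @param parc a [make_parcellation()].
#' @return A `hub_table` with one row per left-hemisphere parcel, each
#'   metric averaged over the homotopic pair.
#' @export
homotopic_average <- function(h, parc) {
  tab <- parc$table
  left <- tab[tab$hemisphere == "L", ]
  il <- match(left$parcel_id, h$parcel_id)
  ir <- match(left$homotopic_id, h$parcel_id)
  if (anyNA(il) || anyNA(ir)) stop("pairing error: unpaired parcel")
  out <- h[il, , drop = FALSE]
  for (m in hub_metric_names(h)) out[[m]] <- (h[[m]][il] + h[[m]][ir]) / 2
  out$parcel_id <- left$parcel_id
  rownames(out) <- NULL
  attr(out, "screened_out") <- attr(h, "screened_out")
  class(out) <- c("hub_table", "data.frame")
  out
}

#' Screen hub metrics redundant with nodal strength
#'
#' Removes every metric whose absolute Spearman correlation with nodal
#' strength exceeds `threshold` (strength itself is always retained) and
#' reports, for a grid of thresholds, which metrics each would remove, to
#' document the stability of the screen.
#'
#' @param h a [hub_metrics()] (or [homotopic_average()]) table.
#' @param threshold Spearman cut-off (default 0.95).
#' @param stability_grid thresholds for the stability report.
#' @return The screened `hub_table`; attributes `screened_out` (removed
#'   metric names) and `screening_stability` (data frame threshold x
#'   removed-metric list).
#' @export
screen_redundant_metrics <- function(h, threshold = 0.95,
                                     stability_grid = seq(0.65, 0.99, by = 0.02)) {
  metrics <- setdiff(hub_metric_names(h), "strength")
  rho <- vapply(metrics, function(m) {
    if (stats::sd(h[[m]]) == 0) return(0)
    abs(spearman(h[[m]], h$strength))
  }, numeric(1))
  removed <- metrics[rho > threshold]
  stab <- data.frame(threshold = stability_grid,
                     removed = vapply(stability_grid, function(t)
                       paste(sort(metrics[rho > t]), collapse = ","),
                       character(1)))
  out <- h[, !(names(h) %in% removed), drop = FALSE]
  attr(out, "screened_out") <- removed
  attr(out, "screening_rho") <- rho
  attr(out, "screening_stability") <- stab
  class(out) <- c("hub_table", "data.frame")
  out
}

#' Spin tests of hub-metric vs tumour-frequency association
#'
#' Runs one [spin_correlation_test()] per surviving hub metric against the
#' parcel-wise tumour frequency map.
#'
#' @param h a screened `hub_table` on the ensemble's scope.
#' @param freq parcel frequency vector on the same scope.
#' @param ens a [build_spin_ensemble()].
#' @param ... passed to [spin_correlation_test()].
#' @return Named list of `spin_test_result`, one per metric.
#' @export
hub_frequency_association <- function(h, freq, ens, ...) {
  metrics <- hub_metric_names(h)
  res <- lapply(metrics, function(m) {
    x <- h[[m]]
    names(x) <- h$parcel_id
    spin_correlation_test(x, freq, ens, ...)
  })
  names(res) <- metrics
  res
}
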