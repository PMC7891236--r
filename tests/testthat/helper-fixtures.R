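# shared toy configurations and independent oracles used across test files

tiny_cfg <- function(seed = 1L, ...) {
  args <- list(...)
  defaults <- list(seed = seed, grid_shape = c(16L, 18L, 16L),
                   n_parcels_per_hemisphere = 12L, n_subcortical = 2L,
                   n_patients = 40L, n_genes = 120L, n_samples = 80L,
                   n_components = 80L, smoothness_mm = 8)
  do.call(synthetic_config, utils::modifyList(defaults, args))
}

small_cfg <- function(seed = 1L, ...) {
  args <- list(...)
  defaults <- list(seed = seed, grid_shape = c(24L, 28L, 24L),
                   n_parcels_per_hemisphere = 40L, n_subcortical = 4L,
                   n_patients = 150L, n_genes = 400L, n_samples = 160L,
                   n_components = 300L)
  do.call(synthetic_config, utils::modifyList(defaults, args))
}

# memoized default-scale parcellation (geometry is seed-independent)
default_parc <- local({
  parc <- NULL
  function() {
    if (is.null(parc)) parc <<- make_parcellation(synthetic_config())
    parc
  }
})

# flood fill: number of 6-connected components among voxels with one label
count_components <- function(labels, id) {
  idx <- which(labels == id)
  if (length(idx) == 0L) return(0L)
  d <- dim(labels)
  co <- arrayInd(idx, d)
  key <- function(m) (m[, 1] - 1) + d[1] * ((m[, 2] - 1) + d[2] * (m[, 3] - 1))
  remaining <- new.env(hash = TRUE)
  for (k in key(co)) assign(as.character(k), TRUE, envir = remaining)
  offs <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  comps <- 0L
  while (length(ls(remaining)) > 0L) {
    comps <- comps + 1L
    seed_key <- ls(remaining)[1]
    rm(list = seed_key, envir = remaining)
    queue <- matrix(co[match(as.numeric(seed_key), key(co)), ], 1)
    while (nrow(queue) > 0L) {
      v <- queue[1, ]; queue <- queue[-1, , drop = FALSE]
      nb <- sweep(offs, 2, v, `+`)
      ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 & nb[, 2] <= d[2] &
        nb[, 3] >= 1 & nb[, 3] <= d[3]
      nb <- nb[ok, , drop = FALSE]
      kk <- as.character(key(nb))
      hit <- vapply(kk, exists, logical(1), envir = remaining,
                    inherits = FALSE)
      if (any(hit)) {
        rm(list = kk[hit], envir = remaining)
        queue <- rbind(queue, nb[hit, , drop = FALSE])
      }
    }
  }
  comps
}

# brute-force betweenness by exhaustive simple-path enumeration:
# for every ordered pair, enumerate all simple paths, find minimal length
# (sum of 1/weight), and credit interior nodes of co-minimal paths
# fractionally; normalized by (n-1)(n-2)
oracle_betweenness <- function(w) {
  n <- nrow(w)
  credit <- numeric(n)
  for (s in seq_len(n)) for (t in seq_len(n)) {
    if (s == t) next
    paths <- list()
    lens <- numeric(0)
    walk <- function(v, visited, len) {
      if (v == t) {
        paths[[length(paths) + 1L]] <<- visited
        lens[length(lens) + 1L] <<- len
        return(invisible(NULL))
      }
      for (u in seq_len(n)) {
        if (w[v, u] > 0 && !(u %in% visited))
          walk(u, c(visited, u), len + 1 / w[v, u])
      }
    }
    walk(s, s, 0)
    if (length(lens) == 0L) next
    dmin <- min(lens)
    minimal <- paths[abs(lens - dmin) < 1e-10]
    for (v in setdiff(seq_len(n), c(s, t))) {
      through <- sum(vapply(minimal, function(p) v %in% p, logical(1)))
      credit[v] <- credit[v] + through / length(minimal)
    }
  }
  credit / ((n - 1) * (n - 2))
}

# direct-formula participation coefficient and within-module z
oracle_participation <- function(w, community) {
  n <- nrow(w)
  k <- rowSums(w)
  vapply(seq_len(n), function(i) {
    if (k[i] == 0) return(0)
    1 - sum(vapply(unique(community), function(m)
      (sum(w[i, community == m]) / k[i])^2, numeric(1)))
  }, numeric(1))
}

oracle_within_module_z <- function(w, community) {
  n <- nrow(w)
  own <- vapply(seq_len(n), function(i) sum(w[i, community == community[i]]),
                numeric(1))
  out <- numeric(n)
  for (m in unique(community)) {
    i <- which(community == m)
    s <- stats::sd(own[i])
    out[i] <- if (is.na(s) || s == 0) 0 else (own[i] - mean(own[i])) / s
  }
  out
}

# independent Moran's I: literal double loop over the definition with
# inverse-distance row-normalized weights
oracle_morans_i <- function(x, coords) {
  n <- length(x)
  w <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) if (i != j)
    w[i, j] <- 1 / sqrt(sum((coords[i, ] - coords[j, ])^2))
  w <- w / rowSums(w)
  z <- x - mean(x)
  num <- 0
  for (i in seq_len(n)) for (j in seq_len(n))
    num <- num + w[i, j] * z[i] * z[j]
  (n / sum(w)) * num / sum(z^2)
}

random_weighted_graph <- function(n, p = 0.5, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  w <- matrix(0, n, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (stats::runif(1) < p) w[i, j] <- w[j, i] <- stats::runif(1, 0.1, 1)
  }
  w
}

fake_connectome <- function(w, community = rep("a", nrow(w))) {
  structure(list(weights = w, parcel_ids = seq_len(nrow(w)),
                 community = community), class = "connectome")
}

# 167-parcel design with planted standardized betas; sqrt() of the
# generated frequency recovers a unit-variance linear signal exactly
simulate_design <- function(n = 167, betas = c(0.2, 0.2, 0.2, 0.5),
                            seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  x <- matrix(rnorm(n * 4), n, 4)
  sigma <- sqrt(max(0, 1 - sum(betas^2)))
  v <- x %*% betas + sigma * rnorm(n)
  y_raw <- pmax(v + 6, 0)^2
  assemble_design(setNames(as.numeric(y_raw), seq_len(n)),
                  strength = x[, 1], opc = x[, 2],
                  pls1 = x[, 3], pls2 = x[, 4])
}
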