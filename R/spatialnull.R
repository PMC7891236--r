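## uniform random rotation in SO(3) via QR of a Gaussian matrix
random_rotation <- function() {
  qr_ <- qr(matrix(stats::rnorm(9), 3))
  q <- qr.Q(qr_)
  q <- q %*% diag(sign(diag(qr.R(qr_))))
  if (det(q) < 0) q[, 3] <- -q[, 3]
  q
}

#' Build a spin-test permutation ensemble
#'
#' Generates contiguity-preserving spatial permutations of a parcel set: for
#' each spin, one uniform random 3D rotation is applied jointly to the
#' unit-sphere centroids of all cortical parcels in scope and rotated
#' centroids are matched back to original centroids. The default is a
#' greedy one-to-one (bijective) nearest-first assignment, which conserves
#' the multiset of map values exactly; `bijective = FALSE` gives the
#' independent nearest-centroid variant, which may reuse donors.
#' Subcortical parcels, which
#' have no spherical embedding, are permuted uniformly at random among
#' themselves (set `subcortical = "exclude"` to keep them fixed out of
#' scope).
#'
#' @param parc a [make_parcellation()].
#' @param n_spins number of spins.
#' @param seed optional RNG seed.
#' @param scope `"left"` (default) or `"bilateral"` parcel set.
#' @param rotations optional list of 3x3 rotation matrices (test hook; an
#'   identity rotation yields the identity permutation).
#' @param bijective one-to-one greedy matching (default) or independent
#'   nearest-centroid lookup (`FALSE`).
#' @param subcortical `"permute"` (default) or `"exclude"`.
#' @return A `spin_ensemble`: `permutations` (n_spins x n_parcels index
#'   matrix mapping each parcel position to the donor parcel position),
#'   `parcel_ids`, `n_spins`, `scope`.
#' @export
build_spin_ensemble <- function(parc, n_spins = 1000L, seed = NULL,
                                scope = c("left", "bilateral", "left_cortical"),
                                rotations = NULL, bijective = TRUE,
                                subcortical = c("permute", "exclude")) {
  scope <- match.arg(scope)
  subcortical <- match.arg(subcortical)
  if (!is.null(seed)) set.seed(seed)
  tab <- parc$table
  if (scope %in% c("left", "left_cortical")) tab <- tab[tab$hemisphere == "L", ]
  if (scope == "left_cortical") tab <- tab[tab$is_cortical, ]
  ids <- tab$parcel_id
  cort <- which(tab$is_cortical)
  sub <- which(!tab$is_cortical)
  cc <- as.matrix(tab[cort, c("cx", "cy", "cz")])
  if (anyNA(cc)) stop("geometry error: cortical parcels lack sphere centroids")
  if (!is.null(rotations)) n_spins <- length(rotations)
  perm <- matrix(0L, n_spins, length(ids))
  for (k in seq_len(n_spins)) {
    r <- if (is.null(rotations)) random_rotation() else rotations[[k]]
    sim <- cc %*% t(cc %*% t(r))  # cos angle(original_i, rotated_j)
    if (!bijective) {
      perm[k, cort] <- cort[max.col(sim, ties.method = "first")]
    } else {
      perm[k, cort] <- cort[bijective_match(sim)]
    }
    perm[k, sub] <- if (subcortical == "permute" && length(sub) > 1L)
      sub[sample.int(length(sub))] else sub
  }
  structure(list(permutations = perm, parcel_ids = ids,
                 n_spins = n_spins, scope = scope),
            class = "spin_ensemble")
}

## one-to-one assignment maximizing total similarity: greedy nearest-first
## seeding followed by 2-opt pairwise-swap refinement to a local optimum,
## so the matched permutation stays close to the underlying rotation
bijective_match <- function(sim) {
  n <- nrow(sim)
  assigned <- integer(n)
  free <- rep(TRUE, n)
  for (i in order(-apply(sim, 1, max))) {
    j <- which.max(ifelse(free, sim[i, ], -Inf))
    assigned[i] <- j
    free[j] <- FALSE
  }
  sa <- sim[, assigned, drop = FALSE]  # sa[i, j] = sim[i, assigned[j]]
  own <- diag(sa)
  for (iter in seq_len(5L * n)) {
    gain <- sa + t(sa) - outer(own, own, `+`)
    best <- which.max(gain)
    if (gain[best] <= 1e-12) break
    i <- (best - 1L) %% n + 1L
    j <- (best - 1L) %/% n + 1L
    assigned[c(i, j)] <- assigned[c(j, i)]
    sa[, c(i, j)] <- sa[, c(j, i)]
    own[c(i, j)] <- c(sa[i, i], sa[j, j])
  }
  assigned
}

spearman <- function(x, y) stats::cor(rank(x), rank(y))

## align a named or unnamed parcel vector to the ensemble's parcel ids
align_to_ensemble <- function(x, ens) {
  if (!is.null(names(x))) {
    m <- match(as.character(ens$parcel_ids), names(x))
    if (anyNA(m)) stop("parcel ids of vector do not cover the ensemble scope")
    x <- x[m]
  } else if (length(x) != length(ens$parcel_ids)) {
    stop("vector length does not match the ensemble scope")
  }
  as.numeric(x)
}

#' Spin-based correlation test between two parcel maps
#'
#' Compares the observed Spearman correlation between two parcel maps with
#' a null distribution obtained by spatially permuting one map with a
#' [build_spin_ensemble()]. The default p-value is one-sided for a
#' prespecified positive association (the directional hypotheses this
#' pipeline tests), with the standard +1 correction, so
#' `p >= 1 / (n_spins + 1)`. `direction = "auto"` tests in the direction
#' of the observed sign — convenient for exploration but anti-conservative
#' by up to a factor of two, since the direction is chosen post hoc.
#'
#' @param x,y parcel vectors on the ensemble's scope (named by parcel id or
#'   ordered to match). `x` is the map that gets spun by default.
#' @param ens a [build_spin_ensemble()].
#' @param sidedness `"one"` (default) or `"two"`.
#' @param direction for one-sided tests: `"positive"` (default),
#'   `"negative"`, or `"auto"` (observed sign).
#' @param spin_target which input is spun, `"x"` (default) or `"y"`.
#' @return A `spin_test_result`: `rho_observed`, `null_rhos`, `p_spin`,
#'   `sidedness`, `direction`, `n_spins`.
#' @export
spin_correlation_test <- function(x, y, ens, sidedness = c("one", "two"),
                                  direction = c("positive", "negative", "auto"),
                                  spin_target = c("x", "y")) {
  sidedness <- match.arg(sidedness)
  direction <- match.arg(direction)
  spin_target <- match.arg(spin_target)
  x <- align_to_ensemble(x, ens)
  y <- align_to_ensemble(y, ens)
  ok <- !is.na(x) & !is.na(y)
  if (stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0)
    stop("undefined-correlation error: constant input vector")
  rho_obs <- spearman(x[ok], y[ok])
  spun <- if (spin_target == "x") x else y
  fixed <- if (spin_target == "x") y else x
  null_rhos <- apply(ens$permutations, 1L, function(p) {
    s <- spun[p]
    k <- !is.na(s) & !is.na(fixed)
    stats::cor(rank(s[k]), rank(fixed[k]))
  })
  p <- if (sidedness == "one") {
    dir <- switch(direction, positive = 1, negative = -1, auto = sign(rho_obs))
    if (dir >= 0) (1 + sum(null_rhos >= rho_obs)) / (1 + ens$n_spins)
    else (1 + sum(null_rhos <= rho_obs)) / (1 + ens$n_spins)
  } else {
    (1 + sum(abs(null_rhos) >= abs(rho_obs))) / (1 + ens$n_spins)
  }
  structure(list(rho_observed = rho_obs, null_rhos = null_rhos, p_spin = p,
                 sidedness = sidedness, direction = direction,
                 n_spins = ens$n_spins),
            class = "spin_test_result")
}

#' @export
print.spin_test_result <- function(x, ...) {
  cat(sprintf("<spin test> rho = %.3f, p_spin = %.4g (%s-sided, %d spins)\n",
              x$rho_observed, x$p_spin, x$sidedness, x$n_spins))
  invisible(x)
}

#' Moran's I spatial autocorrelation of a parcel map
#'
#' Computes Moran's I over an inverse-distance weight matrix on parcel
#' centroids (`w_ij = 1/d_ij`, `w_ii = 0`, rows normalized to sum 1), with
#' a permutation p-value (one-sided for positive autocorrelation). The
#' permutation-null expectation is `-1/(n-1)`. With `metric = "volume"`
#' distances are Euclidean between volumetric centroids; with
#' `metric = "sphere"` they are great-circle distances on the cortical
#' unit-sphere embedding (cortical parcels only) — the geometry the spin
#' null operates on.
#'
#' @param x parcel vector (length = left, bilateral, or — for the sphere
#'   metric — left-cortical parcel count; named vectors are matched by
#'   parcel id).
#' @param parc a [make_parcellation()].
#' @param n_perm permutations for the p-value.
#' @param seed optional seed.
#' @param metric `"volume"` (default) or `"sphere"`.
#' @return List with `I`, `p`, `expectation`, `n`.
#' @export
morans_i <- function(x, parc, n_perm = 1000L, seed = NULL,
                     metric = c("volume", "sphere")) {
  metric <- match.arg(metric)
  tab <- parc$table
  if (metric == "sphere") {
    tab <- tab[tab$is_cortical, ]
    nl <- sum(tab$hemisphere == "L")
    tab <- if (length(x) == nl) tab[tab$hemisphere == "L", ] else tab
  } else {
    n_left <- sum(tab$hemisphere == "L")
    tab <- if (length(x) == n_left) tab[tab$hemisphere == "L", ] else tab
  }
  if (length(x) != nrow(tab))
    stop("vector length does not match the parcel scope for this metric")
  if (!is.null(names(x))) x <- x[match(as.character(tab$parcel_id), names(x))]
  x <- as.numeric(x)
  if (stats::sd(x) == 0) stop("degenerate-variance error: constant map")
  if (!is.null(seed)) set.seed(seed)
  if (metric == "sphere") {
    cc <- as.matrix(tab[, c("cx", "cy", "cz")])
    d <- acos(pmax(pmin(cc %*% t(cc), 1), -1))
  } else {
    d <- as.matrix(stats::dist(as.matrix(tab[, c("vx", "vy", "vz")])))
  }
  w <- 1 / d
  diag(w) <- 0
  w[!is.finite(w)] <- 0
  w <- w / rowSums(w)
  n <- length(x)
  s0 <- sum(w)
  z <- x - mean(x)
  i_of <- function(zz) (n / s0) * sum(zz * (w %*% zz)) / sum(zz^2)
  i_obs <- i_of(z)
  p <- NA_real_
  if (n_perm > 0L) {
    zp <- vapply(seq_len(n_perm), function(k) {
      zz <- z[sample.int(n)]
      (n / s0) * sum(zz * (w %*% zz)) / sum(zz^2)
    }, numeric(1))
    p <- (1 + sum(zp >= i_obs)) / (1 + n_perm)
  }
  list(I = i_obs, p = p, expectation = -1 / (n - 1), n = n)
}
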