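#' Configuration for the synthetic-data generator
#'
#' Collects every parameter of the synthetic study: grid geometry,
#' parcellation size, cohort size and grade mix, spatial smoothness of the
#' ground-truth fields, expression-atlas dimensions, and the planted effect
#' sizes that downstream analyses are expected to recover. Identical
#' configurations (including the seed) produce bit-identical data.
#'
#' Defaults mirror the study conditions the pipeline is designed around:
#' 335 patients with a ~23% low-grade fraction, 167 parcels per hemisphere
#' of which 8 are subcortical, and moderate planted effects (0.5) for the
#' hub, OPC-marker and driver-gene associations.
#'
#' @param seed integer seed; all generator randomness flows from it.
#' @param grid_shape integer length-3 voxel counts (first axis is left-right
#'   and must be even so a midline exists).
#' @param voxel_size_mm voxel edge lengths in mm.
#' @param n_parcels_per_hemisphere,n_subcortical parcellation size.
#' @param n_patients,lgg_fraction cohort size and low-grade proportion.
#' @param smoothness_mm length-scale (mm) of the Gaussian-process ground
#'   truth fields; 0 gives spatially independent parcel noise.
#' @param n_genes,n_samples expression atlas dimensions.
#' @param effect_sizes named numeric in \[-1, 1\]: `hub` (tumour-hub field
#'   correlation), `opc` (marker profile vs target), `driver` (driver
#'   profile vs target).
#' @param n_components number of connectome loading components.
#' @param n_marker_genes,n_marker_decoys,n_driver_genes,n_driver_decoys
#'   planted gene-set sizes; decoys are anti-correlated members.
#' @param lesion_radius_meanlog,lesion_radius_sdlog log-normal lesion radius
#'   (mm); a free parameter of the generator, not an estimate of any cohort.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(seed = 1L,
                             grid_shape = c(40L, 44L, 40L),
                             voxel_size_mm = c(2, 2, 2),
                             n_parcels_per_hemisphere = 167L,
                             n_subcortical = 8L,
                             n_patients = 335L,
                             lgg_fraction = 0.23,
                             smoothness_mm = 12,
                             n_genes = 2000L,
                             n_samples = 600L,
                             effect_sizes = c(hub = 0.5, opc = 0.5, driver = 0.5),
                             n_components = 1200L,
                             n_marker_genes = 25L,
                             n_marker_decoys = 0L,
                             n_driver_genes = 17L,
                             n_driver_decoys = 3L,
                             lesion_radius_meanlog = log(8),
                             lesion_radius_sdlog = 0.4) {
  cfg <- list(seed = as.integer(seed), grid_shape = as.integer(grid_shape),
              voxel_size_mm = rep_len(as.numeric(voxel_size_mm), 3L),
              n_parcels_per_hemisphere = as.integer(n_parcels_per_hemisphere),
              n_subcortical = as.integer(n_subcortical),
              n_patients = as.integer(n_patients),
              lgg_fraction = lgg_fraction, smoothness_mm = smoothness_mm,
              n_genes = as.integer(n_genes), n_samples = as.integer(n_samples),
              effect_sizes = effect_sizes, n_components = as.integer(n_components),
              n_marker_genes = as.integer(n_marker_genes),
              n_marker_decoys = as.integer(n_marker_decoys),
              n_driver_genes = as.integer(n_driver_genes),
              n_driver_decoys = as.integer(n_driver_decoys),
              lesion_radius_meanlog = lesion_radius_meanlog,
              lesion_radius_sdlog = lesion_radius_sdlog)
  if (cfg$lgg_fraction < 0 || cfg$lgg_fraction > 1)
    stop("lgg_fraction must lie in [0, 1]")
  counts <- c(cfg$n_parcels_per_hemisphere, cfg$n_subcortical,
              cfg$n_genes, cfg$n_samples, cfg$n_components)
  if (any(counts < 1L)) stop("all counts must be >= 1")
  if (any(abs(cfg$effect_sizes) > 1)) stop("effect sizes must lie in [-1, 1]")
  for (nm in c("hub", "opc", "driver"))
    if (is.na(cfg$effect_sizes[nm])) stop("effect_sizes needs hub, opc, driver")
  class(cfg) <- "synthetic_config"
  cfg
}

## squared-exponential Gaussian-process draw over a set of mm coordinates
gp_draw <- function(coords_mm, length_scale_mm, n = 1L) {
  m <- nrow(coords_mm)
  if (length_scale_mm <= 0) return(matrix(stats::rnorm(m * n), m, n))
  d2 <- as.matrix(stats::dist(coords_mm))^2
  k <- exp(-d2 / (2 * length_scale_mm^2)) + diag(1e-6, m)
  t(chol(k)) %*% matrix(stats::rnorm(m * n), m, n)
}

#' Spatially autocorrelated parcel fields
#'
#' Draws smooth random fields on parcels from a Gaussian process with
#' squared-exponential covariance; each field is z-scored. With
#' `geometry = "volume"` the kernel acts on Euclidean distances between
#' volumetric centroids; with `geometry = "sphere"` it acts on great-circle
#' distances on the cortical unit-sphere embedding (the geometry cortical
#' surface maps live in, and the one the spin null preserves) — subcortical
#' parcels, which have no surface embedding, then receive i.i.d. noise.
#' With `length_scale_mm = 0` the fields are i.i.d. parcel noise.
#'
#' @param parc A [make_parcellation()] object.
#' @param length_scale_mm spatial length-scale in mm (for the sphere
#'   geometry it is divided by the hemisphere's mean centroid radius to
#'   give an angular scale).
#' @param n number of independent fields.
#' @param scope `"left"` (default), `"bilateral"` or `"left_cortical"`.
#' @param seed optional seed.
#' @param geometry `"volume"` (default) or `"sphere"`.
#' @return Matrix of `n_parcels x n` field values (parcel ids as rownames).
#' @export
make_parcel_field <- function(parc, length_scale_mm, n = 1L,
                              scope = c("left", "bilateral", "left_cortical"),
                              seed = NULL,
                              geometry = c("volume", "sphere")) {
  scope <- match.arg(scope)
  geometry <- match.arg(geometry)
  if (!is.null(seed)) set.seed(seed)
  tab <- parc$table
  if (scope %in% c("left", "left_cortical")) tab <- tab[tab$hemisphere == "L", ]
  if (scope == "left_cortical") tab <- tab[tab$is_cortical, ]
  if (geometry == "volume") {
    f <- gp_draw(as.matrix(tab[, c("vx", "vy", "vz")]), length_scale_mm, n)
  } else {
    f <- matrix(stats::rnorm(nrow(tab) * n), nrow(tab), n)
    cort <- which(tab$is_cortical)
    if (length_scale_mm > 0 && length(cort) > 1L) {
      cc <- as.matrix(tab[cort, c("cx", "cy", "cz")])
      ctr <- colMeans(as.matrix(tab[cort, c("vx", "vy", "vz")]))
      radius <- mean(sqrt(rowSums(
        sweep(as.matrix(tab[cort, c("vx", "vy", "vz")]), 2L, ctr)^2)))
      gc2 <- acos(pmax(pmin(cc %*% t(cc), 1), -1))^2
      k <- exp(-gc2 / (2 * (length_scale_mm / radius)^2)) +
        diag(1e-6, length(cort))
      f[cort, ] <- t(chol(k)) %*% matrix(stats::rnorm(length(cort) * n),
                                         length(cort), n)
    }
  }
  f <- scale(f)
  attr(f, "scaled:center") <- attr(f, "scaled:scale") <- NULL
  rownames(f) <- tab$parcel_id
  f
}

#' Ground-truth parcel fields with planted correlations
#'
#' Generates three spatially autocorrelated left-hemisphere parcel fields —
#' tumour-frequency truth, hub truth and cell (OPC) truth — with pairwise
#' planted correlations: `cor(tumour, hub) = effect_sizes["hub"]` and
#' `cor(tumour, cell) = effect_sizes["opc"]` (the implied hub-cell
#' correlation is their product). Fields are z-scored; monotone transforms
#' (e.g. `exp`) convert the tumour field into a non-negative placement law.
#'
#' @param cfg A [synthetic_config()].
#' @param parc A [make_parcellation()].
#' @return Named list of numeric vectors (`tumour`, `hub`, `cell`), one value
#'   per left-hemisphere parcel.
#' @export
make_ground_truth_fields <- function(cfg, parc) {
  set.seed(cfg$seed + 1L)
  f <- make_parcel_field(parc, cfg$smoothness_mm, n = 3L, scope = "left")
  tumour <- f[, 1]
  list(tumour = as.numeric(tumour),
       hub = mix_exact(tumour, f[, 2], cfg$effect_sizes[["hub"]]),
       cell = mix_exact(tumour, f[, 3], cfg$effect_sizes[["opc"]]))
}

## mix `other` into `base` at exactly the requested in-sample correlation:
## the nuisance component is first orthogonalized against `base`, so the
## planted effect size is not blurred by chance alignment of two smooth
## fields (which at realistic spatial smoothness has few effective degrees
## of freedom and large sampling spread)
mix_exact <- function(base, other, rho) {
  b <- as.numeric(scale(base))
  o <- other - b * sum(other * b) / sum(b^2)
  o <- as.numeric(scale(o))
  as.numeric(scale(rho * b + sqrt(1 - rho^2) * o))
}

## expand a left-hemisphere parcel vector to the bilateral parcel set by
## copying each value to its homotopic partner
mirror_parcel_vector <- function(x, parc) {
  tab <- parc$table
  left <- tab$parcel_id[tab$hemisphere == "L"]
  if (length(x) == nrow(tab)) return(x)
  stopifnot(length(x) == length(left))
  out <- numeric(nrow(tab))
  out[left] <- x
  out[tab$homotopic_id[left]] <- x
  out
}

#' Synthetic lesion cohort
#'
#' Draws `n_patients` spherical binary lesion masks. Each blob centre parcel
#' is sampled with probability proportional to `truth` (a non-negative
#' placement law per parcel; left-hemisphere vectors are mirrored
#' bilaterally), the centre voxel is uniform within the parcel, and the blob
#' radius is log-normal in mm. Grade labels are Bernoulli with
#' `P(LGG) = lgg_fraction`.
#'
#' @param cfg A [synthetic_config()].
#' @param parc A [make_parcellation()].
#' @param truth non-negative placement weights, one per parcel (left or
#'   bilateral length).
#' @return A `lesion_cohort`: `masks` (list of mask [volume_map()]s),
#'   `grade` (factor LGG/HGG), `centre_parcel`, `centre_mm`.
#' @export
make_lesion_cohort <- function(cfg, parc, truth) {
  if (any(truth < 0)) stop("truth must be non-negative")
  truth <- mirror_parcel_vector(truth, parc)
  if (all(truth == 0)) stop("degenerate-field error: all-zero placement law")
  set.seed(cfg$seed + 2L)
  n <- cfg$n_patients
  d <- dim(parc$labels)
  vox <- parc$voxel_size_mm
  masks <- vector("list", n)
  centre_parcel <- integer(n)
  centre_mm <- matrix(0, n, 3L)
  if (n > 0L) {
    idx_by_parcel <- split(which(parc$labels > 0L),
                           parc$labels[parc$labels > 0L])
    probs <- truth / sum(truth)
    ax <- lapply(1:3, function(a) axis_mm(d[a], vox[a]))
    for (i in seq_len(n)) {
      p <- sample.int(length(probs), 1L, prob = probs)
      vix <- idx_by_parcel[[as.character(p)]]
      centre <- arrayInd(vix[sample.int(length(vix), 1L)], d)
      cmm <- (centre - 0.5) * vox
      r <- stats::rlnorm(1, cfg$lesion_radius_meanlog, cfg$lesion_radius_sdlog)
      vals <- array(0, d)
      lo <- pmax(1L, centre - ceiling(r / vox))
      hi <- pmin(d, centre + ceiling(r / vox))
      xs <- lo[1]:hi[1]; ys <- lo[2]:hi[2]; zs <- lo[3]:hi[3]
      dx2 <- (ax[[1]][xs] - cmm[1])^2
      dy2 <- (ax[[2]][ys] - cmm[2])^2
      dz2 <- (ax[[3]][zs] - cmm[3])^2
      blob <- outer(outer(dx2, dy2, `+`), dz2, `+`) <= r^2
      vals[xs, ys, zs] <- blob + 0
      masks[[i]] <- volume_map(vals, vox, kind = "mask")
      centre_parcel[i] <- p
      centre_mm[i, ] <- cmm
    }
  }
  grade <- factor(ifelse(stats::runif(n) < cfg$lgg_fraction, "LGG", "HGG"),
                  levels = c("LGG", "HGG"))
  structure(list(masks = masks, grade = grade,
                 centre_parcel = centre_parcel, centre_mm = centre_mm),
            class = "lesion_cohort")
}

#' Synthetic connectome component loadings
#'
#' Generates per-parcel component-loading vectors whose pairwise correlations
#' realize a modular weighted graph: parcels within the same canonical
#' network share a module factor, a weak global factor sets the
#' between-module baseline, and each parcel's module-factor weight increases
#' with its (noisy) hub-truth rank, so realized nodal strength
#' rank-correlates with `hub_truth` at a level controlled by
#' `effect_sizes["hub"]`.
#'
#' @param cfg A [synthetic_config()].
#' @param parc A [make_parcellation()].
#' @param hub_truth hub field, one value per parcel (left or bilateral).
#' @return Matrix `n_parcels x n_components` of loadings.
#' @export
make_connectome_source <- function(cfg, parc, hub_truth) {
  if (cfg$n_components < 2L) stop("dimension error: need >= 2 components")
  hub_truth <- mirror_parcel_vector(hub_truth, parc)
  set.seed(cfg$seed + 3L)
  n <- nrow(parc$table)
  k <- cfg$n_components
  rho <- cfg$effect_sizes[["hub"]]
  ht <- if (stats::sd(hub_truth) > 0) as.numeric(scale(hub_truth)) else
    rep(0, n)
  z <- rho * ht + sqrt(max(0, 1 - rho^2)) * stats::rnorm(n)
  w <- 0.35 + 0.55 * stats::pnorm(z)
  b <- 0.1  # between- vs within-module share of the common signal
  nets <- parc$table$network
  g0 <- stats::rnorm(k)
  gm <- matrix(stats::rnorm(7L * k), 7L, k,
               dimnames = list(sort(unique(nets)), NULL))
  eps <- matrix(stats::rnorm(n * k), n, k)
  shared <- sqrt(b) * matrix(g0, n, k, byrow = TRUE) +
    sqrt(1 - b) * gm[nets, , drop = FALSE]
  load <- w * shared + sqrt(1 - w^2) * eps
  rownames(load) <- parc$table$parcel_id
  load
}

#' Synthetic regional gene-expression atlas
#'
#' Places `n_samples` sample locations uniformly within left-hemisphere
#' parcels, then generates a samples-by-genes expression matrix: background
#' genes mix a small bank of smooth latent spatial factors with i.i.d.
#' noise; a planted marker gene set shares one spatial profile correlated
#' with `target` at `effect_sizes["opc"]`; a planted driver gene set loads
#' on a profile correlated with `target` at `effect_sizes["driver"]`. Each
#' set may include anti-correlated decoy genes (negative loading on the
#' shared profile), emulating set members with discordant co-expression.
#'
#' @param cfg A [synthetic_config()].
#' @param parc A [make_parcellation()].
#' @param target left-hemisphere parcel field the planted profiles track.
#' @return An `expression_atlas`: `expr` (samples x genes), `coords`
#'   (sample_id, x, y, z in mm), `sample_parcel`, `gene_sets` (list with
#'   `opc_markers`, `glioma_drivers`, and `*_decoys`), `profiles` (the
#'   planted marker/driver spatial profiles).
#' @export
make_expression_atlas <- function(cfg, parc, target) {
  n_special <- cfg$n_marker_genes + cfg$n_driver_genes
  if (cfg$n_genes < n_special + 10L)
    stop("sizing error: n_genes too small for the planted gene sets")
  if (cfg$n_marker_decoys >= cfg$n_marker_genes ||
      cfg$n_driver_decoys >= cfg$n_driver_genes)
    stop("sizing error: decoys must be fewer than set size")
  tab <- parc$table
  n_left <- sum(tab$hemisphere == "L")
  if (cfg$n_samples < n_left)
    warning("fewer samples than parcels; some parcels will lack samples")
  set.seed(cfg$seed + 4L)
  d <- dim(parc$labels)
  vox <- parc$voxel_size_mm
  left_vox <- which(parc$labels > 0L &
                      parc$labels <= n_left)
  pick <- left_vox[sample.int(length(left_vox), cfg$n_samples, replace = TRUE)]
  co <- arrayInd(pick, d)
  coords <- sweep(co - stats::runif(length(pick) * 3L), 2L, vox, `*`)
  sample_parcel <- parc$labels[pick]

  tgt <- as.numeric(scale(target[sample_parcel]))
  mk_profile <- function(rho) {
    u <- as.numeric(gp_draw(coords, cfg$smoothness_mm))
    mix_exact(tgt, u, rho)
  }
  marker_profile <- mk_profile(cfg$effect_sizes[["opc"]])
  driver_profile <- mk_profile(cfg$effect_sizes[["driver"]])

  genes <- sprintf("gene%05d", seq_len(cfg$n_genes))
  n_lat <- 8L
  ## background genes are planted nulls with respect to the target map:
  ## their shared smooth factors are orthogonalized against it in-sample
  lat <- apply(gp_draw(coords, cfg$smoothness_mm, n_lat), 2L,
               function(u) mix_exact(tgt, u, 0))
  a <- matrix(stats::rnorm(n_lat * cfg$n_genes), n_lat)
  a <- a / rep(sqrt(colSums(a^2)), each = n_lat)
  expr <- sqrt(0.5) * (lat %*% a) +
    sqrt(0.5) * matrix(stats::rnorm(cfg$n_samples * cfg$n_genes),
                       cfg$n_samples)
  colnames(expr) <- genes

  lam <- 0.75
  plant <- function(profile, n_set, n_decoy, cols) {
    sgn <- c(rep(1, n_set - n_decoy), rep(-1, n_decoy))
    expr[, cols] <<- lam * outer(profile, sgn) +
      sqrt(1 - lam^2) * matrix(stats::rnorm(cfg$n_samples * n_set),
                               cfg$n_samples)
  }
  marker_cols <- seq_len(cfg$n_marker_genes)
  driver_cols <- cfg$n_marker_genes + seq_len(cfg$n_driver_genes)
  plant(marker_profile, cfg$n_marker_genes, cfg$n_marker_decoys, marker_cols)
  plant(driver_profile, cfg$n_driver_genes, cfg$n_driver_decoys, driver_cols)
  ## shuffle gene order so planted sets are not a giveaway block
  ## (column names travel with the columns, so set membership is unchanged)
  expr <- expr[, sample.int(cfg$n_genes)]

  tail_ids <- function(cols, n_decoy)
    if (n_decoy == 0L) character(0) else
      genes[cols[(length(cols) - n_decoy + 1L):length(cols)]]
  gene_sets <- list(
    opc_markers = genes[marker_cols],
    opc_decoys = tail_ids(marker_cols, cfg$n_marker_decoys),
    glioma_drivers = genes[driver_cols],
    driver_decoys = tail_ids(driver_cols, cfg$n_driver_decoys))

  structure(list(
    expr = expr,
    coords = data.frame(sample_id = sprintf("s%04d", seq_len(cfg$n_samples)),
                        x = coords[, 1], y = coords[, 2], z = coords[, 3]),
    sample_parcel = sample_parcel,
    gene_sets = gene_sets,
    profiles = list(marker = marker_profile, driver = driver_profile)),
    class = "expression_atlas")
}
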