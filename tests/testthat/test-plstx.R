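aligned_from_matrix <- function(x, y) {
  x <- scale(x)
  attr(x, "scaled:center") <- attr(x, "scaled:scale") <- NULL
  if (is.null(colnames(x))) colnames(x) <- sprintf("g%04d", seq_len(ncol(x)))
  structure(list(X = x, y = y, sample_coords = NULL, sample_parcel = NULL),
            class = "aligned_dataset")
}

test_that("sample alignment reads sqrt frequency at (reflected) sample voxels", {
  cfg <- small_cfg(seed = 2L)
  parc <- make_parcellation(cfg)
  d <- dim(parc$labels)
  f <- make_ground_truth_fields(cfg, parc)
  atlas <- make_expression_atlas(cfg, parc, f$tumour)
  ## constant 16% map: every sample reads sqrt(16) = 4
  const <- volume_map(array(16, d), parc$voxel_size_mm)
  al <- align_samples_to_frequency(atlas, const, parc)
  expect_equal(al$y, rep(4, nrow(atlas$expr)))
  ## zero map gives y = 0, and X columns are z-scored
  zero <- volume_map(array(0, d), parc$voxel_size_mm)
  al0 <- align_samples_to_frequency(atlas, zero, parc)
  expect_equal(al0$y, rep(0, nrow(atlas$expr)))
  expect_lt(max(abs(colMeans(al$X))), 1e-8)
  expect_lt(max(abs(apply(al$X, 2, sd) - 1)), 1e-8)
  ## right-hemisphere samples reflect to the homotopic left voxel
  set.seed(4)
  v <- array(runif(prod(d), 0, 50), d)
  raw <- volume_map(v, parc$voxel_size_mm)
  atlas_r <- atlas
  lims <- d * parc$voxel_size_mm
  atlas_r$coords$x <- lims[1] - atlas$coords$x  # push all samples right
  al_r <- align_samples_to_frequency(atlas_r, raw, parc)
  expect_equal(al_r$y, align_samples_to_frequency(atlas, raw, parc)$y)
})

test_that("PLS component 1 matches the cross-covariance SVD oracle", {
  for (s in 1:5) {
    set.seed(s)
    x <- matrix(rnorm(50 * 100), 50, 100)
    y <- rnorm(50)
    d <- aligned_from_matrix(x, y)
    fit <- fit_pls(d, n_components = 2)
    cc <- crossprod(d$X, y - mean(y))       # gene-response cross-covariance
    sv <- cc / sqrt(sum(cc^2))              # dominant singular direction
    expect_gt(abs(sum(fit$weights[, 1] * sv)), 0.999)
    expect_true(all(abs(colSums(fit$weights^2) - 1) < 1e-10))
  }
})

test_that("a perfect single-gene predictor is captured by component 1", {
  ## noise columns are residualized against y so the cross-covariance is
  ## supported on the single informative gene
  set.seed(6)
  x <- matrix(rnorm(60 * 40), 60, 40)
  y <- 3 * x[, 7]
  x[, -7] <- apply(x[, -7], 2, function(v) resid(lm(v ~ y)))
  fit <- fit_pls(aligned_from_matrix(x, y))
  expect_gte(fit$variance_explained_y[1], 0.999)
})

test_that("variance explained is invariant to gene order and sign convention", {
  set.seed(7)
  x <- matrix(rnorm(50 * 30), 50, 30)
  y <- x[, 1] + rnorm(50)
  d1 <- aligned_from_matrix(x, y)
  d2 <- aligned_from_matrix(x[, sample(30)], y)
  f1 <- fit_pls(d1); f2 <- fit_pls(d2)
  expect_equal(f1$variance_explained_y, f2$variance_explained_y,
               tolerance = 1e-10)
  ## gene-wise affine rescaling before z-scoring changes nothing
  d3 <- aligned_from_matrix(sweep(sweep(x, 2, runif(30, 0.5, 3), `*`),
                                  2, rnorm(30), `+`), y)
  expect_equal(fit_pls(d3)$variance_explained_y, f1$variance_explained_y,
               tolerance = 1e-10)
  ## flipping y flips scores, leaves variance and |z| unchanged
  d4 <- aligned_from_matrix(x, -y)
  f4 <- fit_pls(d4)
  expect_equal(f4$variance_explained_y, f1$variance_explained_y,
               tolerance = 1e-10)
  expect_equal(f4$scores[, 1], -f1$scores[, 1], tolerance = 1e-10)
  z1 <- bootstrap_gene_z(d1, n_boot = 50, seed = 1)
  z4 <- bootstrap_gene_z(d4, n_boot = 50, seed = 1)
  expect_equal(abs(z4$z_pls1), abs(z1$z_pls1), tolerance = 1e-8)
})

test_that("permutation p-values are uniform under independence and detect signal", {
  set.seed(8)
  ps <- replicate(100, {
    x <- matrix(rnorm(40 * 25), 40, 25)
    d <- aligned_from_matrix(x, rnorm(40))
    permute_pls_significance(d, fit_pls(d), n_perm = 99)$p
  })
  expect_gt(suppressWarnings(stats::ks.test(ps, "punif"))$p.value, 0.01)
  ## strong planted signal pins p to the floor
  x <- matrix(rnorm(60 * 25), 60, 25)
  y <- x[, 3] + 0.5 * rnorm(60)
  d <- aligned_from_matrix(x, y)
  expect_equal(permute_pls_significance(d, fit_pls(d), n_perm = 99,
                                        seed = 1)$p, 1 / 100)
})

test_that("bootstrap z ranks planted predictors high, noise genes low", {
  set.seed(9)
  n <- 80; p <- 120
  x <- matrix(rnorm(n * p), n, p)
  driver <- rnorm(n)
  x[, 5] <- driver + 0.3 * rnorm(n)
  y <- driver + 0.5 * rnorm(n)
  d <- aligned_from_matrix(x, y)
  r <- bootstrap_gene_z(d, n_boot = 200, seed = 2)
  expect_lte(r$rank1[5], ceiling(0.01 * p))   # top 1%
  expect_gt(mean(abs(r$z_pls1[-5]) < 3), 0.95)
  expect_true(all(sort(r$rank1) == seq_len(p)))
})

test_that("duplicated gene columns get identical z and id-ordered adjacent ranks", {
  set.seed(10)
  x <- matrix(rnorm(50 * 20), 50, 20)
  x[, 2] <- x[, 1]
  colnames(x) <- sprintf("g%02d", 1:20)
  y <- rowSums(x[, 1:3]) + rnorm(50)
  d <- aligned_from_matrix(x, y)
  r <- bootstrap_gene_z(d, n_boot = 100, seed = 3)
  expect_equal(r$z_pls1[1], r$z_pls1[2], tolerance = 1e-10)
  expect_equal(abs(r$rank1[1] - r$rank1[2]), 1L)
  expect_lt(r$rank1[1], r$rank1[2])  # tie broken by gene id
})

test_that("median-rank enrichment matches complete enumeration on a toy ranking", {
  r <- data.frame(gene_id = sprintf("g%02d", 1:20),
                  z_pls1 = 20:1, z_pls2 = 1:20,
                  rank1 = 1:20, rank2 = 20:1)
  class(r) <- c("gene_ranking", "data.frame")
  set_genes <- c("g01", "g04", "g09")
  got <- rank_enrichment_test(r, set_genes, component = 1, exhaustive = TRUE)
  sets <- utils::combn(20, 3)
  null <- apply(sets, 2, function(i) median(r$rank1[i]))
  obs <- median(r$rank1[match(set_genes, r$gene_id)])
  expect_equal(got$p, (1 + sum(null <= obs)) / (1 + ncol(sets)))
  ## the k top-ranked genes give the floor
  top <- rank_enrichment_test(r, c("g01", "g02", "g03"), component = 1,
                              exhaustive = TRUE)
  expect_equal(top$p, (1 + sum(null <= 2)) / (1 + ncol(sets)))
  expect_equal(top$median_rank, 2)
})

test_that("parcel loading maps take sample-score medians and fill empty parcels", {
  cfg <- small_cfg(seed = 11L)
  parc <- make_parcellation(cfg)
  f <- make_ground_truth_fields(cfg, parc)
  atlas <- make_expression_atlas(cfg, parc, f$tumour)
  raw <- build_frequency_map(make_lesion_cohort(cfg, parc, exp(f$tumour)))
  al <- align_samples_to_frequency(atlas, raw, parc)
  fit <- fit_pls(al)
  lm_ <- map_loadings_to_parcels(fit, al, parc)
  left_ids <- parc$table$parcel_id[parc$table$hemisphere == "L"]
  for (id in left_ids) {
    in_p <- al$sample_parcel == id
    expected <- if (any(in_p)) median(fit$scores[in_p, 1]) else
      mean(fit$scores[, 1])
    expect_equal(unname(lm_$loadings[as.character(id), 1]), expected)
  }
  expect_equal(sum(lm_$n_samples), nrow(atlas$expr))
  expect_setequal(as.character(lm_$empty_parcels),
                  names(lm_$n_samples)[lm_$n_samples == 0])
})

test_that("planted driver genes rank in the top decile across seeds", {
  parc <- default_parc()
  hits <- vapply(1:10, function(s) {
    cfg <- synthetic_config(seed = s, n_driver_genes = 30L,
                            n_driver_decoys = 0L)
    f <- make_ground_truth_fields(cfg, parc)
    raw <- build_frequency_map(make_lesion_cohort(cfg, parc, exp(f$tumour)))
    freq <- parcel_aggregate(mirror_map(smooth_map(raw, 2)), parc, "left", 4)
    target <- as.numeric(scale(sqrt(ifelse(is.na(freq), 0, freq))))
    atlas <- make_expression_atlas(cfg, parc, target)
    al <- align_samples_to_frequency(atlas, raw, parc)
    r <- bootstrap_gene_z(al, n_boot = 100, seed = s)
    median(r$rank1[match(atlas$gene_sets$glioma_drivers, r$gene_id)]) <=
      0.1 * nrow(r)
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})
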