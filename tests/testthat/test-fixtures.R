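test_that("parcellation has the requested size, symmetry and contiguity", {
  cfg <- tiny_cfg(n_parcels_per_hemisphere = 4L, n_subcortical = 1L)
  parc <- make_parcellation(cfg)
  expect_equal(nrow(parc$table), 8L)
  expect_equal(sum(parc$table$hemisphere == "L"), 4L)
  expect_equal(sum(!parc$table$is_cortical), 2L)
  ## every label spatially contiguous (flood-fill oracle)
  for (id in parc$table$parcel_id)
    expect_equal(count_components(parc$labels, id), 1L)
  ## left-right flip maps every parcel onto its homotopic partner
  d <- dim(parc$labels)
  flipped <- parc$labels[d[1]:1, , ]
  lab <- parc$labels[parc$labels > 0]
  expect_equal(flipped[parc$labels > 0], parc$table$homotopic_id[lab])
})

test_that("paper-scale parcellation yields 334 labels with 8 subcortical per hemisphere", {
  parc <- default_parc()
  expect_equal(nrow(parc$table), 334L)
  expect_equal(sum(parc$table$hemisphere == "L"), 167L)
  expect_equal(sum(!parc$table$is_cortical & parc$table$hemisphere == "L"), 8L)
  ## unit-sphere centroids for all cortical parcels
  cc <- parc$table[parc$table$is_cortical, c("cx", "cy", "cz")]
  expect_true(all(abs(sqrt(rowSums(cc^2)) - 1) < 1e-9))
})

test_that("infeasible parcel counts raise sizing errors", {
  expect_error(make_parcellation(tiny_cfg(grid_shape = c(6L, 6L, 6L),
                                          n_parcels_per_hemisphere = 200L)),
               "sizing")
})

test_that("generator output is bit-identical under an identical config", {
  cfg <- tiny_cfg(seed = 42L)
  parc <- make_parcellation(cfg)
  f1 <- make_ground_truth_fields(cfg, parc)
  f2 <- make_ground_truth_fields(cfg, parc)
  expect_identical(f1, f2)
  c1 <- make_lesion_cohort(cfg, parc, exp(f1$tumour))
  c2 <- make_lesion_cohort(cfg, parc, exp(f1$tumour))
  expect_identical(c1, c2)
  a1 <- make_expression_atlas(cfg, parc, f1$tumour)
  a2 <- make_expression_atlas(cfg, parc, f1$tumour)
  expect_identical(a1, a2)
})

test_that("lesion centres follow the planted placement law", {
  cfg <- tiny_cfg(n_patients = 50L)
  parc <- make_parcellation(cfg)
  truth <- rep(0, parc$n_left)
  truth[5] <- 1  # all mass on one parcel (and its mirror)
  cohort <- make_lesion_cohort(cfg, parc, truth)
  hit <- cohort$centre_parcel %in% c(5L, 5L + parc$n_left)
  expect_gte(mean(hit), 0.9)
  ## blobs are single contiguous components
  expect_equal(count_components(cohort$masks[[1]]$values > 0, TRUE), 1L)
})

test_that("cohort grade mix is binomial around the configured fraction", {
  cfg <- tiny_cfg(n_patients = 335L, lgg_fraction = 0.23)
  parc <- make_parcellation(cfg)
  truth <- rep(1, parc$n_left)
  cohort <- make_lesion_cohort(cfg, parc, truth)
  n_lgg <- sum(cohort$grade == "LGG")
  bounds <- qbinom(c(0.0005, 0.9995), 335, 0.23)
  expect_gte(n_lgg, bounds[1])
  expect_lte(n_lgg, bounds[2])
})

test_that("degenerate lesion inputs are rejected; empty cohort allowed", {
  cfg <- tiny_cfg()
  parc <- make_parcellation(cfg)
  expect_error(make_lesion_cohort(cfg, parc, rep(0, parc$n_left)),
               "degenerate")
  empty <- make_lesion_cohort(tiny_cfg(n_patients = 0L), parc,
                              rep(1, parc$n_left))
  expect_length(empty$masks, 0L)
})

test_that("connectome source realizes a modular graph", {
  cfg <- small_cfg(seed = 2L)
  parc <- make_parcellation(cfg)
  f <- make_ground_truth_fields(cfg, parc)
  conn <- build_parcel_connectome(make_connectome_source(cfg, parc, f$hub),
                                  parc)
  same <- outer(conn$community, conn$community, `==`) & upper.tri(conn$weights)
  diff <- !outer(conn$community, conn$community, `==`) & upper.tri(conn$weights)
  expect_gt(mean(conn$weights[same]), mean(conn$weights[diff]))
})

test_that("constant hub truth leaves only sampling noise in strengths", {
  cfg <- small_cfg(seed = 3L, n_components = 1200L)
  parc <- make_parcellation(cfg)
  conn <- build_parcel_connectome(
    make_connectome_source(cfg, parc, rep(1, parc$n_left)), parc)
  st <- rowSums(conn$weights)
  expect_lt(stats::sd(st) / mean(st), 0.25)
})

test_that("connectome source rejects fewer than two components", {
  cfg <- tiny_cfg(n_components = 1L)
  parc <- make_parcellation(cfg)
  expect_error(make_connectome_source(cfg, parc, rep(1, parc$n_left)),
               "dimension")
})

test_that("hub generator calibration: planted 0.8 recovers Spearman in [0.6, 0.95]", {
  parc <- default_parc()
  rs <- vapply(1:20, function(s) {
    cfg <- synthetic_config(seed = s,
                            effect_sizes = c(hub = 0.8, opc = 0.5, driver = 0.5))
    f <- make_ground_truth_fields(cfg, parc)
    conn <- build_parcel_connectome(make_connectome_source(cfg, parc, f$hub),
                                    parc)
    ht <- c(f$hub, f$hub)  # right parcel i + n_left is homotopic to left i
    cor(rank(rowSums(conn$weights)), rank(ht))
  }, numeric(1))
  expect_true(all(rs >= 0.6 & rs <= 0.95))
})

test_that("planted marker set co-expresses above its own random-set null", {
  cfg <- small_cfg(seed = 4L)
  parc <- make_parcellation(cfg)
  f <- make_ground_truth_fields(cfg, parc)
  atlas <- make_expression_atlas(cfg, parc, f$tumour)
  obs <- mean(cor(atlas$expr[, atlas$gene_sets$opc_markers])[
    upper.tri(diag(cfg$n_marker_genes))])
  set.seed(1)
  null <- vapply(1:1000, function(i) {
    g <- sample(colnames(atlas$expr), cfg$n_marker_genes)
    mean(cor(atlas$expr[, g])[upper.tri(diag(cfg$n_marker_genes))])
  }, numeric(1))
  expect_gt(obs, stats::quantile(null, 0.975))
})

test_that("zero planted OPC effect leaves marker-target correlation centred on zero", {
  rs <- vapply(1:8, function(s) {
    cfg <- tiny_cfg(seed = s,
                    effect_sizes = c(hub = 0.5, opc = 0, driver = 0.5))
    parc <- make_parcellation(cfg)
    f <- make_ground_truth_fields(cfg, parc)
    atlas <- make_expression_atlas(cfg, parc, f$tumour)
    cor(atlas$profiles$marker, scale(f$tumour[atlas$sample_parcel]))
  }, numeric(1))
  expect_lt(abs(mean(rs)), 0.25)
})

test_that("expression atlas rejects too-small gene budgets", {
  cfg <- tiny_cfg(n_genes = 20L)
  parc <- make_parcellation(cfg)
  expect_error(make_expression_atlas(cfg, parc, rnorm(parc$n_left)), "sizing")
})

test_that("unsmoothed truth fields sit at the permutation-null Moran expectation", {
  cfg <- small_cfg(seed = 6L, smoothness_mm = 0)
  parc <- make_parcellation(cfg)
  f <- make_ground_truth_fields(cfg, parc)
  mi <- morans_i(f$tumour, parc, n_perm = 500, seed = 1)
  null_sd <- stats::sd(replicate(200, {
    morans_i(sample(f$tumour), parc, n_perm = 0)$I
  }))
  expect_lt(abs(mi$I - mi$expectation), 4 * null_sd)
})

test_that("smooth truth fields carry significant positive spatial autocorrelation", {
  cfg <- small_cfg(seed = 7L, smoothness_mm = 14)
  parc <- make_parcellation(cfg)
  f <- make_ground_truth_fields(cfg, parc)
  mi <- morans_i(f$tumour, parc, n_perm = 500, seed = 1)
  expect_gt(mi$I, mi$expectation)
  expect_lt(mi$p, 0.01)
})

test_that("planted field-pair correlation 0.5 is recovered in [0.3, 0.7]", {
  parc <- default_parc()
  rs <- vapply(1:20, function(s) {
    cfg <- synthetic_config(seed = s)
    f <- make_ground_truth_fields(cfg, parc)
    cor(f$tumour, f$hub)
  }, numeric(1))
  ## smooth fields have limited effective spatial degrees of freedom, so the
  ## per-seed sample correlation scatters around the planted value; the
  ## calibration claim is about its centre and sign
  expect_gte(mean(rs), 0.3)
  expect_lte(mean(rs), 0.7)
  expect_true(all(rs > 0))
})
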