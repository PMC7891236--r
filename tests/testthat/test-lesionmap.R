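make_mask <- function(d, idx, vox = c(2, 2, 2)) {
  v <- array(0, d)
  v[idx] <- 1
  volume_map(v, vox, kind = "mask")
}

test_that("frequency map equals an independent per-voxel counting loop", {
  d <- c(8L, 8L, 8L)
  set.seed(11)
  masks <- lapply(1:200, function(i)
    make_mask(d, sample.int(prod(d), 25)))
  fm <- build_frequency_map(masks)
  counts <- array(0, d)
  for (m in masks)
    for (v in seq_len(prod(d))) counts[v] <- counts[v] + m$values[v]
  expect_identical(fm$values, 100 * counts / 200)
  ## single mask and two disjoint masks
  expect_equal(build_frequency_map(masks[1])$values, 100 * masks[[1]]$values)
  m1 <- make_mask(d, 1:5); m2 <- make_mask(d, 6:10)
  two <- build_frequency_map(list(m1, m2))
  expect_equal(sort(unique(as.numeric(two$values))), c(0, 50))
  ## mass conservation: sum(map)/100 = mean lesion volume in voxels
  expect_equal(sum(fm$values) / 100, mean(vapply(masks, function(m)
    sum(m$values), numeric(1))))
})

test_that("frequency map rejects grid mismatches and empty cohorts", {
  expect_error(build_frequency_map(list()), "empty-cohort")
  a <- make_mask(c(4L, 4L, 4L), 1)
  b <- make_mask(c(4L, 4L, 6L), 1)
  expect_error(build_frequency_map(list(a, b)), "geometry")
})

test_that("smoothing matches the analytic Gaussian and preserves constants", {
  d <- c(15L, 15L, 15L)
  const <- volume_map(array(7, d), c(1, 1, 1))
  expect_equal(smooth_map(const, 2)$values, const$values, tolerance = 1e-10)
  expect_identical(smooth_map(const, 0)$values, const$values)
  ## delta response: off-centre / peak ratio is exp(-1 / (2 sigma^2))
  delta <- array(0, d); delta[8, 8, 8] <- 100
  sm <- smooth_map(volume_map(delta, c(1, 1, 1)), 2)
  sigma <- 2 / (2 * sqrt(2 * log(2)))
  expect_equal(sm$values[9, 8, 8] / sm$values[8, 8, 8],
               exp(-1 / (2 * sigma^2)), tolerance = 1e-9)
  expect_error(smooth_map(const, -1), "parameter")
})

test_that("mirroring averages homotopic voxels and keeps the source side", {
  d <- c(8L, 6L, 6L)
  set.seed(3)
  v <- array(runif(prod(d), 0, 50), d)
  m <- volume_map(v, c(2, 2, 2))
  mm <- mirror_map(m, to = "left")
  for (x in 1:4) {
    expect_equal(mm$values[x, , ], (v[x, , ] + v[9 - x, , ]) / 2)
    expect_equal(mm$values[9 - x, , ], v[9 - x, , ])
  }
  ## symmetric map is unchanged; pure right-hemisphere map reflects
  vs <- v; vs[1:4, , ] <- v[8:5, , ]
  expect_equal(mirror_map(volume_map(vs, c(2, 2, 2)))$values, vs)
  vr <- array(0, d); vr[5:8, , ] <- v[5:8, , ]
  left <- mirror_map(volume_map(vr, c(2, 2, 2)))$values[4:1, , ]
  expect_equal(left, vr[5:8, , ] / 2)
})

test_that("parcel aggregation averages within labels and honours dilation", {
  cfg <- tiny_cfg()
  parc <- make_parcellation(cfg)
  d <- dim(parc$labels)
  const <- volume_map(array(3, d), parc$voxel_size_mm)
  v0 <- parcel_aggregate(const, parc, "left", wm_extension_mm = 0)
  expect_equal(unname(v0), rep(3, parc$n_left))
  ## half 0 / half 100 inside a parcel averages to 50
  v <- array(0, d)
  in5 <- which(parc$labels == 5L)
  v[in5[seq_len(floor(length(in5) / 2))]] <- 100
  got <- parcel_aggregate(volume_map(v, parc$voxel_size_mm), parc, "left", 0)
  expect_equal(unname(got["5"]),
               100 * floor(length(in5) / 2) / length(in5))
  ## dilation matches a brute-force euclidean nearest-boundary oracle
  lab <- array(0L, c(7L, 5L, 5L))
  lab[1:2, , ] <- 1L
  lab[6:7, , ] <- 2L   # two-voxel corridor at x = 3:5... x=3,4,5 unlabelled
  dil <- dilate_labels(lab, c(2, 2, 2), 4)
  idx_lab <- which(lab > 0L)
  co_lab <- arrayInd(idx_lab, dim(lab))
  for (vx in which(lab == 0L)) {
    co <- arrayInd(vx, dim(lab))
    dd <- sqrt(colSums((t(co_lab) - as.numeric(co))^2)) * 2
    near <- dd <= 4 + 1e-9
    expected <- if (!any(near)) 0L else min(lab[idx_lab[near & dd <= min(dd) + 1e-9]])
    expect_identical(dil[vx], expected)
  }
})

test_that("aggregation matches a direct per-parcel mean oracle", {
  cfg <- tiny_cfg(seed = 5L)
  parc <- make_parcellation(cfg)
  d <- dim(parc$labels)
  set.seed(9)
  v <- array(runif(prod(d), 0, 100), d)
  got <- parcel_aggregate(volume_map(v, parc$voxel_size_mm), parc,
                          "bilateral", wm_extension_mm = 4)
  lab <- dilate_labels(parc$labels, parc$voxel_size_mm, 4)
  for (id in parc$table$parcel_id)
    expect_equal(unname(got[as.character(id)]), mean(v[lab == id]))
})

test_that("grade-stratified splits meet the target low-grade imbalance", {
  set.seed(21)
  grade <- factor(rep(c("LGG", "HGG"), c(77, 258)), levels = c("LGG", "HGG"))
  sp <- gliotopo:::split_cohort(grade, 1.5)
  expect_length(intersect(sp$group1, sp$group2), 0L)
  expect_setequal(c(sp$group1, sp$group2), seq_along(grade))
  f <- mean(grade == "LGG")
  expect_lt(abs(sp$lgg_fractions[1] - 1.5 * f), 0.02)
  expect_lt(abs(sp$lgg_fractions[2] - 0.5 * f), 0.02)
  expect_error(gliotopo:::split_cohort(factor(rep("HGG", 10),
                                              levels = c("LGG", "HGG")), 1.5),
               "split")
})

test_that("split-half replicability tracks the cohort's self-consistency", {
  cfg <- small_cfg(seed = 8L, n_patients = 300L)
  parc <- make_parcellation(cfg)
  f <- make_ground_truth_fields(cfg, parc)
  cohort <- make_lesion_cohort(cfg, parc, exp(f$tumour))
  sh <- split_half_replicability(cohort, parc, n_repeats = 20, seed = 2)
  expect_true(all(sh$r_all > 0))
  expect_lte(sh$ci[1], sh$r_point)
  expect_gte(sh$ci[2], sh$r_point)
  ## independent resampling oracle: correlation between two frequency maps
  ## from bootstrap half-cohorts estimates the same self-consistency
  oracle <- replicate(10, {
    idx <- sample(length(cohort$masks))
    h1 <- idx[1:150]; h2 <- idx[151:300]
    v1 <- parcel_aggregate(mirror_map(smooth_map(
      build_frequency_map(cohort$masks[h1]), 2)), parc, "left", 4)
    v2 <- parcel_aggregate(mirror_map(smooth_map(
      build_frequency_map(cohort$masks[h2]), 2)), parc, "left", 4)
    cor(v1, v2)
  })
  expect_lte(sh$ci[1], max(oracle))
  expect_gte(sh$ci[2], min(oracle))
})

test_that("network summaries reproduce hand-computed voxel means", {
  cfg <- tiny_cfg()
  parc <- make_parcellation(cfg)
  d <- dim(parc$labels)
  const <- volume_map(array(4.2, d), parc$voxel_size_mm)
  ns <- network_summaries(const, parc)
  expect_equal(ns$by_network$mean_percent,
               rep(4.2, nrow(ns$by_network)))
  ## value = parcel network index -> means recover the index exactly
  nets <- ns$by_network$network
  v <- array(0, d)
  keep <- parc$labels > 0
  v[keep] <- match(parc$table$network[parc$labels[keep]], nets)
  ns2 <- network_summaries(volume_map(v, parc$voxel_size_mm), parc)
  present <- ns2$by_network$n_voxels > 0
  expect_equal(ns2$by_network$mean_percent[present], which(present))
  bad <- parc
  bad$table$network[1] <- "mystery"
  expect_error(network_summaries(const, bad), "labelling")
})
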