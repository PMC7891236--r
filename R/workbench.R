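#' Default analysis parameters
#'
#' The analysis defaults of the pipeline: 2 mm FWHM smoothing, 4 mm
#' white-matter parcel extension, Spearman 0.95 redundancy screen, 10 000
#' spins and random parcel pairs, 1000 permutations/bootstraps, and 100
#' split-half repeats.
#'
#' @param fwhm_mm,wm_extension_mm map-processing parameters.
#' @param n_spins,n_pairs,n_perm,n_boot,n_coexpr_null,n_rank_null,n_repeats
#'   resampling sizes.
#' @param screen_rho redundancy screen threshold.
#' @param with_expression run the transcriptomic stages?
#' @return A named list of parameters.
#' @export
pipeline_params <- function(fwhm_mm = 2, wm_extension_mm = 4,
                            n_spins = 10000L, n_pairs = 10000L,
                            n_perm = 1000L, n_boot = 1000L,
                            n_coexpr_null = 1000L, n_rank_null = 10000L,
                            n_repeats = 100L, screen_rho = 0.95,
                            with_expression = TRUE) {
  as.list(environment())
}

#' Run the full synthetic-study pipeline
#'
#' Executes every stage end-to-end on generated data: synthetic inputs,
#' tumour frequency mapping (build, smooth, mirror, parcellate), network
#' summaries, split-half replicability, Moran's I, spin-ensemble
#' construction, connectome hub profiling with redundancy screening and
#' hub-frequency spin tests, the NSC-niche and OPC-marker analyses, the
#' PLS transcriptomic analysis with permutation significance, bootstrap
#' gene ranking and driver-set enrichment, and the integrative regression
#' with partial-variance decomposition and predictor spin p-values. When
#' `params$with_expression` is `FALSE` the transcriptomic stages (and the
#' integrative model, which needs them) are marked skipped.
#'
#' @param cfg a [synthetic_config()].
#' @param params a [pipeline_params()] list.
#' @return A list with `results` (per-stage outputs), `manifest`
#'   (config snapshot, seeds, parameters, stage list, reproducibility
#'   hash).
#' @export
run_pipeline <- function(cfg = synthetic_config(), params = pipeline_params()) {
  res <- list()
  parc <- make_parcellation(cfg)
  fields <- make_ground_truth_fields(cfg, parc)
  cohort <- make_lesion_cohort(cfg, parc, exp(fields$tumour))

  raw_map <- build_frequency_map(cohort)
  proc_map <- mirror_map(smooth_map(raw_map, params$fwhm_mm), to = "left")
  freq <- parcel_aggregate(proc_map, parc, scope = "left",
                           wm_extension_mm = params$wm_extension_mm)
  res$lesionmap <- list(
    freq = freq,
    networks = network_summaries(proc_map, parc),
    split_half = split_half_replicability(
      cohort, parc, n_repeats = params$n_repeats,
      fwhm_mm = params$fwhm_mm, wm_extension_mm = params$wm_extension_mm,
      seed = cfg$seed + 10L))
  res$spatialnull <- list(
    morans = morans_i(freq, parc, seed = cfg$seed + 11L))

  ens <- build_spin_ensemble(parc, n_spins = params$n_spins,
                             seed = cfg$seed + 12L, scope = "left")

  loadings <- make_connectome_source(cfg, parc, fields$hub)
  conn <- build_parcel_connectome(loadings, parc)
  hubs <- screen_redundant_metrics(
    homotopic_average(hub_metrics(conn), parc), threshold = params$screen_rho)
  res$hubgraph <- list(
    hub_table = hubs,
    screened_out = attr(hubs, "screened_out"),
    association = hub_frequency_association(hubs, freq, ens))

  res$cellorigin <- list(
    nsc = nsc_niche_test(freq, parc = parc, n_null = params$n_pairs,
                         seed = cfg$seed + 13L))

  if (params$with_expression) {
    ## the planted expression profiles track the *measured* tumour frequency
    ## map (sqrt scale, as the PLS response), so effect sizes refer to the
    ## map the analyses actually see
    freq0 <- ifelse(is.na(freq), 0, freq)
    atlas_target <- as.numeric(scale(sqrt(freq0)))
    atlas <- make_expression_atlas(cfg, parc, atlas_target)
    ens_cort <- build_spin_ensemble(parc, n_spins = params$n_spins,
                                    seed = cfg$seed + 14L,
                                    scope = "left_cortical")
    opc_set <- gene_set("opc_markers", atlas$gene_sets$opc_markers,
                        "planted synthetic marker set")
    opc_spec <- coexpression_specificity(opc_set, atlas,
                                         n_null = params$n_coexpr_null,
                                         seed = cfg$seed + 15L)
    opc_filt <- filter_gene_set(opc_set, atlas)
    opc_map <- marker_score_map(opc_filt, atlas, parc)
    res$cellorigin$opc <- list(
      specificity = opc_spec,
      removed = attr(opc_filt, "removed"),
      score_map = opc_map$score_map,
      spin = spin_correlation_test(opc_map$score_map,
                                   freq[names(opc_map$score_map)], ens_cort))

    aligned <- align_samples_to_frequency(atlas, raw_map, parc,
                                          fwhm_mm = params$fwhm_mm)
    fit <- fit_pls(aligned, n_components = 2L)
    perm <- permute_pls_significance(aligned, fit, n_perm = params$n_perm,
                                     seed = cfg$seed + 16L)
    ranking <- bootstrap_gene_z(aligned, n_boot = params$n_boot,
                                seed = cfg$seed + 17L)
    driver_set <- gene_set("glioma_drivers", atlas$gene_sets$glioma_drivers,
                           "planted synthetic driver set")
    driver_spec <- coexpression_specificity(driver_set, atlas,
                                            n_null = params$n_coexpr_null,
                                            seed = cfg$seed + 18L)
    driver_filt <- filter_gene_set(driver_set, atlas)
    enrich1 <- rank_enrichment_test(ranking, driver_filt, component = 1L,
                                    n_null = params$n_rank_null,
                                    seed = cfg$seed + 19L)
    enrich2 <- rank_enrichment_test(ranking, driver_filt, component = 2L,
                                    n_null = params$n_rank_null,
                                    seed = cfg$seed + 20L)
    lmap <- map_loadings_to_parcels(fit, aligned, parc)
    res$plstx <- list(fit = fit, permutation = perm, ranking = ranking,
                      driver_specificity = driver_spec,
                      driver_removed = attr(driver_filt, "removed"),
                      enrichment = list(pls1 = enrich1, pls2 = enrich2),
                      loading_maps = lmap)

    opc_full <- stats::setNames(rep(NA_real_, length(freq)), names(freq))
    opc_full[names(opc_map$score_map)] <- opc_map$score_map
    strength <- stats::setNames(hubs$strength, hubs$parcel_id)
    design <- assemble_design(freq, strength, opc_full,
                              stats::setNames(lmap$loadings[, 1],
                                              rownames(lmap$loadings)),
                              stats::setNames(lmap$loadings[, 2],
                                              rownames(lmap$loadings)))
    gate <- fit_glioma_model(design, interactions = TRUE)
    inter_terms <- grep(":", rownames(gate$coefficients), value = TRUE)
    main <- fit_glioma_model(design, interactions = FALSE)
    res$multifactor <- list(
      design = design,
      interaction_gate = list(
        fit = gate,
        significant = inter_terms[gate$coefficients[inter_terms, "p"] < 0.05]),
      fit = main,
      partial_variance = partial_variance(design, main),
      spin_p = predictor_spin_pvalues(design, ens))
  } else {
    res$plstx <- res$multifactor <- "skipped: no expression inputs"
  }

  quantities <- pipeline_quantities(res)
  manifest <- list(
    package_version = as.character(utils::packageVersion("gliotopo")),
    config = unclass(cfg), params = params, seed = cfg$seed,
    stages = names(res),
    quantities = quantities,
    hash = rlang::hash(quantities))
  list(results = res, manifest = manifest, parcellation = parc,
       fields = fields)
}

## flat named list of the pipeline's headline numbers (also used by the
## manifest's reproducibility hash)
pipeline_quantities <- function(res) {
  q <- list(
    split_half_r = res$lesionmap$split_half$r_point,
    split_half_ci_low = res$lesionmap$split_half$ci[1],
    split_half_ci_high = res$lesionmap$split_half$ci[2],
    morans_i = res$spatialnull$morans$I,
    morans_p = res$spatialnull$morans$p,
    nsc_niche_p = res$cellorigin$nsc$p,
    freq_sum = sum(res$lesionmap$freq, na.rm = TRUE))
  for (m in names(res$hubgraph$association)) {
    q[[paste0("hub_", m, "_rho")]] <- res$hubgraph$association[[m]]$rho_observed
    q[[paste0("hub_", m, "_p_spin")]] <- res$hubgraph$association[[m]]$p_spin
  }
  if (is.list(res$plstx)) {
    q$opc_rho <- res$cellorigin$opc$spin$rho_observed
    q$opc_p_spin <- res$cellorigin$opc$spin$p_spin
    q$opc_coexpression_p <- res$cellorigin$opc$specificity$p
    q$pls1_pct_var <- 100 * res$plstx$fit$variance_explained_y[1]
    q$pls2_pct_var <- 100 * res$plstx$fit$variance_explained_y[2]
    q$pls_perm_p <- res$plstx$permutation$p
    q$driver_enrichment_p_pls1 <- res$plstx$enrichment$pls1$p
    q$driver_enrichment_p_pls2 <- res$plstx$enrichment$pls2$p
    q$n_driver_genes_filtered <- length(res$plstx$driver_removed)
    q$adjusted_r2 <- res$multifactor$fit$adj_r_squared
    q$f_statistic <- unname(res$multifactor$fit$f_statistic[1])
    for (p in c("strength", "opc", "pls1", "pls2")) {
      q[[paste0("beta_", p)]] <- res$multifactor$fit$coefficients[p, "beta"]
      q[[paste0("partial_r2_", p)]] <-
        unname(res$multifactor$partial_variance[p])
    }
  }
  q
}

#' Write a run manifest as JSON
#' @param manifest the `manifest` element of [run_pipeline()].
#' @param path output path.
#' @export
write_manifest <- function(manifest, path) {
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
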