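#' Assemble the integrative design table
#'
#' Builds the 167-parcel design for the integrative regression: the
#' response is the z-scored square root of parcel tumour frequency, the
#' predictors (nodal strength, OPC score, PLS1 and PLS2 parcel loadings)
#' are z-scored, and cells that cannot be computed (e.g. subcortical
#' parcels for the OPC score) are filled with zero *after* z-scoring — so
#' filled cells sit at the column mean — and flagged.
#'
#' @param freq parcel tumour frequency (percent, length 167 or named).
#' @param strength,opc,pls1,pls2 predictor parcel vectors on the same index
#'   (`NA` where undefined).
#' @return A `design_table` data frame (`parcel_id`, `y`, `strength`,
#'   `opc`, `pls1`, `pls2`) with a logical `zero_filled` matrix attribute.
#' @export
assemble_design <- function(freq, strength, opc, pls1, pls2) {
  cols <- list(strength = strength, opc = opc, pls1 = pls1, pls2 = pls2)
  n <- length(freq)
  ids <- names(freq) %||% as.character(seq_len(n))
  for (nm in names(cols)) {
    v <- cols[[nm]]
    if (length(v) != n) stop("all vectors must share the 167-parcel index")
    if (!is.null(names(v))) {
      if (!all(ids %in% names(v))) stop("parcel ids do not match")
      cols[[nm]] <- as.numeric(v[ids])
    }
  }
  zcol <- function(v, nm) {
    ok <- !is.na(v)
    if (stats::sd(v[ok]) == 0)
      stop("degenerate-scaling error: constant column ", nm)
    z <- (v - mean(v[ok])) / stats::sd(v[ok])
    z[!ok] <- 0
    z
  }
  y <- zcol(sqrt(pmax(0, as.numeric(freq))), "response")
  mat <- vapply(names(cols), function(nm) zcol(cols[[nm]], nm), numeric(n))
  filled <- cbind(y = is.na(freq),
                  vapply(cols, is.na, logical(n)))
  out <- data.frame(parcel_id = ids, y = y, mat,
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "zero_filled") <- filled
  class(out) <- c("design_table", "data.frame")
  out
}

design_formula <- function(interactions) {
  if (interactions)
    y ~ strength + opc + pls1 + pls2 + strength:opc + strength:pls1 +
      strength:pls2 + opc:pls1 + opc:pls2
  else y ~ strength + opc + pls1 + pls2
}

#' Fit the integrative tumour-frequency regression
#'
#' Ordinary least squares of z-scored sqrt tumour frequency on the four
#' z-scored predictors; with `interactions = TRUE` the five two-way
#' products between the connectomic (strength), cellular (OPC) and genetic
#' (PLS1, PLS2) factors are added. The interaction model serves as a gate:
#' when none of its interaction terms reaches |p| < 0.05 the main-effects
#' model is the reported specification.
#'
#' @param d an [assemble_design()] table.
#' @param interactions include two-way interaction terms?
#' @return A `model_fit`: `coefficients` table (beta, SE, t, p),
#'   `adj_r_squared`, `r_squared`, `f_statistic` (+dof), `lm` (the
#'   underlying fit), `interactions`.
#' @export
fit_glioma_model <- function(d, interactions = FALSE) {
  fm <- stats::lm(design_formula(interactions), data = d)
  if (any(is.na(stats::coef(fm)))) {
    bad <- names(stats::coef(fm))[is.na(stats::coef(fm))]
    stop("collinearity error: rank-deficient design, offending terms: ",
         paste(bad, collapse = ", "))
  }
  s <- summary(fm)
  co <- as.data.frame(s$coefficients)
  names(co) <- c("beta", "se", "t", "p")
  structure(list(coefficients = co, adj_r_squared = s$adj.r.squared,
                 r_squared = s$r.squared,
                 f_statistic = s$fstatistic, lm = fm,
                 interactions = interactions),
            class = "model_fit")
}

#' @export
print.model_fit <- function(x, ...) {
  cat(sprintf("<model_fit> adjusted R^2 = %.3f, F(%d,%d) = %.1f\n",
              x$adj_r_squared, x$f_statistic[2], x$f_statistic[3],
              x$f_statistic[1]))
  print(round(x$coefficients, 4))
  invisible(x)
}

partial_r2_one <- function(d, predictor) {
  others <- setdiff(c("strength", "opc", "pls1", "pls2"), predictor)
  fo <- stats::as.formula(paste("~", paste(others, collapse = "+")))
  ry <- stats::resid(stats::lm(stats::update(fo, y ~ .), data = d))
  rx <- stats::resid(stats::lm(stats::update(fo, paste(predictor, "~ .")),
                               data = d))
  stats::cor(ry, rx)^2
}

#' Per-predictor partial variance explained
#'
#' For each predictor, the squared partial correlation with the response
#' given the other three predictors, expressed in percent.
#'
#' @param d an [assemble_design()] table.
#' @param fit the main-effects [fit_glioma_model()] (used for the t-based
#'   computation; the residualization definition is equivalent).
#' @return Named numeric vector of percentages.
#' @export
partial_variance <- function(d, fit = NULL) {
  preds <- c("strength", "opc", "pls1", "pls2")
  if (is.null(fit)) fit <- fit_glioma_model(d, interactions = FALSE)
  tt <- fit$coefficients[preds, "t"]
  df <- fit$lm$df.residual
  stats::setNames(100 * tt^2 / (tt^2 + df), preds)
}

#' Spin-based significance of each predictor's partial variance
#'
#' For each predictor, compares its observed partial explained variance
#' with a null distribution in which the response map is replaced by
#' spatially contiguous (spun) null tumour frequency maps. P-values are
#' one-sided with the +1 correction and Bonferroni-corrected across the
#' four predictors (configurable).
#'
#' @param d an [assemble_design()] table (parcel ids must match the
#'   ensemble scope).
#' @param ens a [build_spin_ensemble()] on the same parcellation scope.
#' @param correction `"bonferroni"` (default), `"fdr"` or `"none"`.
#' @param spin `"response"` (default, the stated null) or `"predictor"`.
#' @return Data frame: predictor, observed partial R^2 (%), raw and
#'   corrected p.
#' @export
predictor_spin_pvalues <- function(d, ens, correction = c("bonferroni", "fdr", "none"),
                                   spin = c("response", "predictor")) {
  correction <- match.arg(correction)
  spin <- match.arg(spin)
  preds <- c("strength", "opc", "pls1", "pls2")
  if (!all(as.character(ens$parcel_ids) == d$parcel_id))
    stop("design parcel ids do not match the ensemble scope")
  obs <- vapply(preds, function(p) partial_r2_one(d, p), numeric(1))
  perm <- ens$permutations
  raw <- vapply(preds, function(p) {
    others <- setdiff(preds, p)
    fo <- stats::as.formula(paste("~", paste(others, collapse = "+")))
    rx <- stats::resid(stats::lm(stats::update(fo, paste(p, "~ .")), data = d))
    mm <- stats::model.matrix(fo, data = d)
    qrm <- qr(mm)
    null <- vapply(seq_len(ens$n_spins), function(k) {
      v <- if (spin == "response") d$y[perm[k, ]] else NULL
      if (spin == "predictor") {
        dd <- d
        dd[[p]] <- d[[p]][perm[k, ]]
        rxk <- stats::resid(stats::lm(stats::update(fo, paste(p, "~ .")),
                                      data = dd))
        ryk <- stats::resid(stats::lm(stats::update(fo, y ~ .), data = d))
        return(stats::cor(ryk, rxk)^2)
      }
      ry <- qr.resid(qrm, v)
      stats::cor(ry, rx)^2
    }, numeric(1))
    (1 + sum(null >= obs[[p]])) / (1 + ens$n_spins)
  }, numeric(1))
  corrected <- switch(correction,
                      bonferroni = pmin(1, raw * length(preds)),
                      fdr = stats::p.adjust(raw, "fdr"),
                      none = raw)
  data.frame(predictor = preds, partial_r2_percent = 100 * obs,
             p_raw = raw, p_corrected = corrected, row.names = NULL)
}
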