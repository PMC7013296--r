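#' Logistic risk-model fit
#'
#' Maximum-likelihood logistic regression (iteratively reweighted least
#' squares, via `stats::glm`). Complete or quasi-complete separation is
#' flagged — fitted probabilities numerically at 0 or 1 — and the
#' coefficients are still returned with a warning rather than an error.
#'
#' @param design Numeric matrix or data frame of predictors (no intercept
#'   column; one is added).
#' @param outcome Logical / 0-1 vector with both classes present.
#' @return List with `coefficients`, `fitted` (probabilities), `converged`,
#'   `separation` (logical flag), and the underlying `glm` object.
#' @export
logistic_fit <- function(design, outcome) {
  design <- as.matrix(design)
  y <- as.numeric(as.logical(outcome))
  if (nrow(design) != length(y)) stop("dimension mismatch")
  if (nrow(design) <= ncol(design) + 1L) stop("need n > number of predictors")
  if (all(y == 0) || all(y == 1)) stop("outcome must contain both classes")
  if (is.null(colnames(design))) {
    colnames(design) <- paste0("x", seq_len(ncol(design)))
  }
  dat <- data.frame(.y = y, design)
  fit <- suppressWarnings(
    glm(.y ~ ., data = dat, family = binomial(), control = list(maxit = 100))
  )
  p <- fitted(fit)
  sep <- any(p < 1e-8 | p > 1 - 1e-8)
  if (sep) {
    warning("possible separation: fitted probabilities numerically 0 or 1",
            call. = FALSE)
  }
  if (!fit$converged) warning("IRLS did not converge", call. = FALSE)
  list(coefficients = coef(fit), fitted = unname(p),
       converged = fit$converged, separation = sep, glm = fit)
}

#' Net reclassification improvement and integrated discrimination
#' improvement
#'
#' Continuous (category-free) NRI:
#' `NRI = P(up | event) - P(down | event) + P(down | non-event) -
#' P(up | non-event)`, where "up"/"down" means the extended model's
#' predicted probability is strictly greater/less than the base model's.
#' IDI is the increase in discrimination slope: `(mean extended prob in
#' events - in non-events) - (same for base)`. 95% CIs are asymptotic:
#' for the NRI, from the multinomial variance of the up/down proportion
#' difference in each outcome group; for the IDI, from the per-group
#' variances of the individual probability changes. When `thresholds` is
#' supplied, a categorical NRI over the induced risk categories is also
#' returned.
#'
#' @param base_probs,extended_probs Predicted event probabilities in
#'   `[0, 1]` from the base and extended models on the same subjects.
#' @param labels Logical / 0-1 event indicator; both classes present.
#' @param thresholds Optional increasing vector of risk-category bounds for
#'   a categorical NRI.
#' @return Object of class `reclassification_result`: list with `nri`,
#'   `nri_ci`, `idi`, `idi_ci`, per-group components, and optionally
#'   `categorical_nri`.
#' @export
reclassification <- function(base_probs, extended_probs, labels,
                             thresholds = NULL) {
  p0 <- as.numeric(base_probs)
  p1 <- as.numeric(extended_probs)
  ev <- as.logical(labels)
  if (length(p0) != length(p1) || length(p0) != length(ev)) {
    stop("`base_probs`, `extended_probs` and `labels` must have equal length")
  }
  if (any(p0 < 0 | p0 > 1 | p1 < 0 | p1 > 1)) {
    stop("probabilities must lie in [0, 1]")
  }
  if (!any(ev) || all(ev)) stop("both classes must be present")
  n_e <- sum(ev)
  n_ne <- sum(!ev)

  move <- sign(p1 - p0)
  prop_diff <- function(mv) {
    # P(up) - P(down) with multinomial variance
    pu <- mean(mv > 0)
    pd <- mean(mv < 0)
    d <- pu - pd
    list(d = d, var = (pu + pd - d^2) / length(mv))
  }
  ce <- prop_diff(move[ev])
  cne <- prop_diff(move[!ev])
  nri <- ce$d - cne$d
  nri_se <- sqrt(ce$var + cne$var)
  nri_ci <- nri + c(-1, 1) * qnorm(0.975) * nri_se
  nri_p <- if (nri_se > 0) 2 * pnorm(-abs(nri / nri_se)) else NA_real_

  dp <- p1 - p0
  slope_base <- mean(p0[ev]) - mean(p0[!ev])
  slope_ext <- mean(p1[ev]) - mean(p1[!ev])
  idi <- slope_ext - slope_base  # the discrimination-slope identity, exact
  v_e <- if (n_e > 1) var(dp[ev]) / n_e else 0
  v_ne <- if (n_ne > 1) var(dp[!ev]) / n_ne else 0
  idi_se <- sqrt(v_e + v_ne)
  idi_ci <- idi + c(-1, 1) * qnorm(0.975) * idi_se
  idi_p <- if (idi_se > 0) 2 * pnorm(-abs(idi / idi_se)) else NA_real_

  out <- list(
    nri = nri, nri_ci = nri_ci, nri_se = nri_se, nri_p = nri_p,
    idi = idi, idi_ci = idi_ci, idi_se = idi_se, idi_p = idi_p,
    p_up_event = mean(move[ev] > 0), p_down_event = mean(move[ev] < 0),
    p_up_nonevent = mean(move[!ev] > 0),
    p_down_nonevent = mean(move[!ev] < 0),
    slope_base = slope_base,
    slope_extended = slope_ext,
    n_event = n_e, n_nonevent = n_ne
  )
  if (!is.null(thresholds)) {
    br <- c(-Inf, sort(thresholds), Inf)
    k0 <- as.integer(cut(p0, br))
    k1 <- as.integer(cut(p1, br))
    mv <- sign(k1 - k0)
    cce <- prop_diff(mv[ev])
    ccne <- prop_diff(mv[!ev])
    cnri <- cce$d - ccne$d
    cse <- sqrt(cce$var + ccne$var)
    out$categorical_nri <- list(
      nri = cnri, ci = cnri + c(-1, 1) * qnorm(0.975) * cse,
      thresholds = sort(thresholds)
    )
  }
  structure(out, class = "reclassification_result")
}

#' @export
print.reclassification_result <- function(x, ...) {
  cat(sprintf("Continuous NRI: %.3f (95%% CI %.3f to %.3f)\n",
              x$nri, x$nri_ci[1], x$nri_ci[2]))
  cat(sprintf("IDI:            %.3f (95%% CI %.3f to %.3f)\n",
              x$idi, x$idi_ci[1], x$idi_ci[2]))
  if (!is.null(x$categorical_nri)) {
    cat(sprintf("Categorical NRI (cuts %s): %.3f\n",
                paste(x$categorical_nri$thresholds, collapse = ", "),
                x$categorical_nri$nri))
  }
  invisible(x)
}

#' Base vs extended FFR risk models on a lesion cohort
#'
#' Fits the base logistic model (outcome FFR significance, predictor
#' diameter stenosis) and the extended model (diameter stenosis plus
#' MMAR/MLD), and assembles their ROC curves, the correlated-AUC
#' comparison, and the reclassification measures.
#'
#' @param cohort A validated lesion table (see [read_lesion_table()]) with
#'   columns `ds_pct`, `mmar_mld`, `significant`.
#' @return List with `base`, `extended` (logistic fits), `roc_base`,
#'   `roc_extended`, `delong` (AUC comparison), `reclass`.
#' @export
ffr_risk_models <- function(cohort) {
  y <- cohort$significant
  base <- logistic_fit(cbind(ds = cohort$ds_pct), y)
  ext <- logistic_fit(cbind(ds = cohort$ds_pct, mmar_mld = cohort$mmar_mld), y)
  list(
    base = base, extended = ext,
    roc_base = roc_auc(base$fitted, y),
    roc_extended = roc_auc(ext$fitted, y),
    delong = delong_compare(ext$fitted, base$fitted, y),
    reclass = reclassification(base$fitted, ext$fitted, y)
  )
}
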