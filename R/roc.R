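# DeLong structural components via midranks.
# V10[i] = mean_j psi(score_pos_i, score_neg_j), V01[j] = mean_i psi(...),
# psi = 1 if pos > neg, 1/2 if tied, 0 otherwise. Computed in O(n log n)
# from overall and within-class ranks.
delong_components <- function(scores, pos) {
  n1 <- sum(pos)
  n0 <- sum(!pos)
  r_all <- rank(scores, ties.method = "average")
  r_pos <- rank(scores[pos], ties.method = "average")
  r_neg <- rank(scores[!pos], ties.method = "average")
  v10 <- (r_all[pos] - r_pos) / n0
  v01 <- 1 - (r_all[!pos] - r_neg) / n1
  list(v10 = v10, v01 = v01, auc = mean(v10), n_pos = n1, n_neg = n0)
}

#' ROC analysis with DeLong variance
#'
#' The AUC is the tie-adjusted Mann--Whitney statistic: the mean over all
#' (positive, negative) pairs of the indicator that the positive scores
#' higher, counting ties one half. Its variance comes from DeLong's
#' structural components; the 95% CI is formed on the logit scale and
#' back-transformed so the bounds stay inside `[0, 1]`. Degenerate
#' zero-variance cases (e.g. AUC exactly 1) return a point interval with a
#' warning.
#'
#' The threshold table applies the inclusive-`>=` positivity convention:
#' at cut-off `c`, sensitivity is the fraction of positives with score
#' `>= c` and specificity the fraction of negatives with score `< c`.
#'
#' @param scores Numeric classifier scores (higher = more likely positive).
#' @param labels Logical / 0-1 outcome vector; both classes must be present.
#' @return Object of class `roc_delong`: list with `auc`, `var_auc`,
#'   `ci_low`, `ci_high`, `thresholds` (data frame: `cutoff`,
#'   `sensitivity`, `specificity`), `n_pos`, `n_neg`, plus the scores and
#'   labels for downstream cut-off metrics.
#' @references DeLong, DeLong & Clarke-Pearson (1988), Biometrics 44:837-845.
#' @export
roc_auc <- function(scores, labels) {
  pos <- as.logical(labels)
  if (length(scores) != length(pos)) stop("length mismatch")
  ok <- is.finite(scores) & !is.na(pos)
  scores <- scores[ok]; pos <- pos[ok]
  if (!any(pos) || all(pos)) stop("both classes must be present")
  comp <- delong_components(scores, pos)
  var_auc <- var(comp$v10) / comp$n_pos + var(comp$v01) / comp$n_neg
  auc <- comp$auc
  if (is.na(var_auc)) var_auc <- 0
  if (var_auc <= 0 || auc <= 0 || auc >= 1) {
    if (auc %in% c(0, 1) || var_auc == 0) {
      warning("degenerate DeLong variance; returning a point interval",
              call. = FALSE)
    }
    ci <- c(auc, auc)
  } else {
    l <- qlogis(auc)
    se_l <- sqrt(var_auc) / (auc * (1 - auc))
    ci <- plogis(l + c(-1, 1) * qnorm(0.975) * se_l)
  }
  cuts <- sort(unique(scores))
  sens <- vapply(cuts, function(cc) mean(scores[pos] >= cc), 1)
  spec <- vapply(cuts, function(cc) mean(scores[!pos] < cc), 1)
  structure(
    list(auc = auc, var_auc = var_auc,
         ci_low = min(ci), ci_high = max(ci),
         thresholds = data.frame(cutoff = cuts, sensitivity = sens,
                                 specificity = spec),
         n_pos = comp$n_pos, n_neg = comp$n_neg,
         scores = scores, labels = pos),
    class = "roc_delong"
  )
}

#' @export
print.roc_delong <- function(x, ...) {
  cat(sprintf("ROC (DeLong): AUC %.3f (95%% CI %.3f-%.3f), %d pos / %d neg\n",
              x$auc, x$ci_low, x$ci_high, x$n_pos, x$n_neg))
  invisible(x)
}

#' @export
plot.roc_delong <- function(x, add = FALSE, ...) {
  fpr <- c(1, 1 - x$thresholds$specificity, 0)
  tpr <- c(1, x$thresholds$sensitivity, 0)
  if (add) {
    lines(fpr, tpr, ...)
  } else {
    plot(fpr, tpr, type = "l", xlim = c(0, 1), ylim = c(0, 1),
         xlab = "1 - specificity", ylab = "Sensitivity", ...)
    abline(0, 1, lty = 3, col = "grey")
  }
  invisible(x)
}

#' Compare two correlated AUCs (DeLong test)
#'
#' Both classifiers must score the same cases. The z statistic is the AUC
#' difference over the DeLong standard error of the difference, which
#' accounts for the within-case correlation of the structural components.
#' Identical score vectors give `z = 0`, `p = 1`.
#'
#' @param scores_a,scores_b Scores of the two classifiers on the same cases.
#' @param labels Outcome vector; both classes present.
#' @return List with `auc_a`, `auc_b`, `var_a`, `var_b`, `z`, `p_value`.
#' @export
delong_compare <- function(scores_a, scores_b, labels) {
  pos <- as.logical(labels)
  if (length(scores_a) != length(pos) || length(scores_b) != length(pos)) {
    stop("score and label lengths must match (same cases)")
  }
  if (!any(pos) || all(pos)) stop("both classes must be present")
  ca <- delong_components(scores_a, pos)
  cb <- delong_components(scores_b, pos)
  var_a <- var(ca$v10) / ca$n_pos + var(ca$v01) / ca$n_neg
  var_b <- var(cb$v10) / cb$n_pos + var(cb$v01) / cb$n_neg
  var_d <- var(ca$v10 - cb$v10) / ca$n_pos + var(ca$v01 - cb$v01) / ca$n_neg
  d <- ca$auc - cb$auc
  if (var_d <= 0 || is.na(var_d)) {
    z <- 0
    p <- 1
  } else {
    z <- d / sqrt(var_d)
    p <- 2 * pnorm(-abs(z))
  }
  list(auc_a = ca$auc, auc_b = cb$auc, var_a = var_a, var_b = var_b,
       var_diff = var_d, z = z, p_value = p)
}

#' Optimal cut-off and diagnostic metrics
#'
#' Default criterion is Youden's J (`sensitivity + specificity - 1`),
#' maximized over the observed thresholds; ties resolve to the lowest
#' cut-off. The alternative `"closest01"` criterion minimizes the Euclidean
#' distance to the perfect-classification corner (0, 1) in ROC space.
#' Predictive values come from the 2 x 2 table at the chosen cut-off on the
#' same data (inclusive `>=` positivity).
#'
#' @param roc A [roc_auc()] result.
#' @param criterion `"youden"` (default) or `"closest01"`.
#' @return Object of class `cutoff_metrics`: list with `cutoff`,
#'   `sensitivity`, `specificity`, `ppv`, `npv`, `youden`, and the 2 x 2
#'   counts `tp`, `fp`, `fn`, `tn`.
#' @export
youden_cutoff <- function(roc, criterion = c("youden", "closest01")) {
  stopifnot(inherits(roc, "roc_delong"))
  criterion <- match.arg(criterion)
  th <- roc$thresholds
  obj <- switch(criterion,
    youden = th$sensitivity + th$specificity - 1,
    closest01 = -sqrt((1 - th$sensitivity)^2 + (1 - th$specificity)^2)
  )
  best <- which(obj >= max(obj) - 1e-12)
  i <- best[which.min(th$cutoff[best])]
  cut <- th$cutoff[i]
  pred <- roc$scores >= cut
  tp <- sum(pred & roc$labels); fp <- sum(pred & !roc$labels)
  fn <- sum(!pred & roc$labels); tn <- sum(!pred & !roc$labels)
  structure(
    list(cutoff = cut,
         sensitivity = tp / (tp + fn),
         specificity = tn / (tn + fp),
         ppv = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
         npv = if (tn + fn > 0) tn / (tn + fn) else NA_real_,
         youden = tp / (tp + fn) + tn / (tn + fp) - 1,
         tp = tp, fp = fp, fn = fn, tn = tn,
         criterion = criterion),
    class = "cutoff_metrics"
  )
}

#' @export
print.cutoff_metrics <- function(x, ...) {
  cat(sprintf(
    "Cut-off %.3g (%s): sens %.0f%%, spec %.0f%%, PPV %.0f%%, NPV %.0f%%\n",
    x$cutoff, x$criterion, 100 * x$sensitivity, 100 * x$specificity,
    100 * x$ppv, 100 * x$npv))
  invisible(x)
}
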