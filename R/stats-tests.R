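#' Pearson correlation with t-test p-value
#'
#' @param x,y Numeric vectors of equal length (>= 3), neither constant.
#' @return List with `r` (in `[-1, 1]`) and `p_value` (two-sided, from the
#'   t distribution with n - 2 df).
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) stop("`x` and `y` must have equal length")
  ok <- complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) stop("need at least 3 complete pairs")
  if (var(x) == 0 || var(y) == 0) stop("constant input vector")
  ct <- cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p_value = ct$p.value, n = length(x))
}

#' Mann--Whitney U test
#'
#' U counts the pairs `(a_i, b_j)` with `a_i > b_j`, plus half the tied
#' pairs (midrank convention). The p-value is exact (full enumeration) when
#' `length(a) * length(b) <= 400` and there are no ties; otherwise the
#' normal approximation with tie-corrected variance is used, without
#' continuity correction.
#'
#' @param a,b Non-empty numeric vectors (the two groups).
#' @return List with `U` and `p_value` (two-sided).
#' @export
mann_whitney_u <- function(a, b) {
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  if (length(a) == 0L || length(b) == 0L) stop("both groups must be non-empty")
  ties <- anyDuplicated(c(a, b)) > 0L
  exact <- !ties && length(a) * length(b) <= 400
  wt <- suppressWarnings(
    wilcox.test(a, b, exact = exact, correct = FALSE)
  )
  list(U = unname(wt$statistic), p_value = wt$p.value)
}

#' Pearson chi-squared test on a 2 x k contingency table
#'
#' Expected counts are `row * col / total`; no continuity correction is
#' applied (documented convention, matching the large-sample Pearson
#' statistic with k - 1 degrees of freedom for a 2 x k table).
#'
#' @param table Matrix of non-negative counts with positive row and column
#'   sums.
#' @return List with `statistic`, `p_value`, `df`.
#' @export
chi_squared <- function(table) {
  table <- as.matrix(table)
  if (any(table < 0)) stop("counts must be non-negative")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    stop("all row and column marginals must be positive")
  }
  ct <- suppressWarnings(chisq.test(table, correct = FALSE))
  list(statistic = unname(ct$statistic), p_value = ct$p.value,
       df = unname(ct$parameter))
}

#' Group summary: median (Q1--Q3) per group with a Mann--Whitney p-value
#'
#' Quartiles use linear interpolation between order statistics
#' (`quantile(type = 7)`), the convention applied throughout the package so
#' that interquartile ranges are reproducible.
#'
#' @param values Numeric vector.
#' @param group Logical or two-level vector splitting `values`.
#' @return List with a `summary` data frame (one row per group: `n`,
#'   `median`, `q1`, `q3`) and `p_value`.
#' @export
summarize_group <- function(values, group) {
  if (length(values) != length(group)) stop("length mismatch")
  g <- as.factor(group)
  if (nlevels(g) > 2L) stop("`group` must have at most two levels")
  split_vals <- split(values, g)
  if (any(vapply(split_vals, length, 1L) == 0L)) stop("empty group")
  summ <- do.call(rbind, lapply(names(split_vals), function(nm) {
    v <- split_vals[[nm]]
    q <- quantile(v, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
    data.frame(group = nm, n = length(v), median = q[2], q1 = q[1], q3 = q[3])
  }))
  p <- if (nlevels(g) == 2L) {
    mann_whitney_u(split_vals[[1]], split_vals[[2]])$p_value
  } else {
    NA_real_
  }
  list(summary = summ, p_value = p)
}
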