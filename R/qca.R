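#' Percent diameter stenosis
#'
#' Standard quantitative-coronary-angiography definition:
#' `DS = (1 - MLD/RD) * 100`, the percent lumen narrowing of the minimal
#' lumen diameter relative to the reference diameter.
#'
#' @param mld Minimal lumen diameter, mm (> 0). Vectorized.
#' @param rd Reference diameter, mm (>= mld).
#' @return Diameter stenosis in percent, in `[0, 100)`.
#' @export
diameter_stenosis <- function(mld, rd) {
  if (any(!is.finite(mld)) || any(!is.finite(rd)) ||
      any(mld <= 0) || any(rd <= 0)) {
    stop("`mld` and `rd` must be positive and finite (mm)")
  }
  if (any(mld > rd)) stop("`mld` must not exceed `rd`")
  (1 - mld / rd) * 100
}

#' The MMAR/MLD demand-to-supply index
#'
#' Ratio of the myocardial mass at risk (ml) to the minimal lumen diameter
#' (mm) — a surrogate for the ratio of hyperemic myocardial blood-flow
#' demand to supply capacity. Higher values predict functionally
#' significant stenosis (FFR <= 0.8).
#'
#' @param mmar_ml Myocardial mass at risk, ml (>= 0). Vectorized.
#' @param mld Minimal lumen diameter, mm (> 0).
#' @return The index in ml/mm.
#' @export
mmar_mld_ratio <- function(mmar_ml, mld) {
  if (any(!is.finite(mmar_ml)) || any(mmar_ml < 0)) {
    stop("`mmar_ml` must be finite and non-negative (ml)")
  }
  if (any(!is.finite(mld)) || any(mld <= 0)) {
    stop("`mld` must be positive and finite (mm)")
  }
  mmar_ml / mld
}

#' Classify an MMAR/MLD value against a cut-off
#'
#' Predicted positive (functionally significant, FFR <= 0.8 expected) when
#' the value is at or above the cut-off. The tie-at-cut-off convention is
#' inclusive `>=`, applied consistently across the package's ROC and
#' diagnostic-metric computations.
#'
#' @param value MMAR/MLD value(s), ml/mm.
#' @param cutoff Decision cut-off, ml/mm (> 0); 29.5 ml/mm is the reference
#'   whole-cohort operating point.
#' @return Logical vector: predicted significant.
#' @export
classify_mmar_mld <- function(value, cutoff = 29.5) {
  if (!is.numeric(cutoff) || length(cutoff) != 1L || cutoff <= 0) {
    stop("`cutoff` must be a single positive number")
  }
  value >= cutoff
}

lesion_csv_columns <- c("lesion_id", "artery", "proximal", "mld_mm", "rd_mm",
                        "length_mm", "ds_pct", "mmar_ml", "pct_mmar", "ffr")

# Validate a lesion table and fill derived columns (ds recomputed, index,
# significance flag). Shared by the CSV reader and the cohort generator.
validate_lesion_table <- function(df, threshold = 0.8) {
  missing_cols <- setdiff(lesion_csv_columns, names(df))
  if (length(missing_cols)) {
    stop("lesion table missing columns: ", paste(missing_cols, collapse = ", "))
  }
  df$proximal <- as.logical(df$proximal)
  num <- c("mld_mm", "rd_mm", "length_mm", "ds_pct", "mmar_ml", "pct_mmar",
           "ffr")
  for (cc in num) df[[cc]] <- as.numeric(df[[cc]])
  if (any(!df$artery %in% c("RCA", "LAD", "LCx"))) {
    stop("artery labels must be RCA, LAD or LCx")
  }
  with(df, {
    if (any(mld_mm <= 0 | rd_mm <= 0 | mld_mm > rd_mm)) {
      stop("lesion geometry must satisfy 0 < MLD <= RD")
    }
    if (any(length_mm <= 0)) stop("lesion length must be positive")
    if (any(mmar_ml < 0)) stop("MMAR must be non-negative")
    if (any(ffr <= 0 | ffr > 1)) stop("FFR must lie in (0, 1]")
  })
  ds <- diameter_stenosis(df$mld_mm, df$rd_mm)
  if (any(abs(ds - df$ds_pct) > 1)) {
    warning("supplied ds_pct differs from (1 - MLD/RD)*100 by more than 1 ",
            "percentage point for some lesions; recomputed values are used",
            call. = FALSE)
  }
  df$ds_pct <- ds
  df$mmar_mld <- mmar_mld_ratio(df$mmar_ml, df$mld_mm)
  df$significant <- df$ffr <= threshold
  df
}

#' Read / write lesion tables
#'
#' CSV schema: `lesion_id, artery, proximal, mld_mm, rd_mm, length_mm,
#' ds_pct, mmar_ml, pct_mmar, ffr`. On read, invariants are validated,
#' diameter stenosis is recomputed from MLD and RD (with a warning if the
#' supplied value is off by more than one percentage point — rounded
#' published values need not compose exactly), and the derived `mmar_mld`
#' and `significant` (FFR at or below `threshold`) columns are added.
#' The writer emits only the canonical schema columns so that a
#' write--read cycle round-trips the stored text exactly.
#'
#' @param path CSV file path.
#' @param threshold FFR significance threshold (default 0.8).
#' @return `read_lesion_table`: validated data frame with derived columns;
#'   `write_lesion_table`: `path`, invisibly.
#' @export
read_lesion_table <- function(path, threshold = 0.8) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  validate_lesion_table(df, threshold = threshold)
}

#' @rdname read_lesion_table
#' @param df A lesion table (extra derived columns are dropped on write).
#' @export
write_lesion_table <- function(df, path) {
  out <- df[lesion_csv_columns]
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
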