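#' Study configuration
#'
#' Single configuration object for the end-to-end pipeline. In `synthetic`
#' mode the shell, tree, lesion and FFR parameter blocks define the cohort;
#' in `files` mode `lesion_csv` must point to a lesion table in the
#' canonical CSV schema. CLI flags and the JSON config file both populate
#' this object.
#'
#' @param mode `"synthetic"` or `"files"`.
#' @param n_lesions Cohort size (synthetic mode).
#' @param seed Integer run seed (required in synthetic mode).
#' @param threshold FFR significance threshold, in `(0, 1)`.
#' @param shell,tree,lesion,ffr Parameter blocks (see [lv_shell_params()],
#'   [tree_params()], [lesion_params()], [ffr_model_params()]).
#' @param lesion_csv Path to a lesion CSV (files mode).
#' @param min_class Minimum positives and negatives for a subgroup ROC row
#'   to be reported rather than flagged (small-sample guard).
#' @return List of class `study_config`.
#' @export
study_config <- function(mode = c("synthetic", "files"),
                         n_lesions = 300, seed = 1, threshold = 0.8,
                         shell = lv_shell_params(), tree = tree_params(),
                         lesion = lesion_params(), ffr = ffr_model_params(),
                         lesion_csv = NULL, min_class = 5L) {
  mode <- match.arg(mode)
  stopifnot(threshold > 0, threshold < 1, min_class >= 2)
  if (mode == "synthetic" && (is.null(seed) || !is.finite(seed))) {
    stop("synthetic mode requires a seed")
  }
  if (mode == "files" && is.null(lesion_csv)) {
    stop("files mode requires `lesion_csv`")
  }
  structure(list(mode = mode, n_lesions = n_lesions, seed = as.integer(seed),
                 threshold = threshold, shell = shell, tree = tree,
                 lesion = lesion, ffr = ffr, lesion_csv = lesion_csv,
                 min_class = as.integer(min_class)),
            class = "study_config")
}

#' Subgroup slices of a lesion cohort
#'
#' Returns the analysis subsets used in the reports: overall, per artery,
#' and the proximal / non-proximal split of the LAD. The three artery
#' slices partition the cohort, as do the two LAD sub-slices within the
#' LAD.
#'
#' @param cohort A validated lesion table.
#' @return Named list of data frames.
#' @export
subgroup_slices <- function(cohort) {
  if (!all(cohort$artery %in% c("RCA", "LAD", "LCx"))) {
    stop("unknown artery label in cohort")
  }
  list(
    overall = cohort,
    RCA = cohort[cohort$artery == "RCA", , drop = FALSE],
    LAD = cohort[cohort$artery == "LAD", , drop = FALSE],
    LCx = cohort[cohort$artery == "LCx", , drop = FALSE],
    LAD_proximal = cohort[cohort$artery == "LAD" & cohort$proximal, ,
                          drop = FALSE],
    LAD_nonproximal = cohort[cohort$artery == "LAD" & !cohort$proximal, ,
                             drop = FALSE]
  )
}

# One ROC-table row for a score on a cohort slice; flagged (NA metrics)
# when either class has fewer than min_class members.
roc_table_row <- function(slice, score_col, name, min_class) {
  y <- slice$significant
  n_pos <- sum(y)
  n_neg <- sum(!y)
  base <- data.frame(subgroup = name, score = score_col,
                     n = nrow(slice), n_pos = n_pos, n_neg = n_neg)
  if (n_pos < min_class || n_neg < min_class) {
    return(cbind(base, data.frame(
      available = FALSE, auc = NA_real_, ci_low = NA_real_,
      ci_high = NA_real_, cutoff = NA_real_, sensitivity = NA_real_,
      specificity = NA_real_, ppv = NA_real_, npv = NA_real_)))
  }
  roc <- roc_auc(slice[[score_col]], y)
  cm <- youden_cutoff(roc)
  cbind(base, data.frame(
    available = TRUE, auc = roc$auc, ci_low = roc$ci_low,
    ci_high = roc$ci_high, cutoff = cm$cutoff,
    sensitivity = cm$sensitivity, specificity = cm$specificity,
    ppv = cm$ppv, npv = cm$npv))
}

#' Run the full study emulation
#'
#' Generates (or loads) the lesion cohort and produces the report battery:
#' a group-comparison table of each variable by FFR significance, a
#' correlation table of every index against FFR (with MMAR/MLD also per
#' subgroup), a ROC table (MMAR/MLD per subgroup plus diameter stenosis
#' overall, each with DeLong CI and Youden operating point), and the
#' reclassification comparison of the base (diameter stenosis) versus
#' extended (diameter stenosis + MMAR/MLD) logistic risk models.
#' Deterministic given the configuration. When a slice has fewer than two
#' lesions in either FFR class, its ROC/reclassification entries are
#' flagged unavailable and the run continues.
#'
#' @param config A [study_config()].
#' @return Object of class `ffr_study`: list with `config`, `cohort`,
#'   `group_table`, `correlation_table`, `roc_table`, `models`
#'   (see [ffr_risk_models()]), and `reclass_available`.
#' @export
run_study <- function(config = study_config()) {
  stopifnot(inherits(config, "study_config"))
  cohort <- if (config$mode == "synthetic") {
    mask <- generate_lv_shell(config$shell)
    set.seed(config$seed)
    tree <- generate_coronary_tree(mask, config$tree)
    generate_cohort(config$n_lesions, mask, tree, config$lesion, config$ffr,
                    seed = config$seed + 1L, threshold = config$threshold)
  } else {
    read_lesion_table(config$lesion_csv, threshold = config$threshold)
  }
  if (nrow(cohort) < 2L) stop("cohort must contain at least 2 lesions")

  vars <- c(ffr = "FFR", ds_pct = "DS (%)", rd_mm = "RD (mm)",
            mld_mm = "MLD (mm)", length_mm = "Length (mm)",
            mmar_ml = "MMAR (ml)", pct_mmar = "%MMAR",
            mmar_mld = "MMAR/MLD (ml/mm)")
  two_class <- length(unique(cohort$significant)) == 2L
  group_table <- do.call(rbind, lapply(names(vars), function(v) {
    all_q <- quantile(cohort[[v]], c(0.25, 0.5, 0.75), type = 7,
                      names = FALSE)
    row <- data.frame(variable = vars[[v]],
                      median_all = all_q[2], q1_all = all_q[1],
                      q3_all = all_q[3])
    if (two_class) {
      sg <- summarize_group(cohort[[v]], cohort$significant)
      pos <- sg$summary[sg$summary$group == "TRUE", ]
      neg <- sg$summary[sg$summary$group == "FALSE", ]
      cbind(row, data.frame(
        median_sig = pos$median, q1_sig = pos$q1, q3_sig = pos$q3,
        median_nonsig = neg$median, q1_nonsig = neg$q1, q3_nonsig = neg$q3,
        p_value = sg$p_value))
    } else {
      cbind(row, data.frame(median_sig = NA_real_, q1_sig = NA_real_,
                            q3_sig = NA_real_, median_nonsig = NA_real_,
                            q1_nonsig = NA_real_, q3_nonsig = NA_real_,
                            p_value = NA_real_))
    }
  }))
  rownames(group_table) <- NULL

  slices <- subgroup_slices(cohort)
  cor_vars <- c("mld_mm", "ds_pct", "rd_mm", "length_mm", "mmar_ml",
                "pct_mmar", "mmar_mld")
  correlation_table <- do.call(rbind, c(
    lapply(cor_vars, function(v) {
      if (var(cohort[[v]]) > 0 && var(cohort$ffr) > 0) {
        pr <- pearson_r(cohort[[v]], cohort$ffr)
        data.frame(subgroup = "overall", variable = v, n = pr$n, r = pr$r,
                   p_value = pr$p_value)
      } else {
        data.frame(subgroup = "overall", variable = v, n = nrow(cohort),
                   r = NA_real_, p_value = NA_real_)
      }
    }),
    lapply(setdiff(names(slices), "overall"), function(nm) {
      sl <- slices[[nm]]
      if (nrow(sl) >= 3 && var(sl$mmar_mld) > 0 && var(sl$ffr) > 0) {
        pr <- pearson_r(sl$mmar_mld, sl$ffr)
        data.frame(subgroup = nm, variable = "mmar_mld", n = pr$n, r = pr$r,
                   p_value = pr$p_value)
      } else {
        data.frame(subgroup = nm, variable = "mmar_mld", n = nrow(sl),
                   r = NA_real_, p_value = NA_real_)
      }
    })
  ))
  rownames(correlation_table) <- NULL

  roc_table <- do.call(rbind, c(
    lapply(names(slices), function(nm) {
      roc_table_row(slices[[nm]], "mmar_mld", nm, config$min_class)
    }),
    list(roc_table_row(cohort, "ds_pct", "overall", config$min_class))
  ))
  rownames(roc_table) <- NULL

  reclass_available <- sum(cohort$significant) >= 2 &&
    sum(!cohort$significant) >= 2
  models <- if (reclass_available) ffr_risk_models(cohort) else NULL

  structure(list(config = config, cohort = cohort,
                 group_table = group_table,
                 correlation_table = correlation_table,
                 roc_table = roc_table,
                 models = models,
                 reclass_available = reclass_available),
            class = "ffr_study")
}

#' @export
print.ffr_study <- function(x, ...) {
  cat("FFR discrimination study:", nrow(x$cohort), "lesions,",
      sum(x$cohort$significant), "with FFR <=", x$config$threshold, "\n")
  ov <- x$roc_table[x$roc_table$subgroup == "overall" &
                      x$roc_table$score == "mmar_mld", ]
  if (nrow(ov) && isTRUE(ov$available)) {
    cat(sprintf(
      "  MMAR/MLD AUC %.3f (95%% CI %.3f-%.3f), cut-off %.1f ml/mm\n",
      ov$auc, ov$ci_low, ov$ci_high, ov$cutoff))
  }
  if (x$reclass_available) {
    rc <- x$models$reclass
    cat(sprintf(
      "  base AUC %.3f -> extended AUC %.3f; NRI %.3f, IDI %.3f\n",
      x$models$roc_base$auc, x$models$roc_extended$auc, rc$nri, rc$idi))
  } else {
    cat("  ROC/reclassification unavailable (degenerate outcome classes)\n")
  }
  invisible(x)
}

#' @export
summary.ffr_study <- function(object, ...) {
  cat("Group comparison (median [Q1-Q3] by FFR significance):\n")
  gt <- object$group_table
  for (i in seq_len(nrow(gt))) {
    cat(sprintf("  %-18s %.2f [%.2f-%.2f]", gt$variable[i],
                gt$median_all[i], gt$q1_all[i], gt$q3_all[i]))
    if (!is.na(gt$p_value[i])) cat(sprintf("  p=%.3g", gt$p_value[i]))
    cat("\n")
  }
  cat("\nCorrelations with FFR (overall):\n")
  ct <- object$correlation_table
  ov <- ct[ct$subgroup == "overall", ]
  for (i in seq_len(nrow(ov))) {
    cat(sprintf("  %-10s r = %+.2f (p = %.3g)\n", ov$variable[i], ov$r[i],
                ov$p_value[i]))
  }
  print(object)
  invisible(object)
}

#' @export
plot.ffr_study <- function(x, ...) {
  op <- par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(par(op))
  plot(x$cohort$mmar_mld, x$cohort$ffr,
       pch = ifelse(x$cohort$significant, 19, 1),
       xlab = "MMAR/MLD (ml/mm)", ylab = "FFR", main = "Index vs FFR")
  abline(h = x$config$threshold, lty = 2)
  if (x$reclass_available) {
    plot(x$models$roc_extended, main = "ROC: base vs extended")
    plot(x$models$roc_base, add = TRUE, lty = 2)
    legend("bottomright", lty = c(1, 2), bty = "n",
           legend = c(sprintf("DS + MMAR/MLD (AUC %.2f)",
                              x$models$roc_extended$auc),
                      sprintf("DS alone (AUC %.2f)", x$models$roc_base$auc)))
  }
  invisible(x)
}

#' Write study report tables
#'
#' Emits `cohort.csv`, `group_comparison.csv`, `correlations.csv`,
#' `roc.csv`, `reclassification.csv` and `run_info.json` (seed, parameters,
#' package version) into `dir`. Output is deterministic: identical
#' configurations produce byte-identical files.
#'
#' @param study A [run_study()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study_report <- function(study, dir) {
  stopifnot(inherits(study, "ffr_study"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_lesion_table(study$cohort, file.path(dir, "cohort.csv"))
  write.csv(study$group_table, file.path(dir, "group_comparison.csv"),
            row.names = FALSE)
  write.csv(study$correlation_table, file.path(dir, "correlations.csv"),
            row.names = FALSE)
  write.csv(study$roc_table, file.path(dir, "roc.csv"), row.names = FALSE)
  rc <- if (study$reclass_available) {
    m <- study$models
    data.frame(
      available = TRUE,
      base_auc = m$roc_base$auc, base_ci_low = m$roc_base$ci_low,
      base_ci_high = m$roc_base$ci_high,
      extended_auc = m$roc_extended$auc,
      extended_ci_low = m$roc_extended$ci_low,
      extended_ci_high = m$roc_extended$ci_high,
      delong_p = m$delong$p_value,
      nri = m$reclass$nri, nri_ci_low = m$reclass$nri_ci[1],
      nri_ci_high = m$reclass$nri_ci[2], nri_p = m$reclass$nri_p,
      idi = m$reclass$idi, idi_ci_low = m$reclass$idi_ci[1],
      idi_ci_high = m$reclass$idi_ci[2], idi_p = m$reclass$idi_p)
  } else {
    data.frame(available = FALSE)
  }
  write.csv(rc, file.path(dir, "reclassification.csv"), row.names = FALSE)
  cfg <- study$config
  jsonlite::write_json(
    list(mode = cfg$mode, n_lesions = cfg$n_lesions, seed = cfg$seed,
         threshold = cfg$threshold,
         shell = unclass(cfg$shell), tree = unclass(cfg$tree),
         lesion = unclass(cfg$lesion), ffr = unclass(cfg$ffr),
         package_version = as.character(utils::packageVersion("mmarisk"))),
    file.path(dir, "run_info.json"), auto_unbox = TRUE, digits = NA,
    null = "null")
  invisible(dir)
}

#' Read a study configuration from a JSON file
#'
#' Recognized top-level keys mirror the [study_config()] arguments; the
#' parameter blocks accept the same fields as their constructors. Omitted
#' fields fall back to the defaults.
#'
#' @param path JSON file path.
#' @return A [study_config()].
#' @export
read_study_config <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  build <- function(ctor, block) {
    if (is.null(block)) return(ctor())
    do.call(ctor, block)
  }
  study_config(
    mode = if (is.null(doc$mode)) "synthetic" else doc$mode,
    n_lesions = if (is.null(doc$n_lesions)) 300 else doc$n_lesions,
    seed = if (is.null(doc$seed)) 1 else doc$seed,
    threshold = if (is.null(doc$threshold)) 0.8 else doc$threshold,
    shell = build(lv_shell_params, doc$shell),
    tree = build(tree_params, doc$tree),
    lesion = build(lesion_params, doc$lesion),
    ffr = build(ffr_model_params, doc$ffr),
    lesion_csv = doc$lesion_csv,
    min_class = if (is.null(doc$min_class)) 5L else doc$min_class
  )
}
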