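#' Nearest-sample Voronoi assignment of myocardium voxels
#'
#' Labels every foreground voxel with the id of the centerline sample that
#' minimizes the Euclidean distance (world mm) between the voxel center and
#' the sample position. Background voxels carry the sentinel `0`. Ties are
#' broken toward the lowest sample id; at floating-point precision this is a
#' measure-zero event.
#'
#' @param mask A [myocardium_mask()] with at least one foreground voxel.
#' @param stree A [densify_centerline()] result with at least one sample.
#' @return Integer 3D array of the mask's dimensions; sample id per
#'   foreground voxel, `0` elsewhere.
#' @export
assign_voxels <- function(mask, stree) {
  stopifnot(inherits(mask, "myocardium_mask"), inherits(stree, "sampled_tree"))
  fg <- which(mask$grid)
  if (length(fg) == 0L) stop("mask has no foreground voxels")
  seeds <- as.matrix(stree$samples[c("x", "y", "z")])
  if (nrow(seeds) == 0L) stop("sampled tree has no samples")
  labels <- array(0L, dim = dim(mask$grid))
  labels[fg] <- nearest_seed(voxel_centers(mask, fg), seeds)
  labels
}

#' Myocardial mass at risk from a territory label map
#'
#' Sums the volume of foreground voxels whose nearest-sample label lies in
#' the distal sample set of a lesion. Volumes are in ml (voxel count times
#' voxel volume); `%MMAR` is the percentage of the total LV myocardial
#' volume. An empty distal set is valid and yields 0 ml.
#'
#' @param labels Label array from [assign_voxels()] computed on `mask`.
#' @param distal_sample_ids Integer vector of sample ids
#'   (from [distal_sample_set()]).
#' @param mask The [myocardium_mask()] the labels were computed on.
#' @param density_g_per_ml Optional myocardial density; when supplied, the
#'   returned list also carries `mmar_g = mmar_ml * density`. The
#'   conventional value is 1.05 g/ml; masses are not reported by default.
#' @return List with `mmar_ml`, `pct_mmar`, `total_lv_ml` (and `mmar_g` when
#'   a density is given).
#' @export
compute_mmar <- function(labels, distal_sample_ids, mask,
                         density_g_per_ml = NULL) {
  stopifnot(inherits(mask, "myocardium_mask"))
  if (!identical(dim(labels), dim(mask$grid))) {
    stop("`labels` must match the mask grid dimensions")
  }
  fg_labels <- labels[mask$grid]
  n_total <- length(fg_labels)
  if (n_total == 0L) stop("mask has no foreground voxels")
  v <- voxel_volume_ml(mask)
  n_distal <- sum(fg_labels %in% as.integer(distal_sample_ids))
  out <- list(
    mmar_ml = n_distal * v,
    pct_mmar = 100 * n_distal / n_total,
    total_lv_ml = n_total * v
  )
  if (!is.null(density_g_per_ml)) {
    out$mmar_g <- out$mmar_ml * density_g_per_ml
  }
  out
}

#' Myocardial mass at risk for a lesion point
#'
#' Convenience composition: densify the tree, resolve the lesion's distal
#' sample set, Voronoi-assign the myocardium voxels, and summarize MMAR.
#' Deterministic given its inputs.
#'
#' @param mask A [myocardium_mask()].
#' @param tree A [centerline_tree()].
#' @param lesion A [lesion_point()].
#' @param max_spacing Densification step, mm; defaults to half the smallest
#'   voxel spacing so that seed density sits below grid resolution.
#' @param labels,stree Optional precomputed [assign_voxels()] label array
#'   and its [densify_centerline()] tree, to amortize the tessellation over
#'   many lesions on the same geometry.
#' @return An object of class `territory_result`: list with `labels`,
#'   `mmar_ml`, `pct_mmar`, `total_lv_ml`, `distal_sample_ids`, `stree`,
#'   `lesion`.
#' @export
mmar_for_lesion <- function(mask, tree, lesion, max_spacing = NULL,
                            labels = NULL, stree = NULL) {
  if (is.null(max_spacing)) max_spacing <- 0.5 * min(mask$spacing)
  if (is.null(stree)) stree <- densify_centerline(tree, max_spacing)
  if (is.null(labels)) labels <- assign_voxels(mask, stree)
  distal <- distal_sample_set(stree, lesion)
  mm <- compute_mmar(labels, distal, mask)
  structure(
    c(list(labels = labels, distal_sample_ids = distal,
           stree = stree, lesion = lesion), mm),
    class = "territory_result"
  )
}

#' @export
print.territory_result <- function(x, ...) {
  cat("Myocardial territory for lesion on", x$lesion$artery, "\n")
  cat(sprintf("  MMAR: %.1f ml (%.1f%% of %.1f ml LV)\n",
              x$mmar_ml, x$pct_mmar, x$total_lv_ml))
  cat("  distal samples:", length(x$distal_sample_ids), "\n")
  invisible(x)
}

#' Export a territory label volume
#'
#' Writes the label array as NIfTI plus a JSON map from sample id to
#' (artery, branch), so labels remain interpretable outside the session.
#'
#' @param result A [mmar_for_lesion()] result.
#' @param mask The mask the labels were computed on.
#' @param nifti_path,json_path Output paths.
#' @return `nifti_path`, invisibly.
#' @export
write_territory <- function(result, mask, nifti_path, json_path) {
  stopifnot(inherits(result, "territory_result"))
  write_mask_nifti(mask, nifti_path, data = result$labels)
  s <- result$stree$samples
  jsonlite::write_json(
    list(samples = data.frame(sample_id = s$sample_id, artery = s$artery,
                              branch = s$branch),
         distal_sample_ids = result$distal_sample_ids),
    json_path, auto_unbox = TRUE, digits = NA
  )
  invisible(nifti_path)
}
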