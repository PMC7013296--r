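# Shared fixtures, built in code.

# Straight single-artery tree along +x from the origin.
straight_tree <- function(len = 10, artery = "LAD") {
  centerline_tree(data.frame(
    id = 1:2, x = c(0, len), y = 0, z = 0,
    parent = c(NA, 1L), artery = artery, branch = "main"
  ))
}

# Y-shaped tree: trunk 1->2 along x, daughters 2->3 and 2->4.
y_tree <- function() {
  centerline_tree(data.frame(
    id = 1:4,
    x = c(0, 10, 16, 16),
    y = c(0, 0, 5, -5),
    z = 0,
    parent = c(NA, 1L, 2L, 2L),
    artery = "LAD",
    branch = c("main", "main", "main", "side1")
  ))
}

# Rectangular slab mask: nx x ny x nz voxels of the given spacing.
slab_mask <- function(nx = 20, ny = 10, nz = 8, spacing = 1) {
  myocardium_mask(array(TRUE, dim = c(nx, ny, nz)),
                  spacing = rep(spacing, 3),
                  origin = rep(spacing / 2, 3))
}

# Two straight parallel vessels along opposite x-faces of a slab, spanning
# its full y extent.
two_vessel_tree <- function(nx = 20, ny = 10, spacing = 1) {
  ylo <- spacing / 2
  yhi <- (ny - 0.5) * spacing
  centerline_tree(data.frame(
    id = 1:4,
    x = c(0, 0, nx * spacing, nx * spacing),
    y = c(ylo, yhi, ylo, yhi),
    z = 0,
    parent = c(NA, 1L, NA, 3L),
    artery = c("LAD", "LAD", "RCA", "RCA"),
    branch = "main"
  ))
}

# Independent brute-force nearest-seed oracle: full distance matrix in R,
# ties to the lowest seed index (which.min convention).
brute_nearest <- function(pts, seeds) {
  apply(pts, 1, function(p) {
    d2 <- colSums((t(seeds) - p)^2)
    which.min(d2)
  })
}

# Independent AUC oracle: exhaustive pair counting with half-credit ties.
pair_count_auc <- function(scores, labels) {
  pos <- scores[as.logical(labels)]
  neg <- scores[!as.logical(labels)]
  tot <- 0
  for (p in pos) for (q in neg) {
    tot <- tot + (p > q) + 0.5 * (p == q)
  }
  tot / (length(pos) * length(neg))
}

# Small synthetic study geometry shared by the pipeline tests (coarse grid
# to keep unit tests quick; acceptance tests use the default resolution).
coarse_geometry <- function(seed = 1) {
  mask <- generate_lv_shell(lv_shell_params(spacing_mm = 2))
  set.seed(seed)
  tree <- generate_coronary_tree(mask)
  list(mask = mask, tree = tree)
}
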