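test_that("single seed claims all foreground; background keeps sentinel", {
  mask <- slab_mask(6, 5, 4)
  mask$grid[1, 1, 1] <- FALSE
  tree <- straight_tree(len = 1)
  st <- densify_centerline(tree, 5)  # endpoints only
  st$samples <- st$samples[1, , drop = FALSE]  # a single seed
  lab <- assign_voxels(mask, st)
  expect_true(all(lab[mask$grid] == 1L))
  expect_equal(lab[1, 1, 1], 0L)
})

test_that("voxel strictly closer to one seed gets that seed's label", {
  # seeds at world x = 0 and x = 10; voxel centered at x = 4 on their axis
  mask <- myocardium_mask(array(TRUE, c(1, 1, 1)), spacing = c(1, 1, 1),
                          origin = c(4, 0, 0))
  tree <- centerline_tree(data.frame(
    id = 1:2, x = c(0, 10), y = 0, z = 0, parent = c(NA, 1L),
    artery = "LAD", branch = "main"))
  st <- densify_centerline(tree, 20)
  lab <- assign_voxels(mask, st)
  near <- st$samples$sample_id[st$samples$x == 0]
  expect_equal(lab[1, 1, 1], near)
})

test_that("assignment matches the brute-force nearest-neighbor oracle", {
  set.seed(42)
  for (rep in 1:25) {
    dims <- sample(4:12, 3, replace = TRUE)
    grid <- array(runif(prod(dims)) < 0.6, dim = dims)
    if (!any(grid)) grid[1] <- TRUE
    spacing <- runif(3, 0.5, 2)
    origin <- runif(3, -5, 5)
    mask <- myocardium_mask(grid, spacing, origin)
    m <- sample(2:20, 1)
    seeds <- cbind(runif(m, -5, 15), runif(m, -5, 15), runif(m, -5, 15))
    st <- list(samples = data.frame(
      sample_id = seq_len(m), x = seeds[, 1], y = seeds[, 2], z = seeds[, 3],
      pred = c(NA_integer_, seq_len(m - 1)), artery = "LAD",
      branch = "main", from_node = 1L, to_node = 1L,
      arc = seq_len(m) - 1))
    class(st) <- "sampled_tree"
    lab <- assign_voxels(mask, st)
    fg <- which(mask$grid)
    oracle <- brute_nearest(mmarisk:::voxel_centers(mask, fg), seeds)
    expect_identical(lab[fg], as.integer(oracle))
  }
})

test_that("MMAR volumes follow voxel counting and the half-plane oracle", {
  mask <- slab_mask(20, 10, 8)
  tree <- two_vessel_tree(20, 10)
  st <- densify_centerline(tree, 0.5)
  lab <- assign_voxels(mask, st)

  lad <- distal_sample_set(st, lesion_point("LAD", node_id = 1))
  mm <- compute_mmar(lab, lad, mask)
  expect_equal(mm$total_lv_ml, 20 * 10 * 8 / 1000)
  # vessels hug opposite faces: territory boundary is the midplane,
  # within one voxel layer
  half <- mm$total_lv_ml / 2
  layer <- 10 * 8 * 1 / 1000
  expect_lt(abs(mm$mmar_ml - half), layer + 1e-12)
  expect_equal(mm$pct_mmar, 100 * mm$mmar_ml / mm$total_lv_ml)

  # empty distal set is valid and gives zero
  zero <- compute_mmar(lab, integer(0), mask)
  expect_equal(zero$mmar_ml, 0)
  expect_equal(zero$pct_mmar, 0)

  # whole-organ territory for a single-artery model
  solo <- slab_mask(8, 6, 4)
  solo_tree <- straight_tree(len = 8)
  res <- mmar_for_lesion(solo, solo_tree, lesion_point("LAD", node_id = 1))
  expect_equal(res$mmar_ml, total_volume_ml(solo))
  expect_equal(res$pct_mmar, 100)
})

test_that("composition equals running the four stages manually", {
  mask <- slab_mask(20, 10, 8)
  tree <- two_vessel_tree(20, 10)
  les <- lesion_point("LAD", branch = "main", arc_mm = 3)
  res <- mmar_for_lesion(mask, tree, les, max_spacing = 0.5)

  st <- densify_centerline(tree, 0.5)
  lab <- assign_voxels(mask, st)
  manual <- compute_mmar(lab, distal_sample_set(st, les), mask)
  expect_equal(res$mmar_ml, manual$mmar_ml)
  expect_equal(res$pct_mmar, manual$pct_mmar)
  expect_identical(res$labels, lab)
})

test_that("distal sets nest and MMAR is monotone along a branch", {
  geo <- coarse_geometry(seed = 3)
  st <- densify_centerline(geo$tree, 1)
  lab <- assign_voxels(geo$mask, st)
  s <- st$samples
  for (artery in c("LAD", "RCA")) {
    blen <- max(s$arc[s$artery == artery & s$branch == "main"])
    arcs <- seq(0, blen, length.out = 8)
    prev_set <- NULL
    prev_mmar <- Inf
    for (a in arcs) {
      les <- lesion_point(artery, branch = "main", arc_mm = a)
      dset <- distal_sample_set(st, les)
      mm <- compute_mmar(lab, dset, geo$mask)
      if (!is.null(prev_set)) {
        expect_true(all(dset %in% prev_set))
        expect_lte(mm$mmar_ml, prev_mmar)
      }
      prev_set <- dset
      prev_mmar <- mm$mmar_ml
    }
  }
})

test_that("ostial territories of the three arteries partition the LV", {
  geo <- coarse_geometry(seed = 5)
  st <- densify_centerline(geo$tree, 1)
  lab <- assign_voxels(geo$mask, st)
  pct <- vapply(c("RCA", "LAD", "LCx"), function(a) {
    compute_mmar(lab, distal_sample_set(st, lesion_point(a, branch = "main",
                                                         arc_mm = 0)),
                 geo$mask)$pct_mmar
  }, 1)
  expect_equal(sum(pct), 100)
  # per-sample conservation: label counts sum to the foreground exactly
  counts <- tabulate(lab[geo$mask$grid], nbins = nrow(st$samples))
  expect_identical(sum(counts), sum(geo$mask$grid))
})

test_that("territory export writes a readable label volume and sample map", {
  mask <- slab_mask(8, 6, 4)
  tree <- two_vessel_tree(8, 6)
  res <- mmar_for_lesion(mask, tree, lesion_point("LAD", node_id = 1))
  nii <- withr::local_tempfile(fileext = ".nii.gz")
  js <- withr::local_tempfile(fileext = ".json")
  write_territory(res, mask, nii, js)
  img <- RNifti::readNifti(nii)
  expect_equal(array(as.integer(img), dim(res$labels)), res$labels)
  meta <- jsonlite::fromJSON(js)
  expect_setequal(meta$distal_sample_ids, res$distal_sample_ids)
})

test_that("NIfTI mask round-trip preserves grid, spacing and origin", {
  mask <- slab_mask(7, 5, 3, spacing = 0.8)
  path <- withr::local_tempfile(fileext = ".nii.gz")
  write_mask_nifti(mask, path)
  back <- read_myocardium_mask(path)
  expect_identical(back$grid, mask$grid)
  expect_equal(back$spacing, mask$spacing, tolerance = 1e-6)
  expect_equal(back$origin, mask$origin, tolerance = 1e-6)
})

test_that("halving voxel spacing changes slab MMAR by under 2 percent", {
  tree <- two_vessel_tree(20, 10)
  les <- lesion_point("LAD", branch = "main", arc_mm = 0)
  m1 <- mmar_for_lesion(slab_mask(20, 10, 8, spacing = 1), tree, les)
  m2 <- mmar_for_lesion(slab_mask(40, 20, 16, spacing = 0.5), tree, les)
  expect_lt(abs(m2$mmar_ml - m1$mmar_ml) / m1$mmar_ml, 0.02)
})

test_that("densification below voxel spacing is resolution-sufficient", {
  mask <- slab_mask(20, 10, 8)
  tree <- two_vessel_tree(20, 10)
  les <- lesion_point("LAD", branch = "main", arc_mm = 3)
  a <- mmar_for_lesion(mask, tree, les, max_spacing = 0.5)$mmar_ml
  b <- mmar_for_lesion(mask, tree, les, max_spacing = 0.25)$mmar_ml
  expect_lt(abs(b - a) / a, 0.01)
})
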