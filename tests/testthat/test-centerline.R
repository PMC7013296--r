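test_that("centerline validation rejects malformed trees", {
  ok <- data.frame(id = 1:2, x = c(0, 5), y = 0, z = 0,
                   parent = c(NA, 1L), artery = "LAD", branch = "main")
  expect_s3_class(centerline_tree(ok), "centerline_tree")

  bad_parent <- ok; bad_parent$parent <- c(NA, 99L)
  expect_error(centerline_tree(bad_parent), "parent")

  cyc <- data.frame(id = 1:2, x = c(0, 5), y = 0, z = 0,
                    parent = c(2L, 1L), artery = "LAD", branch = "main")
  expect_error(centerline_tree(cyc), "cycle")

  mixed <- data.frame(id = 1:2, x = c(0, 5), y = 0, z = 0,
                      parent = c(NA, 1L), artery = c("LAD", "RCA"),
                      branch = "main")
  expect_error(centerline_tree(mixed), "constant")

  nonfin <- ok; nonfin$x[2] <- NaN
  expect_error(centerline_tree(nonfin), "finite")

  two_roots <- data.frame(id = 1:2, x = c(0, 5), y = 0, z = 0,
                          parent = NA_integer_, artery = "LAD",
                          branch = "main")
  expect_error(centerline_tree(two_roots), "one root")
})

test_that("densification subdivides edges at the requested spacing", {
  st <- densify_centerline(straight_tree(len = 10), 2)
  expect_equal(nrow(st$samples), 6)
  expect_equal(sort(st$samples$x), seq(0, 10, by = 2))
  # original endpoints preserved
  expect_true(all(c(0, 10) %in% st$samples$x))

  # max_spacing >= edge length: endpoints only
  st2 <- densify_centerline(straight_tree(len = 10), 15)
  expect_equal(nrow(st2$samples), 2)
  expect_equal(sort(st2$samples$x), c(0, 10))
})

test_that("densified sample count matches per-edge subdivision oracle", {
  tree <- y_tree()
  max_spacing <- 1
  nd <- tree$nodes
  # oracle: sum over edges of interior+child samples, plus one per root
  per_edge <- vapply(which(!is.na(nd$parent)), function(i) {
    p <- nd[match(nd$parent[i], nd$id), ]
    len <- sqrt((nd$x[i] - p$x)^2 + (nd$y[i] - p$y)^2 + (nd$z[i] - p$z)^2)
    as.integer(ceiling(len / max_spacing))
  }, 1L)
  expected <- sum(per_edge) + sum(is.na(nd$parent))
  st <- densify_centerline(tree, max_spacing)
  expect_equal(nrow(st$samples), expected)
  # spacing bound honoured along every edge
  s <- st$samples
  gaps <- sapply(which(!is.na(s$pred)), function(i) {
    j <- s$pred[i]
    sqrt((s$x[i] - s$x[j])^2 + (s$y[i] - s$y[j])^2 + (s$z[i] - s$z[j])^2)
  })
  expect_true(all(gaps <= max_spacing + 1e-12))
})

test_that("zero-length edges are skipped with a warning, empty tree errors", {
  dup <- data.frame(id = 1:3, x = c(0, 5, 5), y = 0, z = 0,
                    parent = c(NA, 1L, 2L), artery = "LAD", branch = "main")
  expect_warning(st <- densify_centerline(centerline_tree(dup), 1),
                 "zero-length")
  expect_equal(nrow(st$samples), 6)  # 0..5 at step 1; node 3 merged
  expect_error(centerline_tree(data.frame()), "columns")
  expect_error(densify_centerline(straight_tree(), 0), "positive")
})

test_that("distal set: root gives whole artery, leaf gives singleton", {
  st <- densify_centerline(y_tree(), 1)
  all_ids <- st$samples$sample_id
  root_set <- distal_sample_set(st, lesion_point("LAD", node_id = 1))
  expect_equal(root_set, sort(all_ids))

  leaf_set <- distal_sample_set(st, lesion_point("LAD", node_id = 3))
  expect_length(leaf_set, 1)
  expect_equal(unname(st$node_sample[["3"]]), leaf_set)
})

test_that("distal set equals independent DFS reachability oracle", {
  st <- densify_centerline(y_tree(), 1)
  s <- st$samples
  # oracle: recursive DFS over the pred-derived child lists
  oracle <- function(start) {
    kids <- lapply(s$sample_id, function(i) s$sample_id[!is.na(s$pred) &
                                                          s$pred == i])
    seen <- integer(0)
    rec <- function(i) {
      seen <<- c(seen, i)
      for (k in kids[[i]]) rec(k)
    }
    rec(start)
    sort(seen)
  }
  # mid-trunk lesion upstream of the bifurcation, via arc anchor
  les <- lesion_point("LAD", branch = "main", arc_mm = 5)
  start <- mmarisk:::resolve_lesion_sample(st, les)
  expect_equal(distal_sample_set(st, les), oracle(start))
})

test_that("lesion anchors resolve and fail as specified", {
  st <- densify_centerline(y_tree(), 1)
  # snap at-or-distal: arc 4.3 resolves to the sample at arc 5
  sid <- mmarisk:::resolve_lesion_sample(
    st, lesion_point("LAD", branch = "main", arc_mm = 4.3))
  expect_equal(st$samples$arc[sid], 5)
  expect_error(distal_sample_set(st, lesion_point("RCA", node_id = 1)),
               "artery")
  expect_error(
    distal_sample_set(st, lesion_point("LAD", branch = "main",
                                       arc_mm = 1e4)),
    "beyond")
  expect_error(
    distal_sample_set(st, lesion_point("LAD", branch = "nope", arc_mm = 1)),
    "no branch")
})

test_that("centerline JSON round-trips through the documented schema", {
  tree <- y_tree()
  path <- withr::local_tempfile(fileext = ".json")
  write_centerline_json(tree, path)
  back <- read_centerline_json(path)
  expect_equal(back$nodes, tree$nodes)
})
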