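#' Coronary centerline tree
#'
#' A rooted polyline forest describing the coronary arteries in world
#' millimetres: one connected component (with one root node) per artery.
#' This is the seed structure for the Voronoi territory computation.
#'
#' @param nodes A data frame with columns `id` (integer, unique), `x`, `y`,
#'   `z` (mm), `parent` (id of the parent node, `NA` for an artery root),
#'   `artery` (one of `"RCA"`, `"LAD"`, `"LCx"`), and `branch` (free label,
#'   e.g. `"main"`, `"side1"`).
#' @return An object of class `centerline_tree` (a validated list wrapping
#'   the node table).
#' @details Validation enforces: unique ids; every non-root parent exists;
#'   the graph is a forest (no cycles); the artery label is constant within
#'   each connected component; all coordinates are finite; and every
#'   parent--child edge has positive length is *not* required here (a
#'   zero-length edge is tolerated and skipped with a warning during
#'   densification).
#' @seealso [densify_centerline()], [read_centerline_json()]
#' @export
centerline_tree <- function(nodes) {
  req <- c("id", "x", "y", "z", "parent", "artery", "branch")
  if (!is.data.frame(nodes) || !all(req %in% names(nodes))) {
    stop("`nodes` must be a data frame with columns: ",
         paste(req, collapse = ", "))
  }
  nodes <- as.data.frame(nodes)[req]
  nodes$id <- as.integer(nodes$id)
  nodes$parent <- as.integer(nodes$parent)
  nodes$artery <- as.character(nodes$artery)
  nodes$branch <- as.character(nodes$branch)
  if (nrow(nodes) == 0L) stop("empty centerline tree")
  if (anyDuplicated(nodes$id)) stop("node ids must be unique")
  if (!all(nodes$artery %in% c("RCA", "LAD", "LCx"))) {
    stop("artery labels must be RCA, LAD or LCx")
  }
  xyz <- as.matrix(nodes[c("x", "y", "z")])
  if (!all(is.finite(xyz))) stop("all node coordinates must be finite")
  idx <- match(nodes$parent, nodes$id)
  has_parent <- !is.na(nodes$parent)
  if (any(has_parent & is.na(idx))) {
    stop("some nodes reference a parent id that does not exist")
  }
  # forest check: follow parents; depth must terminate within n steps
  n <- nrow(nodes)
  depth <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    j <- i
    steps <- 0L
    while (!is.na(j) && is.na(depth[j])) {
      pj <- idx[j]
      if (is.na(nodes$parent[j])) {
        depth[j] <- 0L
        break
      }
      if (!is.na(depth[pj])) {
        depth[j] <- depth[pj] + 1L
        break
      }
      steps <- steps + 1L
      if (steps > n) stop("centerline graph contains a cycle")
      j <- pj
    }
  }
  # second pass to fill remaining depths now that some anchors exist
  for (pass in 1:2) {
    for (i in seq_len(n)) {
      if (is.na(depth[i]) && !is.na(idx[i]) && !is.na(depth[idx[i]])) {
        depth[i] <- depth[idx[i]] + 1L
      }
    }
  }
  if (anyNA(depth)) stop("centerline graph contains a cycle")
  same_artery <- nodes$artery[has_parent] == nodes$artery[idx[has_parent]]
  if (!all(same_artery)) {
    stop("artery label must be constant within each connected component")
  }
  roots <- nodes$artery[!has_parent]
  if (anyDuplicated(roots)) stop("each artery must have exactly one root")
  structure(list(nodes = nodes), class = "centerline_tree")
}

#' @export
print.centerline_tree <- function(x, ...) {
  tab <- table(x$nodes$artery)
  cat("Coronary centerline tree:", nrow(x$nodes), "nodes (",
      paste(names(tab), tab, sep = ":", collapse = ", "), ")\n")
  invisible(x)
}

#' Read / write the centerline JSON interchange format
#'
#' The schema is
#' `{"arteries": [{"name": "LAD", "nodes": [{"id": 0, "xyz": [x,y,z],
#' "parent": null, "branch": "main"}, ...]}, ...]}` with coordinates in mm.
#' Node ids must be unique across the whole file.
#'
#' @param path File path.
#' @return `read_centerline_json` returns a validated [centerline_tree()];
#'   `write_centerline_json` returns `path` invisibly.
#' @export
read_centerline_json <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  if (is.null(doc$arteries)) stop("JSON missing top-level 'arteries' array")
  rows <- list()
  for (art in doc$arteries) {
    for (nd in art$nodes) {
      rows[[length(rows) + 1L]] <- data.frame(
        id = as.integer(nd$id),
        x = nd$xyz[[1]], y = nd$xyz[[2]], z = nd$xyz[[3]],
        parent = if (is.null(nd$parent)) NA_integer_ else as.integer(nd$parent),
        artery = art$name,
        branch = if (is.null(nd$branch)) "main" else as.character(nd$branch)
      )
    }
  }
  centerline_tree(do.call(rbind, rows))
}

#' @rdname read_centerline_json
#' @param tree A [centerline_tree()].
#' @export
write_centerline_json <- function(tree, path) {
  stopifnot(inherits(tree, "centerline_tree"))
  nd <- tree$nodes
  arteries <- lapply(unique(nd$artery), function(a) {
    sub <- nd[nd$artery == a, , drop = FALSE]
    list(
      name = a,
      nodes = lapply(seq_len(nrow(sub)), function(i) {
        list(
          id = sub$id[i],
          xyz = c(sub$x[i], sub$y[i], sub$z[i]),
          parent = if (is.na(sub$parent[i])) NULL else sub$parent[i],
          branch = sub$branch[i]
        )
      })
    )
  })
  jsonlite::write_json(list(arteries = arteries), path,
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Densify a centerline tree into evenly spaced samples
#'
#' Subdivides every parent--child edge so that consecutive samples along any
#' polyline are at most `max_spacing` mm apart. Original nodes are preserved
#' as samples and sample connectivity mirrors the tree topology. Sampling
#' the tree densely removes the bias that sparse polyline nodes would
#' introduce into nearest-seed (Voronoi) territory assignment, which should
#' measure distance to the artery as a curve.
#'
#' @param tree A [centerline_tree()].
#' @param max_spacing Maximum distance between consecutive samples, mm (> 0).
#' @return An object of class `sampled_tree`: a list with
#'   \describe{
#'     \item{samples}{data frame `sample_id`, `x`, `y`, `z`, `pred`
#'       (predecessor sample id, `NA` at roots), `artery`, `branch`,
#'       `from_node`, `to_node` (the originating node interval), `arc`
#'       (arc length in mm from the start of the sample's branch).}
#'     \item{node_sample}{named integer vector mapping node id to sample id.}
#'   }
#' @export
densify_centerline <- function(tree, max_spacing) {
  stopifnot(inherits(tree, "centerline_tree"))
  if (!is.numeric(max_spacing) || length(max_spacing) != 1L ||
      !is.finite(max_spacing) || max_spacing <= 0) {
    stop("`max_spacing` must be a single positive number (mm)")
  }
  nd <- tree$nodes
  children <- split(nd$id[!is.na(nd$parent)], nd$parent[!is.na(nd$parent)])
  node_row <- function(id) nd[match(id, nd$id), , drop = FALSE]

  samples <- vector("list", 0L)
  node_sample <- integer(0)   # node id (as name) -> sample id
  node_arc <- numeric(0)      # arc within the node's own branch
  nid <- 0L

  add_sample <- function(x, y, z, pred, artery, branch, from, to, arc) {
    nid <<- nid + 1L
    samples[[nid]] <<- data.frame(
      sample_id = nid, x = x, y = y, z = z, pred = pred,
      artery = artery, branch = branch,
      from_node = from, to_node = to, arc = arc
    )
    nid
  }

  roots <- nd$id[is.na(nd$parent)]
  for (root in sort(roots)) {
    # iterative DFS, children visited in ascending id order
    stack <- root
    while (length(stack)) {
      cur <- stack[[length(stack)]]
      stack <- stack[-length(stack)]
      r <- node_row(cur)
      if (is.na(r$parent)) {
        sid <- add_sample(r$x, r$y, r$z, NA_integer_, r$artery, r$branch,
                          cur, cur, 0)
        node_sample[as.character(cur)] <- sid
        node_arc[as.character(cur)] <- 0
      } else {
        p <- node_row(r$parent)
        p0 <- c(p$x, p$y, p$z)
        p1 <- c(r$x, r$y, r$z)
        len <- sqrt(sum((p1 - p0)^2))
        psid <- node_sample[as.character(r$parent)]
        if (len == 0) {
          warning("zero-length edge ", r$parent, " -> ", cur,
                  "; skipping subdivision", call. = FALSE)
          node_sample[as.character(cur)] <- psid
          node_arc[as.character(cur)] <-
            if (identical(p$branch, r$branch)) node_arc[as.character(r$parent)] else 0
        } else {
          base_arc <- if (identical(p$branch, r$branch)) {
            node_arc[as.character(r$parent)]
          } else {
            0
          }
          nseg <- max(1L, as.integer(ceiling(len / max_spacing - 1e-9)))
          prev <- psid
          for (s in seq_len(nseg)) {
            t <- s / nseg
            pt <- p0 + t * (p1 - p0)
            prev <- add_sample(pt[1], pt[2], pt[3], prev, r$artery, r$branch,
                               r$parent, cur, base_arc + t * len)
          }
          node_sample[as.character(cur)] <- prev
          node_arc[as.character(cur)] <- base_arc + len
        }
      }
      kids <- children[[as.character(cur)]]
      if (length(kids)) stack <- c(stack, sort(kids, decreasing = TRUE))
    }
  }
  out <- do.call(rbind, samples)
  rownames(out) <- NULL
  structure(list(samples = out, node_sample = node_sample),
            class = "sampled_tree")
}

#' @export
print.sampled_tree <- function(x, ...) {
  cat("Sampled centerline tree:", nrow(x$samples), "samples,",
      length(x$node_sample), "original nodes\n")
  invisible(x)
}

#' Specify a lesion point on the coronary tree
#'
#' The anchor is either an original node id or a (branch, arc-length)
#' position; arc length is measured in mm from the start of that branch.
#' Arc-length anchors are snapped to the nearest densified sample at or
#' distal to the requested position so that the distal set is well defined
#' on the sampled tree.
#'
#' @param artery Artery label (`"RCA"`, `"LAD"`, `"LCx"`).
#' @param node_id Original node id (mutually exclusive with
#'   `branch`/`arc_mm`).
#' @param branch Branch label within the artery.
#' @param arc_mm Arc length from the branch start, mm.
#' @return An object of class `lesion_point`.
#' @export
lesion_point <- function(artery, node_id = NULL, branch = NULL, arc_mm = NULL) {
  if (!is.null(node_id) && (!is.null(branch) || !is.null(arc_mm))) {
    stop("give either `node_id` or (`branch`, `arc_mm`), not both")
  }
  if (is.null(node_id) && (is.null(branch) || is.null(arc_mm))) {
    stop("an anchor requires `node_id` or both `branch` and `arc_mm`")
  }
  structure(list(artery = as.character(artery),
                 node_id = if (is.null(node_id)) NULL else as.integer(node_id),
                 branch = branch,
                 arc_mm = arc_mm),
            class = "lesion_point")
}

# Resolve a lesion point to a single sample id on a sampled tree.
resolve_lesion_sample <- function(stree, lesion) {
  stopifnot(inherits(stree, "sampled_tree"), inherits(lesion, "lesion_point"))
  s <- stree$samples
  if (!is.null(lesion$node_id)) {
    sid <- stree$node_sample[as.character(lesion$node_id)]
    if (is.na(sid) || is.null(sid)) {
      stop("lesion anchor node ", lesion$node_id, " is not on the tree")
    }
    sid <- unname(sid)
    if (s$artery[sid] != lesion$artery) {
      stop("lesion anchor node lies on artery ", s$artery[sid],
           ", not ", lesion$artery)
    }
    return(sid)
  }
  cand <- s[s$artery == lesion$artery & s$branch == lesion$branch, ,
            drop = FALSE]
  if (nrow(cand) == 0L) {
    stop("no branch '", lesion$branch, "' on artery ", lesion$artery)
  }
  if (lesion$arc_mm > max(cand$arc) + 1e-9) {
    stop("arc length ", lesion$arc_mm, " mm is beyond branch '",
         lesion$branch, "' (length ", format(max(cand$arc)), " mm)")
  }
  at_or_distal <- cand[cand$arc >= lesion$arc_mm - 1e-9, , drop = FALSE]
  at_or_distal$sample_id[which.min(at_or_distal$arc)]
}

#' Samples distal to a lesion point
#'
#' Returns the lesion sample plus every sample reachable from it moving away
#' from the artery root, i.e. the directed downstream closure into all
#' daughter branches. Distality is along-tree reachability, not Euclidean
#' position.
#'
#' @param stree A [densify_centerline()] result.
#' @param lesion A [lesion_point()].
#' @return Sorted integer vector of sample ids.
#' @export
distal_sample_set <- function(stree, lesion) {
  start <- resolve_lesion_sample(stree, lesion)
  s <- stree$samples
  kids <- split(s$sample_id[!is.na(s$pred)], s$pred[!is.na(s$pred)])
  out <- integer(0)
  queue <- start
  while (length(queue)) {
    cur <- queue[[1]]
    queue <- queue[-1]
    out <- c(out, cur)
    nxt <- kids[[as.character(cur)]]
    if (length(nxt)) queue <- c(queue, nxt)
  }
  sort(out)
}
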