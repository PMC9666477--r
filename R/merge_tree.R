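#' Merge trees
#'
#' A merge tree is a rooted, unordered, edge-weighted tree in which every
#' vertex carries a height and heights weakly increase from the leaves to the
#' root. It is the abstract form of an agglomerative-clustering dendrogram:
#' leaves are lesions, internal vertices are merges, and the weight of the
#' edge above a vertex is the height gap to its parent,
#' `w(v) = height(parent(v)) - height(v)`. Edge weights are derived from
#' heights, never stored, so structural operations (pruning, ghosting) keep
#' them consistent by construction.
#'
#' @param height Numeric vector of vertex heights (one per vertex).
#' @param parent Integer vector of parent indices; `0` marks the single root.
#' @param label Optional character vector of vertex labels (typically lesion
#'   ids on leaves, `NA` elsewhere).
#' @return An object of class `merge_tree`.
#' @examples
#' # the dendrogram of the 1-d point cloud {0, 1, 10} under average linkage
#' t <- merge_tree(
#'   height = c(0, 0, 0, 1, 9.5),
#'   parent = c(4L, 4L, 5L, 5L, 0L),
#'   label = c("a", "b", "c", NA, NA)
#' )
#' tree_weights(t)
#' total_weight(t)
#' @export
merge_tree <- function(height, parent, label = NULL) {
  height <- as.numeric(height)
  parent <- as.integer(parent)
  n <- length(height)
  if (length(parent) != n) {
    stop_hetree("`height` and `parent` must have the same length.", "hetree_validation_error")
  }
  if (is.null(label)) label <- rep(NA_character_, n)
  label <- as.character(label)
  if (length(label) != n) {
    stop_hetree("`label` must have one entry per vertex.", "hetree_validation_error")
  }
  tree <- structure(list(height = height, parent = parent, label = label),
    class = "merge_tree"
  )
  validate_merge_tree(tree)
  tree
}

validate_merge_tree <- function(tree) {
  n <- length(tree$height)
  if (n < 1L) stop_hetree("A merge tree needs at least one vertex.", "hetree_validation_error")
  roots <- which(tree$parent == 0L)
  if (length(roots) != 1L) {
    stop_hetree("A merge tree must have exactly one root.", "hetree_validation_error")
  }
  if (any(tree$parent < 0L | tree$parent > n)) {
    stop_hetree("Parent indices out of range.", "hetree_validation_error")
  }
  nonroot <- setdiff(seq_len(n), roots)
  if (any(tree$height[tree$parent[nonroot]] < tree$height[nonroot] - 1e-12)) {
    stop_hetree(
      "Vertex heights must weakly increase from leaf to root (edge weights >= 0).",
      "hetree_validation_error"
    )
  }
  # reject cycles / disconnected components: every vertex must reach the root
  depth <- integer(n)
  for (v in seq_len(n)) {
    u <- v
    steps <- 0L
    while (tree$parent[u] != 0L) {
      u <- tree$parent[u]
      steps <- steps + 1L
      if (steps > n) {
        stop_hetree("Parent pointers contain a cycle.", "hetree_validation_error")
      }
    }
    depth[v] <- steps
  }
  invisible(tree)
}

#' @export
print.merge_tree <- function(x, ...) {
  cat(
    "<merge_tree> ", n_leaves(x), " leaves, ",
    length(x$height), " vertices, root height ",
    format(root_height(x)), "\n",
    sep = ""
  )
  invisible(x)
}

tree_root <- function(tree) which(tree$parent == 0L)

#' @rdname merge_tree
#' @param tree A `merge_tree`.
#' @export
tree_weights <- function(tree) {
  w <- numeric(length(tree$height))
  nonroot <- which(tree$parent != 0L)
  w[nonroot] <- tree$height[tree$parent[nonroot]] - tree$height[nonroot]
  pmax(w, 0)
}

tree_children <- function(tree) {
  n <- length(tree$parent)
  kids <- vector("list", n)
  for (v in seq_len(n)) {
    if (tree$parent[v] != 0L) kids[[tree$parent[v]]] <- c(kids[[tree$parent[v]]], v)
  }
  kids
}

tree_leaves <- function(tree) {
  setdiff(seq_along(tree$parent), tree$parent)
}

#' @rdname merge_tree
#' @export
n_leaves <- function(tree) length(tree_leaves(tree))

#' @rdname merge_tree
#' @export
root_height <- function(tree) tree$height[tree_root(tree)]

#' Total edge weight of a merge tree
#'
#' Sum of all edge weights, i.e. of all parent-child height gaps. Used by the
#' edit-distance bounds: the distance between two trees is at least the
#' absolute difference and at most the sum of their total weights.
#'
#' @param tree A `merge_tree`.
#' @return A non-negative number.
#' @export
total_weight <- function(tree) sum(tree_weights(tree))

# Drop the given vertices, reattaching any orphaned child to its nearest
# surviving ancestor. Heights of survivors are untouched, so edge weights
# along ghosted chains sum automatically.
tree_drop_vertices <- function(tree, drop) {
  if (length(drop) == 0L) return(tree)
  n <- length(tree$height)
  keep <- setdiff(seq_len(n), drop)
  if (length(keep) == 0L) {
    stop_hetree("Cannot drop every vertex of a merge tree.", "hetree_validation_error")
  }
  dropped <- rep(FALSE, n)
  dropped[drop] <- TRUE
  new_parent_of <- function(v) {
    u <- tree$parent[v]
    while (u != 0L && dropped[u]) u <- tree$parent[u]
    u
  }
  idx <- integer(n)
  idx[keep] <- seq_along(keep)
  parent <- vapply(keep, new_parent_of, integer(1))
  parent <- ifelse(parent == 0L, 0L, idx[parent])
  merge_tree(tree$height[keep], parent, tree$label[keep])
}

# Remove every order-2 vertex (a non-root internal vertex with exactly one
# child): the ghosting edit, cost free, merging the two incident edges.
ghost_order2 <- function(tree) {
  repeat {
    kids <- tree_children(tree)
    deg1 <- which(
      vapply(kids, length, integer(1)) == 1L & tree$parent != 0L
    )
    if (length(deg1) == 0L) return(tree)
    tree <- tree_drop_vertices(tree, deg1)
  }
}

#' Rescale merge-tree heights to a common [0, 1] range
#'
#' Divides all vertex heights by a normalizer: in `"global"` mode the largest
#' root height in the cohort (preserving between-patient scale ratios), in
#' `"per_tree"` mode each tree's own root height. Rescaled trees are the
#' expected input for the Beta-weighted pruned edit distance, whose default
#' measure lives on [0, 1].
#'
#' @param trees A list of `merge_tree` objects.
#' @param mode `"global"` (default) or `"per_tree"`.
#' @return A list of rescaled `merge_tree` objects.
#' @export
rescale_heights <- function(trees, mode = c("global", "per_tree")) {
  mode <- match.arg(mode)
  stopifnot(length(trees) >= 1L)
  roots <- vapply(trees, root_height, numeric(1))
  if (mode == "global") {
    norm <- max(roots)
    if (norm <= 0) {
      stop_hetree("All root heights are zero; nothing to rescale by.", "hetree_data_error")
    }
    norms <- rep(norm, length(trees))
  } else {
    if (all(roots <= 0)) {
      stop_hetree("All root heights are zero; nothing to rescale by.", "hetree_data_error")
    }
    # a degenerate single-vertex tree (root height 0) is left unscaled
    norms <- ifelse(roots > 0, roots, 1)
  }
  purrr::map2(trees, norms, function(tr, s) {
    tr$height <- tr$height / s
    tr
  })
}

#' Height-count curve of a merge tree
#'
#' For each threshold on an ascending grid, counts the internal vertices whose
#' height is strictly greater than the threshold. The resulting
#' non-increasing step function is a one-dimensional summary of the
#' heterogeneity encoded by the tree: the slower it decays, the more merges
#' happen at large radiomic distances, i.e. the more mutually heterogeneous
#' the lesions.
#'
#' Leaves (height-0 vertices in a dendrogram) are not counted: they would add
#' a constant equal to the lesion count at every threshold below zero height.
#'
#' @param tree A `merge_tree`.
#' @param grid Ascending numeric vector of height thresholds.
#' @return A tibble with columns `threshold` and `count`.
#' @export
height_count_curve <- function(tree, grid) {
  grid <- as.numeric(grid)
  if (is.unsorted(grid, strictly = FALSE)) {
    stop_hetree("`grid` must be ascending.", "hetree_validation_error")
  }
  internal <- unique(tree$parent[tree$parent != 0L])
  h <- tree$height[internal]
  tibble::tibble(
    threshold = grid,
    count = vapply(grid, function(t) sum(h > t), numeric(1))
  )
}
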