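#' Newick serialization of merge trees
#'
#' Merge trees are written as rooted Newick strings with branch lengths equal
#' to the edge weights (parent-child height gaps); reading reconstructs
#' heights by placing the lowest leaf at height 0. Round-tripping preserves
#' topology, weights and labels. Parsing is delegated to \pkg{ape}.
#'
#' A single-vertex tree (a patient with one lesion) has no edges; it is
#' encoded as a zero-length pendant edge `"(label:0);"`, which is
#' edit-distance-equivalent (a zero-weight edge is free to delete).
#'
#' @param tree A [merge_tree()].
#' @return `to_newick()`: a Newick string. `from_newick()`: a `merge_tree`.
#' @export
to_newick <- function(tree) {
  n <- length(tree$height)
  if (n == 1L) {
    lab <- tree$label[1]
    if (is.na(lab)) lab <- "v1"
    return(paste0("(", lab, ":0);"))
  }
  phy <- merge_tree_to_phylo(tree)
  ape::write.tree(phy, digits = 15)
}

#' @rdname to_newick
#' @param text A Newick string with branch lengths.
#' @export
from_newick <- function(text) {
  phy <- tryCatch(
    ape::read.tree(text = text),
    error = function(e) NULL,
    warning = function(w) NULL
  )
  if (is.null(phy) || is.null(phy$edge)) {
    stop_hetree(
      paste0("Malformed Newick string: ", substr(text, 1, 60)),
      "hetree_parse_error"
    )
  }
  if (is.null(phy$edge.length)) {
    stop_hetree("Newick string has no branch lengths.", "hetree_parse_error")
  }
  phylo_to_merge_tree(phy)
}

#' @rdname to_newick
#' @param path File path; `write_trees()` writes one `<patient_id>.nwk` per
#'   tree into directory `path` and returns the file paths.
#' @param trees Named list of merge trees.
#' @export
write_trees <- function(trees, path) {
  stopifnot(!is.null(names(trees)))
  if (!dir.exists(path)) dir.create(path, recursive = TRUE)
  vapply(names(trees), function(id) {
    f <- file.path(path, paste0(id, ".nwk"))
    writeLines(to_newick(trees[[id]]), f)
    f
  }, character(1))
}

merge_tree_to_phylo <- function(tree) {
  n_all <- length(tree$height)
  leaves <- tree_leaves(tree)
  internal <- setdiff(seq_len(n_all), leaves)
  root <- tree_root(tree)
  # phylo wants tips 1..n then internal nodes with the root first
  internal <- c(root, setdiff(internal, root))
  new_id <- integer(n_all)
  new_id[leaves] <- seq_along(leaves)
  new_id[internal] <- length(leaves) + seq_along(internal)
  nonroot <- setdiff(seq_len(n_all), root)
  w <- tree_weights(tree)
  labs <- tree$label[leaves]
  labs[is.na(labs)] <- paste0("t", which(is.na(labs)))
  structure(
    list(
      edge = cbind(new_id[tree$parent[nonroot]], new_id[nonroot]),
      edge.length = w[nonroot],
      tip.label = labs,
      Nnode = length(internal)
    ),
    class = "phylo", order = "cladewise"
  )
}

phylo_to_merge_tree <- function(phy) {
  n_tip <- length(phy$tip.label)
  n_all <- n_tip + phy$Nnode
  parent <- integer(n_all)
  parent[phy$edge[, 2]] <- phy$edge[, 1]
  # depth = summed branch length from the root, filled top-down by BFS
  depth <- numeric(n_all)
  elen <- setNames(phy$edge.length, phy$edge[, 2])
  root <- setdiff(phy$edge[, 1], phy$edge[, 2])[1]
  frontier <- root
  while (length(frontier) > 0L) {
    kids <- phy$edge[phy$edge[, 1] %in% frontier, 2]
    depth[kids] <- depth[parent[kids]] + elen[as.character(kids)]
    frontier <- kids
  }
  height <- max(depth) - depth
  labels <- c(phy$tip.label, rep(NA_character_, phy$Nnode))
  merge_tree(height, parent, labels)
}
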