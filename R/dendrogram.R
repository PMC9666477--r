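#' Average-linkage dendrogram of a lesion distance matrix
#'
#' Builds the per-patient representation: agglomerative clustering of the
#' lesions under unweighted average linkage (UPGMA-style update, the
#' arithmetic mean of all inter-cluster pairwise distances), returned as a
#' merge tree with the lesions as height-0 leaves and one internal vertex per
#' merge at its agglomeration height. Average linkage is used within patients
#' because it is comparatively insensitive to outlying lesions.
#'
#' @param D Symmetric distance matrix with zero diagonal (n >= 1).
#' @param labels Optional leaf labels; defaults to `rownames(D)`.
#' @return A [merge_tree()]. A single lesion yields a single-vertex tree at
#'   height 0.
#' @export
average_linkage_dendrogram <- function(D, labels = rownames(D)) {
  D <- as.matrix(D)
  n <- nrow(D)
  if (n == 0L) stop_hetree("Empty distance matrix.", "hetree_validation_error")
  if (ncol(D) != n || any(abs(D - t(D)) > 1e-8) || any(abs(diag(D)) > 1e-12)) {
    stop_hetree(
      "Distance matrix must be symmetric with a zero diagonal.",
      "hetree_integrity_error"
    )
  }
  if (is.null(labels)) labels <- paste0("l", seq_len(n))
  if (n == 1L) {
    return(merge_tree(0, 0L, labels))
  }
  hc <- hclust(as.dist(D), method = "average")
  hclust_to_merge_tree(hc, labels)
}

# Convert an hclust object to a merge_tree: leaves 1..n at height 0, merge
# i at vertex n+i with the agglomeration height; the last merge is the root.
hclust_to_merge_tree <- function(hc, labels) {
  n <- length(hc$order)
  m <- nrow(hc$merge)
  height <- c(rep(0, n), pmax(hc$height, 0))
  parent <- integer(n + m)
  for (i in seq_len(m)) {
    for (child in hc$merge[i, ]) {
      v <- if (child < 0) -child else n + child
      parent[v] <- n + i
    }
  }
  parent[n + m] <- 0L
  merge_tree(height, parent, c(labels, rep(NA_character_, m)))
}

#' Build the dendrogram of every patient in a reduced matrix
#'
#' @param reduced A `reduced_matrix`.
#' @return A named list of [merge_tree()] objects, one per patient, in order
#'   of first appearance.
#' @export
patient_trees <- function(reduced) {
  ids <- unique(reduced$patient_id)
  trees <- purrr::map(ids, function(pid) {
    cloud <- patient_point_cloud(reduced, pid)
    average_linkage_dendrogram(lesion_distance_matrix(cloud))
  })
  setNames(trees, ids)
}
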