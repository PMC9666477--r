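#' Canonical form of a merge tree
#'
#' A total-order string encoding of a rooted, unordered, edge-weighted tree,
#' invariant under sibling permutation. Two trees have equal canonical forms
#' exactly when they are isomorphic with equal weights after the cost-free
#' normalizing edits: ghosting all order-2 vertices and contracting
#' zero-weight edges (both are free in the edit model, so they cannot
#' separate trees at positive distance). Weights are compared at a 1e-12
#' rounding tolerance.
#'
#' @param tree A [merge_tree()].
#' @return A character scalar.
#' @export
canonical_form <- function(tree) {
  tree <- canonical_normalize(tree)
  kids <- tree_children(tree)
  w <- round(tree_weights(tree), 12)
  enc <- function(v) {
    if (length(kids[[v]]) == 0L) {
      paste0("L", format(w[v], digits = 15))
    } else {
      inner <- sort(vapply(kids[[v]], enc, character(1)))
      paste0("(", paste(inner, collapse = ","), ")", format(w[v], digits = 15))
    }
  }
  enc(tree_root(tree))
}

# apply the zero-cost edits exhaustively: ghost order-2 vertices and remove
# zero-weight edges (deleting a zero-weight edge is free; its children are
# reattached to the parent). The root is never removed.
canonical_normalize <- function(tree, tol = 1e-12) {
  repeat {
    tree <- ghost_order2(tree)
    if (length(tree$height) == 1L) return(tree)
    w <- tree_weights(tree)
    zero <- setdiff(which(w <= tol), tree_root(tree))
    if (length(zero) == 0L) return(tree)
    tree <- tree_drop_vertices(tree, zero[1])
  }
}
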