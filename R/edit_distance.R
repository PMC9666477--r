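#' Cost of a vertex mapping between two merge trees
#'
#' A mapping is a one-to-one correspondence between vertices of `a` and `b`
#' that matches root to root and preserves ancestry in both directions. It
#' encodes an edit path: unmatched vertices are removed from their tree
#' (deleted at the cost of their edge weight, or ghosted for free when the
#' removals leave them with a single child), inserted on the other side
#' symmetrically, and each matched pair is reconciled by shrinking its
#' ghost-aggregated edge.
#'
#' The aggregated weight \eqn{W(v)} of a matched vertex is the sum of edge
#' weights from `v` up to (exclusive) its nearest matched strict ancestor,
#' restricted to ghosted vertices: an unmatched vertex is ghosted exactly
#' when the topmost matched vertices in its subtree number one (after all
#' removals it has a single child), and deleted otherwise. Ghosting is never
#' costlier than deletion for a fixed matching (triangle inequality), so
#' this canonical split realizes the cheapest edit path inducing the
#' matching.
#'
#' @param a,b [merge_tree()] objects.
#' @param pairs Two-column integer matrix of matched vertex indices
#'   (`a`-vertex, `b`-vertex), including the root pair.
#' @return The non-negative edit cost realized by the mapping.
#' @export
mapping_cost <- function(a, b, pairs) {
  pairs <- matrix(as.integer(pairs), ncol = 2)
  validate_mapping(a, b, pairs)
  side_a <- side_decomposition(a, pairs[, 1])
  side_b <- side_decomposition(b, pairs[, 2])
  wa <- setNames(side_a$W, pairs[, 1])[as.character(pairs[, 1])]
  wb <- setNames(side_b$W, pairs[, 2])[as.character(pairs[, 2])]
  side_a$deleted + side_b$deleted + sum(abs(wa - wb))
}

validate_mapping <- function(a, b, pairs) {
  if (anyDuplicated(pairs[, 1]) || anyDuplicated(pairs[, 2])) {
    stop_hetree("Mapping is not one-to-one.", "hetree_mapping_error")
  }
  if (any(pairs[, 1] > length(a$height)) || any(pairs[, 2] > length(b$height)) ||
    any(pairs < 1L)) {
    stop_hetree("Mapping refers to vertices outside the trees.", "hetree_mapping_error")
  }
  ra <- tree_root(a)
  rb <- tree_root(b)
  has_root <- any(pairs[, 1] == ra)
  if (!has_root || pairs[pairs[, 1] == ra, 2] != rb || any(pairs[, 2] == rb & pairs[, 1] != ra)) {
    stop_hetree("Mapping must match root to root.", "hetree_mapping_error")
  }
  anc_a <- ancestor_matrix(a)
  anc_b <- ancestor_matrix(b)
  m <- nrow(pairs)
  if (m > 1L) {
    for (i in seq_len(m - 1L)) {
      for (j in seq(i + 1L, m)) {
        ok <- anc_a[pairs[i, 1], pairs[j, 1]] == anc_b[pairs[i, 2], pairs[j, 2]] &&
          anc_a[pairs[j, 1], pairs[i, 1]] == anc_b[pairs[j, 2], pairs[i, 2]]
        if (!ok) {
          stop_hetree(
            paste0(
              "Mapping violates ancestry preservation between pairs (",
              pairs[i, 1], ",", pairs[i, 2], ") and (", pairs[j, 1], ",", pairs[j, 2], ")."
            ),
            "hetree_mapping_error"
          )
        }
      }
    }
  }
  invisible(TRUE)
}

# strict-ancestor indicator matrix: anc[i, j] is TRUE iff i is a strict
# ancestor of j
ancestor_matrix <- function(tree) {
  n <- length(tree$parent)
  anc <- matrix(FALSE, n, n)
  for (v in seq_len(n)) {
    u <- tree$parent[v]
    while (u != 0L) {
      anc[u, v] <- TRUE
      u <- tree$parent[u]
    }
  }
  anc
}

# For one side of a mapping: total deleted weight and the ghost-aggregated
# weight W of every matched vertex (in the order of `matched`).
side_decomposition <- function(tree, matched) {
  n <- length(tree$parent)
  w <- tree_weights(tree)
  is_matched <- rep(FALSE, n)
  is_matched[matched] <- TRUE
  kids <- tree_children(tree)
  # antichain[v]: number of topmost matched vertices in subtree(v)
  antichain <- integer(n)
  order_depth <- order(vapply(seq_len(n), function(v) {
    d <- 0L
    u <- v
    while (tree$parent[u] != 0L) {
      u <- tree$parent[u]
      d <- d + 1L
    }
    d
  }, integer(1)), decreasing = TRUE)
  for (v in order_depth) {
    antichain[v] <- if (is_matched[v]) 1L else sum(antichain[kids[[v]]])
  }
  ghosted <- !is_matched & antichain == 1L
  root <- tree_root(tree)
  deleted <- sum(w[!is_matched & !ghosted & seq_len(n) != root])
  W <- vapply(matched, function(v) {
    if (v == root) {
      return(0)
    }
    acc <- w[v]
    u <- tree$parent[v]
    while (u != 0L && !is_matched[u]) {
      if (ghosted[u]) acc <- acc + w[u]
      u <- tree$parent[u]
    }
    acc
  }, numeric(1))
  list(deleted = deleted, W = W, ghosted = ghosted)
}

#' Exhaustive-enumeration edit distance (definitional oracle)
#'
#' Minimizes [mapping_cost()] over every valid mapping between the two
#' trees, enumerated exhaustively. This is the definitional semantics of the
#' merge-tree edit distance -- the infimum over edit paths realized as a
#' minimum over ancestry-preserving one-to-one vertex matchings -- and the
#' contract that the optimized solver in [edit_distance()] must reproduce.
#' Enumeration is exponential, so a vertex bound guards against accidental
#' large calls.
#'
#' @param a,b [merge_tree()] objects.
#' @param max_vertices Per-tree vertex bound (default 9).
#' @return A list with `distance` and `mapping` (an argmin pair matrix).
#' @export
edit_distance_oracle <- function(a, b, max_vertices = 9L) {
  if (length(a$height) > max_vertices || length(b$height) > max_vertices) {
    stop_hetree(
      paste0(
        "Trees exceed the oracle's exhaustive-enumeration bound (",
        max_vertices, " vertices); use edit_distance()."
      ),
      "hetree_capacity_error"
    )
  }
  anc_a <- ancestor_matrix(a)
  anc_b <- ancestor_matrix(b)
  ra <- tree_root(a)
  rb <- tree_root(b)
  va <- setdiff(preorder(a), ra)
  vb <- setdiff(seq_along(b$height), rb)
  best <- list(distance = Inf, mapping = NULL)
  m_a <- integer(0)
  m_b <- integer(0)

  cost_of <- function(ma, mb) {
    pa <- c(ra, ma)
    pb <- c(rb, mb)
    sa <- side_decomposition(a, pa)
    sb <- side_decomposition(b, pb)
    sa$deleted + sb$deleted + sum(abs(sa$W - sb$W))
  }
  recurse <- function(i, ma, mb) {
    if (i > length(va)) {
      d <- cost_of(ma, mb)
      if (d < best$distance) {
        best <<- list(distance = d, mapping = cbind(c(ra, ma), c(rb, mb)))
      }
      return(invisible(NULL))
    }
    x <- va[i]
    # leave x unmatched
    recurse(i + 1L, ma, mb)
    # or match x to any ancestry-consistent unused vertex of b
    for (y in setdiff(vb, mb)) {
      ok <- TRUE
      for (k in seq_along(ma)) {
        if (anc_a[ma[k], x] != anc_b[mb[k], y] ||
          anc_a[x, ma[k]] != anc_b[y, mb[k]]) {
          ok <- FALSE
          break
        }
      }
      if (ok) recurse(i + 1L, c(ma, x), c(mb, y))
    }
  }
  recurse(1L, m_a, m_b)
  best
}

preorder <- function(tree) {
  kids <- tree_children(tree)
  out <- integer(0)
  visit <- function(v) {
    out <<- c(out, v)
    for (k in kids[[v]]) visit(k)
  }
  visit(tree_root(tree))
  out
}

#' Merge-tree edit distance
#'
#' The minimal total cost of shrink / delete--insert / ghost--split edits
#' transforming one tree into the other. Shrinking an edge costs the
#' absolute weight change, deleting or inserting an edge costs its weight,
#' and ghosting/splitting (removing/introducing an order-2 vertex, merging
#' or splitting edges) is free. Computed exactly by a branch-and-bound
#' search over ancestry-preserving vertex matchings with an admissible
#' weight-partition bound; agrees with [edit_distance_oracle()] on every
#' instance within the oracle's reach.
#'
#' The distance always satisfies
#' `|total_weight(a) - total_weight(b)| <= d <= total_weight(a) + total_weight(b)`.
#'
#' @param a,b [merge_tree()] objects.
#' @param solver `"branch_and_bound"` (the exact optimized solver).
#' @param max_nodes Search-node budget; exceeding it raises a capacity error
#'   reporting the best bound found.
#' @param gap Absolute optimality-gap certificate (like a MILP gap): the
#'   returned value is the cost of an explicit edit script within `gap` of
#'   the optimum. The default 0 proves optimality exactly; cohort pipelines
#'   may trade a small certified gap for speed on large similar trees.
#' @return The distance (non-negative scalar).
#' @export
edit_distance <- function(a, b, solver = "branch_and_bound", max_nodes = 2e8,
                          gap = 0) {
  solver <- match.arg(solver, "branch_and_bound")
  stopifnot(is.numeric(gap), length(gap) == 1L, gap >= 0)
  a <- canonical_normalize(a)
  b <- canonical_normalize(b)
  if (canonical_form(a) == canonical_form(b)) {
    return(0)
  }
  res <- edit_distance_bb(
    a$parent, tree_weights(a),
    b$parent, tree_weights(b),
    as.numeric(max_nodes), as.numeric(gap)
  )
  if (res$status != 0L) {
    stop_hetree(
      paste0(
        "Edit-distance search exceeded the node budget; best bounds [",
        format(res$lower), ", ", format(res$distance), "]."
      ),
      "hetree_capacity_error"
    )
  }
  res$distance
}

# Effort-bounded variant for cohort pipelines: never errors; when the node
# budget runs out it returns the best edit script found so far (a true upper
# bound) together with the certified lower bound.
edit_distance_bounded <- function(a, b, gap = 0, max_nodes = 3e5) {
  a <- canonical_normalize(a)
  b <- canonical_normalize(b)
  if (canonical_form(a) == canonical_form(b)) {
    return(list(distance = 0, lower = 0, certified = TRUE))
  }
  res <- edit_distance_bb(
    a$parent, tree_weights(a),
    b$parent, tree_weights(b),
    as.numeric(max_nodes), as.numeric(gap)
  )
  list(
    distance = res$distance, lower = res$lower,
    certified = res$status == 0L
  )
}
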