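#' Pruning operator on merge trees
#'
#' `prune()` applies the regularizing operator \eqn{P_\varepsilon}: leaves
#' whose parent edge has weight `<= eps` represent lesions so similar to
#' their neighbours that they are collapsed into a single imaging phenotype.
#' The rule is applied recursively until it stabilizes:
#'
#' 1. mark every leaf whose edge weight is `<= eps`;
#' 2. at a father with marked leaf children: if at least one child survives
#'    (an unmarked child or an internal child), delete all marked leaves;
#'    if *all* children are marked leaves, keep the one of largest weight
#'    (seeded uniform choice on ties, the common case in dendrograms where
#'    sibling leaves merge at the same height) and delete the rest;
#' 3. ghost every resulting order-2 vertex (merging its two edges at no
#'    cost), which lengthens the kept leaf's edge;
#' 4. repeat.
#'
#' A father left with a single kept child is only ghosted when it is not the
#' root: the root has no father edge, so the tree degenerates gracefully
#' toward a single root--leaf edge and the last leaf is never deleted. The
#' operator is idempotent, and the number of leaves of `prune(tree, eps)` is
#' non-increasing in `eps`.
#'
#' @param tree A [merge_tree()].
#' @param eps Non-negative pruning threshold, on the height scale of `tree`.
#' @param seed Integer seed for the sibling tie-break.
#' @return The pruned `merge_tree`.
#' @export
prune <- function(tree, eps, seed = 1L) {
  if (!is.numeric(eps) || length(eps) != 1L || is.na(eps) || eps < 0) {
    stop_hetree("`eps` must be a single non-negative number.", "hetree_validation_error")
  }
  pass <- 0L
  repeat {
    pass <- pass + 1L
    w <- tree_weights(tree)
    kids <- tree_children(tree)
    leaves <- tree_leaves(tree)
    root <- tree_root(tree)
    marked <- setdiff(leaves[w[leaves] <= eps], root)
    if (length(marked) == 0L) break
    drop <- integer(0)
    for (f in sort(unique(tree$parent[marked]))) {
      mk <- intersect(kids[[f]], marked)
      if (length(kids[[f]]) > length(mk)) {
        # some child survives: delete every marked leaf under f
        drop <- c(drop, mk)
      } else if (length(mk) >= 2L) {
        # deletion would orphan the father: keep the largest-weight leaf
        wmx <- max(w[mk])
        top <- mk[w[mk] >= wmx - 1e-15]
        keep <- if (length(top) == 1L) top else top[tie_pick(seed, pass, f, length(top))]
        drop <- c(drop, setdiff(mk, keep))
      }
      # a single marked only-child is kept: nothing to delete under f
    }
    if (length(drop) == 0L) break
    tree <- ghost_order2(tree_drop_vertices(tree, drop))
  }
  tree
}

# deterministic "uniform" pick among k tied siblings, a pure function of
# (seed, pass, father): reproducible without touching the global RNG
tie_pick <- function(seed, pass, f, k) {
  h <- (as.numeric(seed) * 2654435761 + pass * 97003 + f * 8191) %% 2147483647
  as.integer(h %% k) + 1L
}

#' Breakpoint profile of the pruning operator
#'
#' As `eps` grows, `prune(tree, eps)` changes only at finitely many
#' thresholds and is constant on the right-open intervals between them
#' (pruning uses `<=`). Any threshold at which the pruned tree changes is a
#' partial sum of edge weights along some leaf-upward path (a ghosted chain's
#' aggregated weight), so those prefix sums form a provable superset of the
#' breakpoints; the profile is obtained by evaluating `prune()` at each
#' candidate and collapsing runs with equal canonical form.
#'
#' @param tree A [merge_tree()].
#' @param seed Tie-break seed passed to [prune()].
#' @return A list of class `breakpoint_profile` with `breakpoints` (ascending
#'   thresholds where the pruned tree changes; the first interval starts at
#'   0) and `segments`, a list of pruned trees, one per interval
#'   `[b_i, b_{i+1})` (with `b_0 = 0` and the last interval unbounded).
#' @export
prune_breakpoints <- function(tree, seed = 1L) {
  # candidate thresholds: every leaf-upward path prefix weight, computed as
  # a direct height gap so it matches the ghost-aggregated edge weight of
  # the pruned tree bit for bit
  prefix <- function(v) {
    sums <- numeric(0)
    u <- tree$parent[v]
    while (u != 0L) {
      sums <- c(sums, tree$height[u] - tree$height[v])
      u <- tree$parent[u]
    }
    sums
  }
  cand <- sort(unique(unlist(lapply(tree_leaves(tree), prefix))))
  cand <- cand[cand > 0]
  eval_at <- c(0, cand)
  pruned <- lapply(eval_at, function(e) prune(tree, e, seed = seed))
  forms <- vapply(pruned, canonical_form, character(1))
  changed <- c(TRUE, forms[-1] != forms[-length(forms)])
  structure(
    list(
      breakpoints = eval_at[changed][-1],
      segments = pruned[changed],
      starts = eval_at[changed]
    ),
    class = "breakpoint_profile"
  )
}

#' @export
print.breakpoint_profile <- function(x, ...) {
  cat(
    "<breakpoint_profile> ", length(x$breakpoints), " breakpoint(s): ",
    paste(format(x$breakpoints), collapse = ", "), "\n",
    sep = ""
  )
  invisible(x)
}

# the pruned tree in force at threshold eps, read off the profile
profile_at <- function(profile, eps) {
  i <- findInterval(eps, profile$starts)
  profile$segments[[max(i, 1L)]]
}
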