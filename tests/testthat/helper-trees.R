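# Shared fixtures: small merge trees with known structure, built in code.

# dendrogram of the 1-d point cloud {0, 1, 10} under average linkage:
# leaves a, b merge at height 1, then join c at height 9.5
tree_0_1_10 <- function() {
  merge_tree(
    height = c(0, 0, 0, 1, 9.5),
    parent = c(4L, 4L, 5L, 5L, 0L),
    label = c("a", "b", "c", NA, NA)
  )
}

# two leaves of weights w1, w2 under a root
cherry <- function(w1, w2) {
  h <- max(w1, w2)
  merge_tree(
    height = c(h - w1, h - w2, h),
    parent = c(3L, 3L, 0L),
    label = c("a", "b", NA)
  )
}

# root with a single pendant leaf of weight w
single_leaf <- function(w) {
  merge_tree(height = c(0, w), parent = c(2L, 0L), label = c("a", NA))
}

expect_tree_equal <- function(a, b) {
  expect_identical(canonical_form(a), canonical_form(b))
}

# a small cohort of rescaled random trees for metric-property suites
random_rescaled_trees <- function(n, leaves = 2:6, seed = 1L) {
  pool <- if (length(leaves) == 1L) rep(leaves, 2L) else leaves
  counts <- hetree:::with_seed(seed, sample(pool, n, replace = TRUE))
  trees <- lapply(seq_len(n), function(i) {
    random_merge_tree(counts[i], seed = hetree:::derive_seed(seed, i))
  })
  rescale_heights(trees, mode = "per_tree")
}
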