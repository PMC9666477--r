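test_that("average linkage reproduces the hand-computed {0,1,10} dendrogram", {
  D <- as.matrix(dist(matrix(c(0, 1, 10), 3)))
  tr <- average_linkage_dendrogram(D, c("a", "b", "c"))
  expect_tree_equal(tr, tree_0_1_10())
  expect_equal(sort(tree_weights(tr)), c(0, 1, 1, 8.5, 9.5))
  expect_equal(root_height(tr), 9.5) # average of d(0,10)=10 and d(1,10)=9

  # two points at distance d -> cherry with root height d
  D2 <- matrix(c(0, 3, 3, 0), 2)
  expect_tree_equal(average_linkage_dendrogram(D2), cherry(3, 3))

  # identical points: all merges at height 0
  D0 <- matrix(0, 4, 4)
  tr0 <- average_linkage_dendrogram(D0)
  expect_equal(max(tr0$height), 0)

  # single lesion: single-vertex tree
  tr1 <- average_linkage_dendrogram(matrix(0, 1, 1), "only")
  expect_equal(length(tr1$height), 1)
  expect_equal(n_leaves(tr1), 1)

  expect_error(
    average_linkage_dendrogram(matrix(c(0, 1, 2, 0), 2)),
    class = "hetree_integrity_error"
  )
})

test_that("dendrograms agree with a naive O(n^3) agglomeration oracle", {
  # from-scratch unweighted average-linkage agglomeration
  naive_upgma_heights <- function(D) {
    n <- nrow(D)
    members <- as.list(seq_len(n))
    active <- rep(TRUE, n + (n - 1))
    M <- matrix(NA_real_, 2 * n - 1, 2 * n - 1)
    M[1:n, 1:n] <- D
    heights <- numeric(0)
    cur <- n
    idx <- which(active[1:n])
    while (length(idx) > 1) {
      best <- c(NA, NA)
      bestd <- Inf
      for (i in idx) {
        for (j in idx) {
          if (i < j && M[i, j] < bestd) {
            bestd <- M[i, j]
            best <- c(i, j)
          }
        }
      }
      cur <- cur + 1
      heights <- c(heights, bestd)
      members[[cur]] <- c(members[[best[1]]], members[[best[2]]])
      active[best] <- FALSE
      idx <- setdiff(c(idx, cur), best)
      for (k in idx) {
        if (k == cur) next
        M[cur, k] <- M[k, cur] <-
          mean(D[members[[cur]], members[[k]], drop = FALSE])
      }
    }
    sort(heights)
  }
  for (rep in 1:5) {
    set.seed(rep)
    n <- sample(3:8, 1)
    pts <- matrix(rnorm(n * 2), n)
    D <- as.matrix(dist(pts))
    tr <- average_linkage_dendrogram(D)
    got <- sort(tr$height[unique(tr$parent[tr$parent != 0])])
    expect_equal(got, naive_upgma_heights(D), tolerance = 1e-9)
  }
})

test_that("dendrogram shape is invariant to point order", {
  set.seed(21)
  pts <- matrix(rnorm(14), 7)
  D <- as.matrix(dist(pts))
  t1 <- average_linkage_dendrogram(D)
  perm <- sample(7)
  t2 <- average_linkage_dendrogram(D[perm, perm])
  expect_tree_equal(t1, t2)
})

test_that("height rescaling supports global and per-tree normalizers", {
  t1 <- cherry(5, 5) # root height 5
  t2 <- cherry(10, 10) # root height 10
  g <- rescale_heights(list(t1, t2), "global")
  expect_equal(root_height(g[[1]]), 0.5)
  expect_equal(root_height(g[[2]]), 1.0)
  p <- rescale_heights(list(t1, t2), "per_tree")
  expect_equal(root_height(p[[1]]), 1.0)
  expect_equal(root_height(p[[2]]), 1.0)
  expect_error(
    rescale_heights(list(merge_tree(c(0, 0), c(2L, 0L)))),
    class = "hetree_data_error"
  )
})

test_that("height-count curves count internal vertices above thresholds", {
  tr <- tree_0_1_10()
  hc <- height_count_curve(tr, c(0.5, 5, 10))
  expect_equal(hc$count, c(2, 1, 0))
  expect_equal(height_count_curve(tr, 100)$count, 0)
  # single-vertex tree has no internal vertices
  expect_equal(height_count_curve(merge_tree(0, 0L), c(0, 1))$count, c(0, 0))
  # monotonicity on random trees
  for (i in 1:10) {
    tr2 <- random_merge_tree(sample(2:9, 1), seed = i)
    counts <- height_count_curve(tr2, seq(0, root_height(tr2) * 1.1, length.out = 25))$count
    expect_true(all(diff(counts) <= 0))
  }
  expect_error(height_count_curve(tr, c(2, 1)), class = "hetree_validation_error")
})

test_that("pruning follows the recursive small-leaf collapse rules", {
  # {0,1,10} tree at eps = 1: equal-weight siblings collapse, father ghosts
  p1 <- prune(tree_0_1_10(), 1)
  expect_tree_equal(p1, cherry(9.5, 9.5))

  # eps = 0 with all positive weights: unchanged
  expect_tree_equal(prune(tree_0_1_10(), 0), tree_0_1_10())

  # cherry(1, 3) at eps = 2: marked leaf deleted, root retained
  p2 <- prune(cherry(1, 3), 2)
  expect_equal(n_leaves(p2), 1)
  expect_equal(sort(tree_weights(p2)), c(0, 3))

  expect_error(prune(tree_0_1_10(), -1), class = "hetree_validation_error")
})

test_that("pruning is a filtration: pruning in stages equals pruning once", {
  for (i in 1:12) {
    tr <- random_merge_tree(sample(2:8, 1), seed = 900 + i)
    es <- sort(runif(3, 0, root_height(tr) * 1.1))
    staged <- prune(prune(prune(tr, es[1]), es[2]), es[3])
    direct <- prune(tr, es[3])
    expect_identical(canonical_form(staged), canonical_form(direct))
  }
})

test_that("pruning is idempotent, monotone in eps, and never empties the tree", {
  for (i in 1:15) {
    tr <- random_merge_tree(sample(2:8, 1), seed = 100 + i)
    epss <- sort(runif(4, 0, root_height(tr) * 1.2))
    leaves_prev <- Inf
    for (e in epss) {
      p <- prune(tr, e)
      expect_identical(canonical_form(prune(p, e)), canonical_form(p))
      expect_gte(n_leaves(p), 1)
      expect_lte(n_leaves(p), leaves_prev)
      expect_lte(total_weight(p), total_weight(tr) + 1e-12)
      leaves_prev <- n_leaves(p)
    }
  }
})

test_that("newick serialization round-trips topology, weights and labels", {
  tr <- tree_0_1_10()
  nw <- to_newick(tr)
  back <- from_newick(nw)
  expect_tree_equal(tr, back)
  expect_setequal(back$label[!is.na(back$label)], c("a", "b", "c"))

  # cherry renders as a two-leaf newick with branch lengths
  expect_match(to_newick(cherry(1, 1)), "^\\(.*:1.*:1.*\\);$")

  # random round trips
  for (i in 1:10) {
    tr2 <- random_merge_tree(sample(2:10, 1), seed = 300 + i)
    expect_tree_equal(tr2, from_newick(to_newick(tr2)))
  }

  # single-leaf (pruned) and single-vertex trees survive the trip
  expect_tree_equal(single_leaf(9.5), from_newick(to_newick(single_leaf(9.5))))
  expect_equal(n_leaves(from_newick(to_newick(merge_tree(0, 0L, "x")))), 1)

  expect_error(from_newick("((a:1,b:2"), class = "hetree_parse_error")
})

test_that("trees write to per-patient newick files", {
  dir <- withr::local_tempdir()
  trees <- list(p1 = cherry(1, 2), p2 = tree_0_1_10())
  files <- write_trees(trees, dir)
  expect_true(all(file.exists(files)))
  expect_equal(basename(files), c("p1.nwk", "p2.nwk"))
  expect_tree_equal(from_newick(readLines(files[2])), tree_0_1_10())
})
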