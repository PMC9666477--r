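test_that("breakpoint profiles capture where pruning changes the tree", {
  bp <- prune_breakpoints(tree_0_1_10())
  expect_equal(bp$breakpoints, c(1, 9.5))
  expect_tree_equal(bp$segments[[1]], tree_0_1_10())
  expect_tree_equal(bp$segments[[2]], cherry(9.5, 9.5))
  expect_equal(n_leaves(bp$segments[[3]]), 1)

  # a single-vertex tree never changes
  expect_length(prune_breakpoints(merge_tree(0, 0L))$breakpoints, 0)

  # cherry(w, w): one breakpoint at w
  expect_equal(prune_breakpoints(cherry(2, 2))$breakpoints, 2)

  # exactness: the stored segment equals a fresh prune at many thresholds
  for (i in 1:8) {
    tr <- random_merge_tree(sample(2:7, 1), seed = 500 + i)
    bp <- prune_breakpoints(tr)
    for (e in seq(0, root_height(tr) * 1.1, length.out = 23)) {
      expect_identical(
        canonical_form(hetree:::profile_at(bp, e)),
        canonical_form(prune(tr, e))
      )
    }
  }
})

test_that("measures normalize and integrate over right-open intervals", {
  mu <- beta_measure(2.5, 15)
  expect_equal(
    hetree:::measure_interval_mass(mu, 0, Inf), 1,
    tolerance = 1e-12
  )
  pm <- point_mass(0)
  expect_equal(hetree:::measure_interval_mass(pm, 0, 0.5), 1)
  expect_equal(hetree:::measure_interval_mass(pm, 0.5, Inf), 0)
  dm <- discrete_measure(c(0.1, 0.4), c(3, 1))
  expect_equal(hetree:::measure_interval_mass(dm, 0, 0.4), 0.75)
  expect_error(discrete_measure(c(0.1), 0), class = "hetree_measure_error")
  expect_error(beta_measure(-1, 2), class = "hetree_measure_error")
})

test_that("the pruned distance reduces to worked values", {
  # identical trees at distance zero for any measure
  expect_equal(pruned_edit_distance(tree_0_1_10(), tree_0_1_10()), 0)

  # point mass at 0 with positive weights recovers the plain edit distance
  c11 <- cherry(1, 1)
  c13 <- cherry(1, 3)
  expect_equal(
    pruned_edit_distance(c11, c13, point_mass(0)),
    edit_distance(c11, c13)
  )

  # point mass at 2: both cherries prune to single leaves of weight 1 and 3
  expect_equal(pruned_edit_distance(c11, c13, point_mass(2)), 2)
})

test_that("exact breakpoint integration agrees with fine grid quadrature", {
  mu <- beta_measure(2.5, 15)
  for (i in 1:12) {
    a <- random_rescaled_trees(1, leaves = 2:5, seed = 8000 + i)[[1]]
    b <- random_rescaled_trees(1, leaves = 2:5, seed = 9000 + i)[[1]]
    cache <- new.env(parent = emptyenv())
    d_exact <- pruned_edit_distance(a, b, mu, mode = "exact", cache = cache)
    d_grid <- pruned_edit_distance(a, b, mu,
      mode = "grid", grid_n = 2000L,
      cache = cache
    )
    expect_equal(d_grid, d_exact, tolerance = 1e-3)
  }
})

test_that("equal-mass discretizations converge to the exact distance", {
  mu <- beta_measure(2.5, 15)
  a <- random_rescaled_trees(1, leaves = 5, seed = 41)[[1]]
  b <- random_rescaled_trees(1, leaves = 4, seed = 42)[[1]]
  cache <- new.env(parent = emptyenv())
  d_exact <- pruned_edit_distance(a, b, mu, cache = cache)
  errs <- vapply(c(10, 100, 1000), function(k) {
    dk <- pruned_edit_distance(a, b, discretize_measure(mu, k), cache = cache)
    abs(dk - d_exact)
  }, numeric(1))
  floor_err <- 0.002 * max(d_exact, 1e-12)
  expect_lte(errs[2], 0.01 * max(d_exact, 1e-12))
  expect_lte(errs[3], max(errs[2], floor_err))
  expect_lte(errs[3], max(errs[1], floor_err))
})

test_that("the pruned distance behaves as a metric on random triples", {
  trees <- random_rescaled_trees(9, leaves = 2:5, seed = 77)
  mu <- beta_measure(2.5, 15)
  cache <- new.env(parent = emptyenv())
  n <- length(trees)
  D <- matrix(0, n, n)
  for (i in 1:n) {
    for (j in 1:n) {
      D[i, j] <- pruned_edit_distance(trees[[i]], trees[[j]], mu, cache = cache)
    }
  }
  expect_equal(diag(D), rep(0, n))
  expect_equal(D, t(D), tolerance = 1e-9)
  for (i in 1:n) {
    for (j in 1:n) {
      for (k in 1:n) {
        expect_lte(D[i, k], D[i, j] + D[j, k] + 1e-9)
      }
    }
  }
})

test_that("pruned leaf counts are non-increasing in the threshold", {
  for (i in 1:6) {
    tr <- random_merge_tree(sample(3:8, 1), seed = 600 + i)
    counts <- vapply(
      seq(0, root_height(tr), length.out = 15),
      function(e) n_leaves(prune(tr, e)), numeric(1)
    )
    expect_true(all(diff(counts) <= 0))
  }
})

test_that("cohort matrices match pairwise calls and stay metric", {
  trees <- random_rescaled_trees(5, leaves = 2:5, seed = 55)
  names(trees) <- paste0("p", 1:5)
  mu <- beta_measure(2.5, 15)
  D <- cohort_distance_matrix(trees, mu)
  expect_equal(rownames(D), names(trees))
  expect_equal(diag(D), setNames(rep(0, 5), names(trees)))
  for (i in 1:4) {
    for (j in (i + 1):5) {
      expect_equal(
        D[i, j],
        pruned_edit_distance(trees[[i]], trees[[j]], mu),
        tolerance = 1e-9
      )
    }
  }
  # identical trees give a zero matrix
  same <- list(a = cherry(0.5, 0.5), b = cherry(0.5, 0.5), c = cherry(0.5, 0.5))
  expect_true(all(cohort_distance_matrix(same, mu) == 0))
})

test_that("the default measure is Beta(2.5, 15) and fitting pins its mean", {
  mu <- fit_mu(NULL)
  expect_equal(mu$alpha, 2.5)
  expect_equal(mu$beta, 15)

  # saddle at 1/7 gives beta = 15 by the mean constraint
  expect_equal(2.5 * (1 - 1 / 7) / (1 / 7), 15)

  # bimodal heights with a valley near 0.3: fitted mean within 0.3 +/- 0.05
  set.seed(13)
  low <- runif(300, 0.05, 0.18)
  high <- runif(200, 0.45, 0.9)
  trees <- lapply(c(low, high), function(h) cherry(h, h))
  mu2 <- fit_mu(trees)
  m <- mu2$alpha / (mu2$alpha + mu2$beta)
  expect_gt(m, 0.25)
  expect_lt(m, 0.35)

  # unimodal heights fall back to the default with a warning
  uni <- lapply(rnorm(500, 0.5, 0.05), function(h) cherry(abs(h), abs(h)))
  expect_warning(mu3 <- fit_mu(uni))
  expect_equal(mu3$beta, 15)
})
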