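# block-structured distance matrix: `sizes` groups, within-block distance
# `near`, between-block distance `far`
block_matrix <- function(sizes, near = 0.1, far = 2, jitter = 0.01, seed = 1) {
  n <- sum(sizes)
  g <- rep(seq_along(sizes), sizes)
  D <- matrix(far, n, n)
  D[outer(g, g, "==")] <- near
  set.seed(seed)
  noise <- matrix(runif(n * n, 0, jitter), n)
  D <- D + noise + t(noise)
  diag(D) <- 0
  rownames(D) <- colnames(D) <- paste0("p", seq_len(n))
  list(D = D, truth = g)
}

test_that("ward clustering recovers planted blocks and reports its trace", {
  bm <- block_matrix(c(6, 6, 6))
  cl <- ward_cluster(bm$D)
  expect_equal(cl$k, 3)
  expect_equal(compare_partitions(cl$labels, bm$truth), 1)
  expect_s3_class(cl$trace, "tbl_df")
  expect_equal(cl$trace$k, 2:5)
  expect_gt(cl$silhouette, 0.8)

  # two duplicated blocks: k = 2 with near-perfect silhouette
  bm2 <- block_matrix(c(8, 8), jitter = 0.001)
  cl2 <- ward_cluster(bm2$D)
  expect_equal(cl2$k, 2)
  expect_gt(cl2$silhouette, 0.9)

  # degenerate all-zero matrix: smallest k with a warning
  Z <- matrix(0, 6, 6)
  expect_warning(clz <- ward_cluster(Z), "zero")
  expect_equal(clz$k, 2)

  expect_error(ward_cluster(matrix(0, 2, 2)), class = "hetree_capacity_error")

  # tidy/glance accessors
  td <- tidy(cl)
  expect_equal(nrow(td), 18)
  expect_named(td, c("patient_id", "cluster"))
  expect_equal(glance(cl)$k, 3)
})

test_that("clustering labels are stable under patient reordering", {
  bm <- block_matrix(c(5, 7, 4), seed = 3)
  cl1 <- ward_cluster(bm$D)
  perm <- sample(nrow(bm$D))
  cl2 <- ward_cluster(bm$D[perm, perm])
  expect_equal(
    compare_partitions(cl2$labels, cl1$labels[perm]), 1
  )
})

test_that("dbscan marks sparse patients as noise on a precomputed matrix", {
  bm <- block_matrix(c(6, 6), near = 0.1, far = 3, jitter = 0.001)
  n <- nrow(bm$D)
  # append 3 patients far from everything (and each other)
  m <- n + 3
  D <- matrix(6, m, m)
  D[1:n, 1:n] <- bm$D
  set.seed(2)
  D[upper.tri(D)] <- D[upper.tri(D)] + runif(sum(upper.tri(D)), 0, 0.2)
  D[lower.tri(D)] <- t(D)[lower.tri(D)]
  diag(D) <- 0
  res <- dbscan_noise_check(D, eps = 0.5, min_samples = 3, reference = c(bm$truth, 3, 3, 3))
  expect_equal(res$n_clusters, 2)
  expect_equal(unname(res$labels[(n + 1):m]), c(0L, 0L, 0L))
  expect_equal(res$agreement, 1)

  # all identical: one cluster, no noise
  Z <- matrix(0, 5, 5)
  rz <- dbscan_noise_check(Z, eps = 0.1, min_samples = 2)
  expect_equal(rz$n_clusters, 1)
  expect_true(all(rz$labels == 1))

  # eps below the smallest positive distance: everything is noise
  ra <- dbscan_noise_check(bm$D, eps = 1e-6, min_samples = 2)
  expect_true(all(ra$labels == 0))
  expect_error(dbscan_noise_check(Z, eps = 0), class = "hetree_validation_error")
})

test_that("rand index equals brute-force pair counting", {
  expect_equal(compare_partitions(c(1, 1, 2, 2), c(1, 1, 2, 2)), 1)
  expect_equal(compare_partitions(c(1, 1, 2, 2), c(2, 2, 1, 1)), 1) # relabeling
  expect_equal(compare_partitions(c(0, 0, 1, 1), c(0, 1, 0, 1)), 1 / 3)
  brute <- function(a, b) {
    n <- length(a)
    agree <- 0
    tot <- 0
    for (i in 1:(n - 1)) {
      for (j in (i + 1):n) {
        tot <- tot + 1
        agree <- agree + ((a[i] == a[j]) == (b[i] == b[j]))
      }
    }
    agree / tot
  }
  set.seed(10)
  for (rep in 1:10) {
    a <- sample(1:3, 12, replace = TRUE)
    b <- sample(1:3, 12, replace = TRUE)
    expect_equal(compare_partitions(a, b), brute(a, b))
  }
  expect_error(compare_partitions(1:3, 1:4), class = "hetree_validation_error")
})

test_that("the biggest-lesion baseline picks volume-maximal lesions deterministically", {
  set.seed(6)
  # 12 patients in two groups whose biggest lesions are well separated
  rows <- purrr::map_dfr(1:12, function(i) {
    grp <- if (i <= 6) 0 else 8
    tibble::tibble(
      patient_id = paste0("P", i),
      lesion_id = paste0("L", 1:3),
      volume_ml = c(5, 1, 1),
      v1_pc1 = c(grp, 50, -50) + rnorm(3, sd = 0.2),
      v1_pc2 = rnorm(3, sd = 0.2)
    )
  })
  red <- structure(rows, class = c("reduced_matrix", class(rows)))
  cl <- baseline_biggest_lesion(red)
  expect_equal(cl$k, 2)
  truth <- ifelse(as.integer(sub("P", "", names(cl$labels))) <= 6, 1, 2)
  expect_equal(compare_partitions(cl$labels, truth), 1)
  # representative = the volume-5 lesion of each patient
  expect_true(all(cl$representative$lesion_id == "L1"))

  # volume ties resolve to the lowest lesion id
  tie <- rows
  tie$volume_ml <- 1
  clt <- baseline_biggest_lesion(structure(tie, class = class(red)))
  expect_true(all(clt$representative$lesion_id == "L1"))

  # missing volumes are a data error
  holes <- rows
  holes$volume_ml[3] <- NA
  expect_error(
    baseline_biggest_lesion(structure(holes, class = class(red))),
    class = "hetree_data_error"
  )
})

test_that("the mean-vector baseline averages lesions and misses spread-only contrast", {
  set.seed(12)
  # two groups with equal means but very different spread
  rows <- purrr::map_dfr(1:16, function(i) {
    spread <- if (i <= 8) 0.1 else 6
    tibble::tibble(
      patient_id = paste0("P", i),
      lesion_id = paste0("L", 1:6),
      volume_ml = 1,
      v1_pc1 = rnorm(6, 0, spread),
      v1_pc2 = rnorm(6, 0, spread)
    )
  })
  red <- structure(rows, class = c("reduced_matrix", class(rows)))
  cl <- baseline_mean_vector(red)
  truth <- ifelse(as.integer(sub("P", "", names(cl$labels))) <= 8, 1, 2)
  # the mean profile cannot see the spread difference
  ari_rand <- compare_partitions(cl$labels, truth)
  expect_lt(ari_rand, 0.7)

  # single-lesion patients: the mean is the lesion itself
  single <- rows |> dplyr::filter(lesion_id == "L1")
  red1 <- structure(single, class = class(red))
  m <- baseline_mean_vector(red1)
  expect_equal(
    m$representative$v1_pc1,
    single$v1_pc1[match(m$representative$patient_id, single$patient_id)]
  )
})

test_that("the characterization battery gates on normality and flags at alpha", {
  set.seed(30)
  clinical <- tibble::tibble(
    patient_id = paste0("P", 1:40),
    psa = c(rnorm(20, 10, 2), rnorm(20, 16, 2)), # strong location shift
    flat = rep(1, 40), # constant covariate
    therapy = rep(c("mono", "combo"), 20) # unrelated categorical
  )
  labels <- setNames(rep(1:2, each = 20), clinical$patient_id)
  rep <- characterize_clusters(labels, clinical, alpha = 0.1)
  expect_s3_class(rep, "cluster_report")
  psa_loc <- rep[rep$variable == "psa" & rep$family == "location", ]
  expect_lt(psa_loc$p_value, 0.001)
  expect_true(psa_loc$significant)
  expect_true(psa_loc$test %in% c("t", "mann-whitney"))
  expect_false(is.na(psa_loc$p_one_sided))
  # constant variable: degenerate tests return NA, never an error
  flat_rows <- rep[rep$variable == "flat", ]
  expect_true(all(is.na(flat_rows$p_value) | flat_rows$p_value > 0.1))
  # unrelated categorical not significant
  ther <- rep[rep$variable == "therapy", ]
  expect_false(ther$significant)

  # small groups fall back to non-parametric with a warning
  tiny_labels <- setNames(c(1, 1, 2, 2), paste0("P", 1:4))
  tiny <- clinical[1:4, ]
  warnings <- testthat::capture_warnings(
    rep2 <- characterize_clusters(tiny_labels, tiny, alpha = 0.1)
  )
  expect_true(any(grepl("Shapiro", warnings)))
  expect_equal(
    rep2$test[rep2$variable == "psa" & rep2$family == "location"],
    "mann-whitney"
  )
})

test_that("location power: a 2-sigma shift at n=20 is detected almost surely", {
  hits <- 0
  for (r in 1:40) {
    set.seed(4000 + r)
    x <- rnorm(20, 0, 1)
    y <- rnorm(20, 2, 1)
    clinical <- tibble::tibble(patient_id = paste0("P", 1:40), v = c(x, y))
    labels <- setNames(rep(1:2, each = 20), clinical$patient_id)
    rep <- characterize_clusters(labels, clinical, alpha = 0.1)
    p <- rep$p_value[rep$family == "location"]
    if (!is.na(p) && p < 0.1) hits <- hits + 1
  }
  expect_gte(hits / 40, 0.95)
})

test_that("group height curves summarize and test group differences", {
  # groups with systematically different branch lengths
  lows <- lapply(1:8, function(i) random_merge_tree(5, weight_law = function(n) rexp(n, 10), seed = i))
  highs <- lapply(1:8, function(i) random_merge_tree(5, weight_law = function(n) rexp(n, 10) + 0.8, seed = 50 + i))
  trees <- c(lows, highs)
  labels <- rep(c("low", "high"), each = 8)
  grid <- seq(0, 3, length.out = 12)
  res <- group_height_curves(trees, labels, grid, n_permutations = 199, seed = 9)
  expect_s3_class(res$summary, "tbl_df")
  # means are non-increasing in the threshold within each group
  for (g in c("low", "high")) {
    m <- res$summary$mean[res$summary$group == g]
    expect_true(all(diff(m) <= 1e-9))
  }
  # clear separation on the mid-height interval
  expect_lt(min(res$pointwise_p), 0.05)

  # identical trees in all groups: no signal anywhere
  same <- rep(list(cherry(1, 1)), 10)
  res0 <- group_height_curves(same, rep(c("a", "b"), 5), grid,
    n_permutations = 99, seed = 2
  )
  expect_true(all(res0$pointwise_p > 0.9))
  expect_true(all(res0$summary$sd == 0))
})

test_that("kaplan-meier curves and the log-rank test behave per group", {
  # one group responds early, the other is fully censored
  set.seed(14)
  labels <- rep(c("fast", "never"), each = 30)
  time <- c(rexp(30, 1), rep(10, 30))
  event <- c(rep(1L, 30), rep(0L, 30))
  km <- km_logrank(labels, time, event)
  expect_lt(km$p_value, 0.001)
  expect_equal(km$n_groups, 2)

  # no events anywhere: flat curves, undefined comparison
  km0 <- km_logrank(labels, rep(5, 60), rep(0L, 60))
  expect_true(all(km0$fit$surv == 1))
  expect_true(is.na(km0$p_value))

  expect_error(km_logrank(labels, -time, event), class = "hetree_data_error")
  expect_equal(glance(km)$p_logrank, km$p_value)
})
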