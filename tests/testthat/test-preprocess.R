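write_fixture_csv <- function(tab) {
  path <- withr::local_tempfile(fileext = ".csv", .local_envir = parent.frame())
  readr::write_csv(tab, path)
  path
}

make_table <- function(n = 3, schema = default_view_schema(), seed = 1) {
  set.seed(seed)
  feats <- hetree:::schema_features(schema)
  tab <- tibble::tibble(
    patient_id = paste0("P", seq_len(n)),
    lesion_id = paste0("L", seq_len(n)),
    volume_ml = runif(n, 1, 10)
  )
  for (f in feats) tab[[f]] <- rnorm(n)
  tab
}

test_that("feature tables round-trip through CSV with schema validation", {
  schema <- default_view_schema()
  tab <- make_table(3)
  path <- write_fixture_csv(tab)
  rt <- read_feature_table(path, schema)
  expect_s3_class(rt, "radiomic_table")
  expect_equal(nrow(rt), 3)
  expect_equal(rt$glcm_f1, tab$glcm_f1)

  # missing schema feature -> format error naming the column
  bad <- tab[, setdiff(names(tab), "glcm_f1")]
  expect_error(
    read_feature_table(write_fixture_csv(bad), schema),
    "glcm_f1",
    class = "hetree_format_error"
  )

  # duplicate key -> integrity error
  dup <- dplyr::bind_rows(tab, tab[1, ])
  expect_error(
    read_feature_table(write_fixture_csv(dup), schema),
    class = "hetree_integrity_error"
  )

  # a non-numeric cell becomes exactly one missing value
  tab2 <- tab
  tab2$shape_f1 <- as.character(tab2$shape_f1)
  tab2$shape_f1[2] <- "not-a-number"
  rt2 <- read_feature_table(write_fixture_csv(tab2), schema)
  expect_equal(sum(is.na(rt2[, hetree:::schema_features(schema)])), 1)
  expect_true(is.na(rt2$shape_f1[2]))
})

test_that("median imputation fills gaps and leaves observed cells alone", {
  schema <- default_view_schema()
  tab <- as_radiomic_table(make_table(3), schema)
  tab$firstorder_f1 <- c(1, NA, 3)
  out <- impute_missing(tab)
  expect_equal(out$firstorder_f1, c(1, 2, 3)) # median of {1, 3}
  expect_equal(out$glcm_f2, tab$glcm_f2)

  # table without missing values is unchanged
  full <- as_radiomic_table(make_table(4), schema)
  expect_equal(
    as.data.frame(impute_missing(full)),
    as.data.frame(full)
  )

  # an all-missing column cannot be imputed
  tab$ngldm_f1 <- NA_real_
  expect_error(impute_missing(tab), "ngldm_f1", class = "hetree_data_error")
})

test_that("z-normalization standardizes with n-1 and drops constant columns", {
  schema <- default_view_schema()
  tab <- as_radiomic_table(make_table(2), schema)
  tab$firstorder_f1 <- c(0, 2)
  out <- z_normalize(tab)
  expect_equal(out$firstorder_f1, c(-1, 1) / sqrt(2), tolerance = 1e-12)

  feats <- hetree:::schema_features(hetree:::table_schema(out))
  for (f in feats) {
    expect_lt(abs(mean(out[[f]])), 1e-9)
    expect_lt(abs(sd(out[[f]]) - 1), 1e-9)
  }

  # idempotence up to tolerance
  out2 <- z_normalize(out)
  expect_equal(as.data.frame(out2), as.data.frame(out), tolerance = 1e-9)

  # constant column dropped with a warning, not an error
  tab3 <- as_radiomic_table(make_table(5), schema)
  tab3$shape_f2 <- 7
  expect_warning(out3 <- z_normalize(tab3), "shape_f2")
  expect_false("shape_f2" %in% names(out3))
})

test_that("view-aware PCA yields 2 orthogonal components per view, deterministically", {
  schema <- default_view_schema()
  tab <- make_table(25) |>
    as_radiomic_table(schema) |>
    impute_missing() |>
    z_normalize()
  red <- view_aware_pca(tab)
  cols <- hetree:::reduced_score_columns(red)
  expect_length(cols, 12) # 2 x 6 views
  for (v in schema$views) {
    s1 <- red[[paste0(v, "_pc1")]]
    s2 <- red[[paste0(v, "_pc2")]]
    expect_lt(abs(cor(s1, s2)), 1e-8)
    ev <- attr(red, "explained_variance")[[v]]
    expect_true(all(ev >= 0 & ev <= 1))
    expect_gte(ev[1], ev[2])
  }
  # bit-identical rerun (fixed sign convention)
  red2 <- view_aware_pca(tab)
  expect_identical(as.data.frame(red2), as.data.frame(red))

  # a view with two perfectly correlated features: first component takes all
  small_schema <- view_schema(c(f1 = "v1", f2 = "v1", g1 = "v2", g2 = "v2"))
  set.seed(9)
  st <- tibble::tibble(
    patient_id = paste0("P", 1:20), lesion_id = paste0("L", 1:20),
    volume_ml = 1, f1 = rnorm(20), g1 = rnorm(20), g2 = rnorm(20)
  )
  st$f2 <- st$f1
  st <- as_radiomic_table(st, small_schema) |> impute_missing()
  # skip z-normalization to keep f2 == f1 exactly collinear
  redc <- view_aware_pca(st, small_schema)
  ev <- attr(redc, "explained_variance")[["v1"]]
  expect_equal(ev[1], 1, tolerance = 1e-12)
  expect_equal(ev[2], 0, tolerance = 1e-12)

  # a view with too few usable features is a configuration error
  thin <- view_schema(c(f1 = "v1", g1 = "v2", g2 = "v2"))
  tt <- tibble::tibble(
    patient_id = paste0("P", 1:5), lesion_id = paste0("L", 1:5),
    volume_ml = 1, f1 = rnorm(5), g1 = rnorm(5), g2 = rnorm(5)
  )
  tt <- as_radiomic_table(tt, thin)
  expect_error(view_aware_pca(tt, thin), "v1", class = "hetree_config_error")
})

test_that("data already in per-view principal axes is recovered up to sign", {
  # oracle: eigen-decomposition of each view covariance; feed uncorrelated
  # per-view scores and expect them back (up to column sign)
  schema <- view_schema(c(a1 = "v1", a2 = "v1", b1 = "v2", b2 = "v2"))
  set.seed(4)
  n <- 300
  z <- cbind(rnorm(n, sd = 3), rnorm(n, sd = 1), rnorm(n, sd = 2), rnorm(n, sd = 0.5))
  tab <- tibble::tibble(
    patient_id = paste0("P", seq_len(n)), lesion_id = paste0("L", seq_len(n)),
    volume_ml = 1, a1 = z[, 1], a2 = z[, 2], b1 = z[, 3], b2 = z[, 4]
  )
  tab <- as_radiomic_table(tab, schema)
  red <- view_aware_pca(tab, schema)
  for (pair in list(c("a1", "v1_pc1"), c("a2", "v1_pc2"), c("b1", "v2_pc1"), c("b2", "v2_pc2"))) {
    r <- cor(tab[[pair[1]]], red[[pair[2]]])
    expect_gt(abs(r), 0.99)
  }
})

test_that("point clouds partition the reduced rows patient by patient", {
  schema <- default_view_schema()
  tab <- make_table(12)
  tab$patient_id <- rep(c("A", "B", "C"), times = c(7, 4, 1))
  tab$lesion_id <- paste0("L", 1:12)
  red <- tab |>
    as_radiomic_table(schema) |>
    impute_missing() |>
    z_normalize() |>
    view_aware_pca()
  cloud <- patient_point_cloud(red, "A")
  expect_equal(nrow(cloud$points), 7)
  expect_equal(ncol(cloud$points), 12)
  single <- patient_point_cloud(red, "C")
  expect_equal(nrow(single$points), 1)
  total <- sum(vapply(
    c("A", "B", "C"),
    function(p) nrow(patient_point_cloud(red, p)$points), numeric(1)
  ))
  expect_equal(total, nrow(red))
  expect_error(patient_point_cloud(red, "nope"), class = "hetree_lookup_error")
})

test_that("lesion distances are plain Euclidean distances", {
  cloud <- structure(
    list(
      patient_id = "p", points = rbind(c(0, 0), c(3, 4)),
      lesion_ids = c("l1", "l2")
    ),
    class = "point_cloud"
  )
  D <- lesion_distance_matrix(cloud)
  expect_equal(D["l1", "l2"], 5)
  expect_equal(diag(D), c(l1 = 0, l2 = 0))

  set.seed(11)
  pts <- matrix(rnorm(15), 5, 3)
  cloud2 <- structure(
    list(patient_id = "q", points = pts, lesion_ids = paste0("l", 1:5)),
    class = "point_cloud"
  )
  D2 <- lesion_distance_matrix(cloud2)
  # brute-force double loop oracle
  for (i in 1:5) {
    for (j in 1:5) {
      expect_equal(D2[i, j], sqrt(sum((pts[i, ] - pts[j, ])^2)), tolerance = 1e-12)
    }
  }
})
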