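#' Read a lesion-level radiomic feature table
#'
#' Reads a CSV with one row per segmented lesion: `patient_id`, `lesion_id`,
#' `volume_ml`, and one numeric column per schema feature. Non-numeric cells
#' in feature columns become missing values (to be handled by
#' [impute_missing()]).
#'
#' @param path CSV path.
#' @param schema A [view_schema()]; defaults to the six-view layout.
#' @return A tibble of class `radiomic_table` carrying the schema as an
#'   attribute.
#' @export
read_feature_table <- function(path, schema = default_view_schema()) {
  if (!file.exists(path)) {
    stop_hetree(paste0("Feature table not found: ", path), "hetree_format_error")
  }
  tab <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  as_radiomic_table(tab, schema)
}

#' @rdname read_feature_table
#' @param tab A data frame with the documented columns.
#' @export
as_radiomic_table <- function(tab, schema = default_view_schema()) {
  feats <- schema_features(schema)
  required <- c("patient_id", "lesion_id", "volume_ml", feats)
  missing_cols <- setdiff(required, names(tab))
  if (length(missing_cols) > 0L) {
    stop_hetree(
      paste0("Feature table is missing column(s): ", paste(missing_cols, collapse = ", ")),
      "hetree_format_error"
    )
  }
  tab <- tibble::as_tibble(tab)[, required]
  tab$patient_id <- as.character(tab$patient_id)
  tab$lesion_id <- as.character(tab$lesion_id)
  key <- paste(tab$patient_id, tab$lesion_id, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- tab[duplicated(key), c("patient_id", "lesion_id")][1, ]
    stop_hetree(
      paste0(
        "Duplicate (patient_id, lesion_id) key: (",
        dup$patient_id, ", ", dup$lesion_id, ")"
      ),
      "hetree_integrity_error"
    )
  }
  tab$volume_ml <- suppressWarnings(as.numeric(tab$volume_ml))
  if (any(!is.na(tab$volume_ml) & tab$volume_ml < 0)) {
    stop_hetree("Lesion volumes must be non-negative.", "hetree_integrity_error")
  }
  for (f in feats) tab[[f]] <- suppressWarnings(as.numeric(tab[[f]]))
  structure(tab, schema = schema, class = c("radiomic_table", class(tab)))
}

table_schema <- function(table) {
  schema <- attr(table, "schema")
  if (is.null(schema)) {
    stop_hetree("Not a radiomic table: no attached view schema.", "hetree_validation_error")
  }
  schema
}

# keep the radiomic_table class and schema through dplyr-style subsetting
restore_radiomic <- function(new, old) {
  structure(tibble::as_tibble(new),
    schema = attr(old, "schema"),
    class = class(old)
  )
}

#' Impute missing radiomic feature values
#'
#' Replaces missing cells of each feature column by the per-feature median
#' (default) or mean over the observed lesions. Non-missing cells are left
#' untouched. Radiomic exports routinely contain sporadic missing entries
#' (failed texture computations on tiny lesions); the median is preferred as
#' radiomic feature distributions are heavy tailed.
#'
#' @param table A `radiomic_table`.
#' @param method `"median"` (default) or `"mean"`.
#' @return The table with complete feature columns.
#' @export
impute_missing <- function(table, method = c("median", "mean")) {
  method <- match.arg(method)
  schema <- table_schema(table)
  fun <- if (method == "median") {
    function(x) median(x, na.rm = TRUE)
  } else {
    function(x) mean(x, na.rm = TRUE)
  }
  for (f in schema_features(schema)) {
    x <- table[[f]]
    if (all(is.na(x))) {
      stop_hetree(
        paste0("Feature '", f, "' is entirely missing; cannot impute."),
        "hetree_data_error"
      )
    }
    x[is.na(x)] <- fun(x)
    table[[f]] <- x
  }
  table
}

#' Z-transform radiomic features
#'
#' Standardizes every feature column to mean 0 and sample standard deviation
#' 1 (denominator `n - 1`), cohort-wide. Constant columns carry no
#' information and cannot be standardized; they are dropped from the schema
#' with a warning rather than raising an error, since real radiomic exports
#' contain them.
#'
#' @param table An imputed `radiomic_table`.
#' @return The standardized table (schema possibly reduced).
#' @export
z_normalize <- function(table) {
  schema <- table_schema(table)
  feats <- schema_features(schema)
  if (anyNA(table[, feats])) {
    stop_hetree("Impute missing values before z-normalization.", "hetree_validation_error")
  }
  sds <- vapply(table[, feats], sd, numeric(1))
  constant <- feats[sds == 0 | is.na(sds)]
  if (length(constant) > 0L) {
    warn(paste0(
      "Dropping constant feature column(s): ",
      paste(constant, collapse = ", ")
    ))
    keep <- setdiff(feats, constant)
    schema <- view_schema(
      schema$view_of_feature[keep],
      intersect(schema$views, unique(schema$view_of_feature[keep]))
    )
    table <- restore_radiomic(
      table[, c("patient_id", "lesion_id", "volume_ml", keep)], table
    )
    attr(table, "schema") <- schema
    feats <- keep
  }
  for (f in feats) {
    x <- table[[f]]
    table[[f]] <- (x - mean(x)) / sd(x)
  }
  table
}

#' View-aware principal component reduction
#'
#' Performs one PCA per view on the standardized feature sub-matrix of that
#' view and retains the top `k_per_view` components of each, so that every
#' texture family contributes the same number of coordinates to the reduced
#' lesion vector regardless of how many raw features it holds. With the
#' default six views and `k_per_view = 2` each lesion becomes a
#' 12-dimensional vector.
#'
#' The PCA is fit on all lesions of the cohort jointly (lesions are reduced
#' before being split into patients). Component signs are fixed so that the
#' loading of largest absolute value in each component is positive, making
#' the reduction fully deterministic.
#'
#' @param table An imputed, z-normalized `radiomic_table`.
#' @param schema Optional schema override; defaults to the table's own.
#' @param k_per_view Components kept per view (default 2).
#' @return A tibble of class `reduced_matrix` with columns `patient_id`,
#'   `lesion_id`, `volume_ml` and `<view>_pc1 ... <view>_pc<k>`; attributes
#'   `explained_variance` (per view, per component, fractions of the view's
#'   total variance) and `loadings` (per view).
#' @export
view_aware_pca <- function(table, schema = NULL, k_per_view = 2L) {
  if (is.null(schema)) schema <- table_schema(table)
  k_per_view <- as.integer(k_per_view)
  if (nrow(table) < 2L) {
    stop_hetree("Need at least 2 lesions to fit a PCA.", "hetree_validation_error")
  }
  scores <- list()
  expl <- list()
  loadings <- list()
  for (v in schema$views) {
    feats <- schema_view_features(schema, v)
    x <- as.matrix(table[, feats])
    usable <- sum(apply(x, 2, sd) > 0)
    if (length(feats) < k_per_view || usable < k_per_view) {
      stop_hetree(
        paste0(
          "View '", v, "' has fewer than ", k_per_view,
          " usable (non-constant) features."
        ),
        "hetree_config_error"
      )
    }
    p <- prcomp(x, center = TRUE, scale. = FALSE)
    rot <- p$rotation[, seq_len(k_per_view), drop = FALSE]
    # sign convention: dominant loading of each component is positive
    for (j in seq_len(ncol(rot))) {
      i_max <- which.max(abs(rot[, j]))
      if (rot[i_max, j] < 0) rot[, j] <- -rot[, j]
    }
    sc <- scale(x, center = p$center, scale = FALSE) %*% rot
    colnames(sc) <- paste0(v, "_pc", seq_len(k_per_view))
    scores[[v]] <- sc
    expl[[v]] <- (p$sdev^2 / sum(p$sdev^2))[seq_len(k_per_view)]
    loadings[[v]] <- rot
  }
  out <- dplyr::bind_cols(
    table[, c("patient_id", "lesion_id", "volume_ml")],
    tibble::as_tibble(do.call(cbind, unname(scores)))
  )
  structure(out,
    schema = schema,
    k_per_view = k_per_view,
    explained_variance = expl,
    loadings = loadings,
    class = c("reduced_matrix", class(out))
  )
}

reduced_score_columns <- function(reduced) {
  setdiff(names(reduced), c("patient_id", "lesion_id", "volume_ml"))
}

#' Extract one patient's lesions as a point cloud
#'
#' All lesions of a patient form a finite point cloud in the reduced radiomic
#' space; the cloud (its dispersion and sub-cluster structure) is the raw
#' material of the patient's dendrogram representation.
#'
#' @param reduced A `reduced_matrix`.
#' @param patient_id Patient identifier.
#' @return A list of class `point_cloud` with `patient_id`, `points`
#'   (n_i x d matrix) and `lesion_ids`.
#' @export
patient_point_cloud <- function(reduced, patient_id) {
  rows <- which(reduced$patient_id == as.character(patient_id))
  if (length(rows) == 0L) {
    stop_hetree(paste0("Unknown patient: ", patient_id), "hetree_lookup_error")
  }
  cols <- reduced_score_columns(reduced)
  structure(
    list(
      patient_id = as.character(patient_id),
      points = as.matrix(reduced[rows, cols]),
      lesion_ids = reduced$lesion_id[rows]
    ),
    class = "point_cloud"
  )
}

#' Pairwise Euclidean distances between a patient's lesions
#'
#' @param cloud A `point_cloud`.
#' @return A symmetric matrix with zero diagonal, row/col names the lesion ids.
#' @export
lesion_distance_matrix <- function(cloud) {
  d <- as.matrix(dist(cloud$points, method = "euclidean"))
  dimnames(d) <- list(cloud$lesion_ids, cloud$lesion_ids)
  d
}
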