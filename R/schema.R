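#' View schemas for radiomic feature tables
#'
#' Radiomic texture features fall into semantic groups ("views") according to
#' the texture-matrix construction they derive from. The default schema has
#' the six standard views: first-order statistics of the grey-level
#' distribution, lesion shape descriptors, and the GLCM (grey-level
#' co-occurrence at a fixed voxel offset), GLRLM (run lengths), GLZLM
#' (homogeneous zone sizes) and NGLDM (neighbourhood grey-level difference)
#' matrix families. A schema maps every feature name to exactly one view;
#' dimensionality reduction is performed view by view so that each texture
#' family keeps a balanced share of the reduced representation.
#'
#' @param view_of_feature Named character vector: `feature name -> view name`.
#' @param views Optional character vector fixing the view order; defaults to
#'   order of first appearance.
#' @return An object of class `view_schema`.
#' @export
view_schema <- function(view_of_feature, views = NULL) {
  if (is.null(names(view_of_feature)) || any(!nzchar(names(view_of_feature)))) {
    stop_hetree("`view_of_feature` must be a named vector (feature -> view).", "hetree_validation_error")
  }
  if (anyDuplicated(names(view_of_feature))) {
    stop_hetree("Each feature must map to exactly one view.", "hetree_validation_error")
  }
  vof <- vapply(view_of_feature, as.character, character(1))
  if (is.null(views)) views <- unique(unname(vof))
  if (!setequal(views, unique(unname(vof)))) {
    stop_hetree("`views` must list exactly the views used by `view_of_feature`.", "hetree_validation_error")
  }
  structure(
    list(view_of_feature = vof, views = as.character(views)),
    class = "view_schema"
  )
}

#' @rdname view_schema
#' @param n_per_view Integer vector (recycled) of feature counts per view for
#'   the default synthetic layout; the standard table spreads 40 features as
#'   evenly as possible over the six views, matching the synthetic-cohort
#'   generator.
#' @export
default_view_schema <- function(n_per_view = c(7, 6, 7, 7, 6, 7)) {
  views <- c("firstorder", "shape", "glcm", "glrlm", "glzlm", "ngldm")
  n_per_view <- rep_len(n_per_view, length(views))
  feats <- unlist(purrr::map2(
    views, n_per_view,
    function(v, k) setNames(rep(v, k), paste0(v, "_f", seq_len(k)))
  ))
  view_schema(feats, views)
}

#' @rdname view_schema
#' @param path Path to a YAML or JSON file of the form `{feature: view}`, or
#'   `{view_of_feature: {...}, views: [...]}`.
#' @export
read_view_schema <- function(path) {
  if (!file.exists(path)) {
    stop_hetree(paste0("Schema file not found: ", path), "hetree_format_error")
  }
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (!is.null(raw$view_of_feature)) {
    view_schema(unlist(raw$view_of_feature), raw$views)
  } else {
    view_schema(unlist(raw))
  }
}

#' @export
print.view_schema <- function(x, ...) {
  cat("<view_schema> ", length(x$view_of_feature), " features in ",
    length(x$views), " views: ", paste(x$views, collapse = ", "), "\n",
    sep = ""
  )
  invisible(x)
}

schema_features <- function(schema) names(schema$view_of_feature)

schema_view_features <- function(schema, view) {
  names(schema$view_of_feature)[schema$view_of_feature == view]
}
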