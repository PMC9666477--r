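#' Pipeline configuration
#'
#' Assembles and validates the configuration of the full stratification
#' pipeline. Defaults reproduce the reference protocol: median imputation,
#' cohort-wide z-normalization, two components per view, average linkage
#' within patients, global height rescaling, Beta(2.5, 15) weighting
#' measure, ward linkage between patients with k selected in 2..5.
#'
#' @param feature_table Path to the lesion CSV (or `NULL` when a table is
#'   passed to [run_pipeline()] directly).
#' @param schema Path to a schema YAML/JSON, or a [view_schema()].
#' @param clinical Optional path to a clinical covariate CSV.
#' @param output_dir Directory for pipeline artifacts.
#' @param impute `"median"` or `"mean"`.
#' @param k_per_view Components kept per view.
#' @param rescale `"global"` or `"per_tree"`.
#' @param mu Measure spec: a [beta_measure()]/[point_mass()] object or a
#'   list like `list(family = "beta", alpha = 2.5, beta = 15)`.
#' @param k_range Candidate cluster numbers.
#' @param integration `"exact"` or `"grid"`.
#' @param solver_gap Relative optimality-gap certificate for cohort
#'   edit-distance solving (fraction of total tree weight); see
#'   [cohort_distance_matrix()].
#' @param solver_nodes Per-call search budget for cohort edit-distance
#'   solving; the best explicit edit script is kept when the budget is hit.
#' @param seed Master seed for every stochastic step.
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(feature_table = NULL, schema = NULL, clinical = NULL,
                            output_dir = NULL,
                            impute = c("median", "mean"), k_per_view = 2L,
                            rescale = c("global", "per_tree"),
                            mu = list(family = "beta", alpha = 2.5, beta = 15),
                            k_range = 2:5,
                            integration = c("exact", "grid"),
                            solver_gap = 0.1,
                            solver_nodes = 5e4,
                            seed = 1L) {
  impute <- match.arg(impute)
  rescale <- match.arg(rescale)
  integration <- match.arg(integration)
  if (!inherits(mu, "tree_measure")) {
    mu <- parse_measure_spec(mu)
  }
  if (!is.null(schema) && !inherits(schema, "view_schema") && !is.character(schema)) {
    stop_hetree("`schema` must be a view_schema or a file path.", "hetree_validation_error")
  }
  structure(
    list(
      feature_table = feature_table, schema = schema, clinical = clinical,
      output_dir = output_dir, impute = impute,
      k_per_view = as.integer(k_per_view), rescale = rescale, mu = mu,
      k_range = as.integer(k_range), integration = integration,
      solver_gap = solver_gap, solver_nodes = solver_nodes,
      seed = as.integer(seed)
    ),
    class = "pipeline_config"
  )
}

parse_measure_spec <- function(spec) {
  if (is.null(spec$family)) {
    stop_hetree("Measure spec needs a `family` field.", "hetree_validation_error")
  }
  switch(as.character(spec$family),
    beta = beta_measure(
      spec$alpha %||% 2.5,
      spec$beta %||% 15
    ),
    point_mass = point_mass(spec$at %||% 0),
    discrete = discrete_measure(unlist(spec$at), unlist(spec$mass)),
    stop_hetree(
      paste0("Unknown measure family: ", spec$family),
      "hetree_validation_error"
    )
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file with the fields of [pipeline_config()].
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0L) {
    stop_hetree(
      paste0("Unknown config field(s): ", paste(unknown, collapse = ", ")),
      "hetree_validation_error"
    )
  }
  if (!is.null(raw$k_range)) raw$k_range <- seq(raw$k_range[[1]], raw$k_range[[length(raw$k_range)]])
  do.call(pipeline_config, raw)
}

#' Run the full stratification pipeline
#'
#' Executes the end-to-end protocol: read (or accept) the lesion feature
#' table, impute and z-normalize, reduce by view-aware PCA, build one
#' average-linkage merge tree per patient, rescale heights, compute the
#' pruned-edit-distance matrix under the configured measure, cluster with
#' ward linkage, and (when clinical data are available) characterize the
#' clusters. All intermediates are returned; when `config$output_dir` is
#' set they are also persisted (reduced CSV, one Newick file per patient,
#' distance CSV, labels CSV, and a YAML run manifest with the seed and
#' configuration, so identical manifests imply identical outputs).
#'
#' @param config A [pipeline_config()].
#' @param table Optional in-memory `radiomic_table` (bypasses
#'   `config$feature_table`).
#' @param clinical Optional in-memory clinical tibble.
#' @return A list of class `pipeline_result` with `reduced`, `trees`,
#'   `trees_rescaled`, `distance`, `clustering`, `report` (or `NULL`),
#'   `config`.
#' @export
run_pipeline <- function(config, table = NULL, clinical = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.null(table)) {
    if (is.null(config$feature_table)) {
      stop_hetree("No feature table given (config or argument).", "hetree_validation_error")
    }
    schema <- if (inherits(config$schema, "view_schema")) {
      config$schema
    } else if (is.character(config$schema)) {
      read_view_schema(config$schema)
    } else {
      default_view_schema()
    }
    table <- read_feature_table(config$feature_table, schema)
  }
  if (is.null(clinical) && !is.null(config$clinical)) {
    clinical <- readr::read_csv(config$clinical, show_col_types = FALSE, progress = FALSE)
  }

  reduced <- table |>
    impute_missing(method = config$impute) |>
    z_normalize() |>
    view_aware_pca(k_per_view = config$k_per_view)
  trees <- patient_trees(reduced)
  trees_rescaled <- rescale_heights(trees, mode = config$rescale)
  D <- cohort_distance_matrix(trees_rescaled,
    mu = config$mu,
    mode = config$integration, seed = config$seed,
    solver_gap = config$solver_gap, solver_nodes = config$solver_nodes
  )
  response <- if (!is.null(clinical) && "response" %in% names(clinical)) {
    clinical$response[match(rownames(D), clinical$patient_id)]
  } else {
    NULL
  }
  clustering <- ward_cluster(D, k_range = config$k_range, response = response)
  report <- if (!is.null(clinical)) {
    characterize_clusters(clustering$labels, clinical)
  } else {
    NULL
  }
  result <- structure(
    list(
      reduced = reduced, trees = trees, trees_rescaled = trees_rescaled,
      distance = D, clustering = clustering, report = report, config = config
    ),
    class = "pipeline_result"
  )
  if (!is.null(config$output_dir)) persist_pipeline(result)
  result
}

persist_pipeline <- function(result) {
  out <- result$config$output_dir
  if (!dir.exists(out)) dir.create(out, recursive = TRUE)
  readr::write_csv(tibble::as_tibble(result$reduced), file.path(out, "reduced.csv"))
  write_trees(result$trees, file.path(out, "trees"))
  D <- result$distance
  readr::write_csv(
    dplyr::bind_cols(
      tibble::tibble(patient_id = rownames(D)),
      tibble::as_tibble(D)
    ),
    file.path(out, "distance.csv")
  )
  readr::write_csv(tidy(result$clustering), file.path(out, "labels.csv"))
  if (!is.null(result$report)) {
    readr::write_csv(tibble::as_tibble(result$report), file.path(out, "report.csv"))
  }
  cfg <- result$config
  manifest <- list(
    seed = cfg$seed,
    impute = cfg$impute,
    k_per_view = cfg$k_per_view,
    rescale = cfg$rescale,
    mu = if (cfg$mu$family == "beta") {
      list(family = "beta", alpha = cfg$mu$alpha, beta = cfg$mu$beta)
    } else {
      list(family = "discrete", at = cfg$mu$at, mass = cfg$mu$mass)
    },
    k_range = cfg$k_range,
    integration = cfg$integration,
    solver_gap = cfg$solver_gap,
    solver_nodes = cfg$solver_nodes,
    n_patients = length(result$trees),
    selected_k = result$clustering$k
  )
  yaml::write_yaml(manifest, file.path(out, "manifest.yaml"))
  invisible(result)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result> ", length(x$trees), " patients, k = ",
    x$clustering$k, "\n",
    sep = ""
  )
  invisible(x)
}
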