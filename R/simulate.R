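#' Heterogeneity archetypes for synthetic patients
#'
#' Three qualitative shapes of a patient's lesion point cloud in the
#' reduced radiomic space, mirroring the canonical dendrogram conformations:
#'
#' * `"homogeneous"` -- lesions concentrate in a small region (one imaging
#'   phenotype): a single Gaussian with spread `sigma_within`; all
#'   dendrogram merges happen low.
#' * `"clustered"` -- groups of homogeneous lesions, mutually
#'   heterogeneous: a mixture of `n_subclusters` Gaussians whose centers
#'   are separated by `delta`; the dendrogram shows low blocks joined by
#'   tall edges.
#' * `"scattered"` -- lesions spread widely with no sub-structure: a broad
#'   Gaussian with spread scaled by `delta`; all merges happen high.
#'
#' The defaults (`sigma_within = 0.2`, `delta = 3` in reduced-space units)
#' are declared constants chosen so that pooled dendrogram heights of a
#' mixed cohort show the characteristic bimodal density with an interior
#' valley separating homogeneous from heterogeneous merges.
#'
#' @param name One of `"homogeneous"`, `"clustered"`, `"scattered"`.
#' @param sigma_within Within-phenotype spread (> 0).
#' @param delta Between-phenotype separation (>= 0).
#' @param n_subclusters Number of phenotype sub-clusters (`clustered` only,
#'   >= 2; default 3).
#' @param lesion_lambda Mean of the truncated-Poisson lesion-count law.
#' @param lesion_range Admissible lesion counts (default 1 to 20).
#' @return An object of class `archetype_spec`.
#' @export
archetype_spec <- function(name = c("homogeneous", "clustered", "scattered"),
                           sigma_within = 0.2, delta = 3,
                           n_subclusters = 3L,
                           lesion_lambda = 6, lesion_range = c(1L, 20L)) {
  name <- match.arg(name)
  if (sigma_within <= 0) {
    stop_hetree("`sigma_within` must be positive.", "hetree_config_error")
  }
  if (delta < 0) stop_hetree("`delta` must be non-negative.", "hetree_config_error")
  if (name == "clustered" && n_subclusters < 2L) {
    stop_hetree("A clustered archetype needs >= 2 sub-clusters.", "hetree_config_error")
  }
  structure(
    list(
      name = name, sigma_within = sigma_within, delta = delta,
      n_subclusters = as.integer(n_subclusters),
      lesion_lambda = lesion_lambda, lesion_range = as.integer(lesion_range)
    ),
    class = "archetype_spec"
  )
}

rtrunc_pois <- function(n, lambda, range) {
  out <- integer(0)
  while (length(out) < n) {
    x <- rpois(2L * n + 10L, lambda)
    out <- c(out, x[x >= range[1] & x <= range[2]])
  }
  out[seq_len(n)]
}

#' Simulate one patient's lesion point cloud
#'
#' Draws `n_lesions` latent lesion positions in `dim` dimensions according
#' to an archetype (see [archetype_spec()]). The patient-level center is
#' standard normal so different patients occupy different regions of the
#' reduced space.
#'
#' @param archetype An [archetype_spec()] (or archetype name).
#' @param n_lesions Number of lesions (>= 1).
#' @param dim Embedding dimension (default 12, the reduced radiomic space).
#' @param seed Integer seed; generation is a pure function of
#'   `(archetype, n_lesions, dim, seed)`.
#' @param patient_id Identifier for the returned cloud.
#' @return A `point_cloud` (see [patient_point_cloud()]).
#' @export
simulate_point_cloud <- function(archetype, n_lesions, dim = 12L, seed = 1L,
                                 patient_id = "sim") {
  if (is.character(archetype)) archetype <- archetype_spec(archetype)
  if (!inherits(archetype, "archetype_spec")) {
    stop_hetree("`archetype` must be an archetype_spec or archetype name.", "hetree_config_error")
  }
  if (n_lesions < 1L) stop_hetree("`n_lesions` must be >= 1.", "hetree_config_error")
  points <- with_seed(seed, {
    center <- rnorm(dim)
    base <- switch(archetype$name,
      homogeneous = {
        matrix(rnorm(n_lesions * dim, sd = archetype$sigma_within), n_lesions, dim)
      },
      scattered = {
        # broad cloud: spread set by the separation scale, no sub-structure
        matrix(rnorm(n_lesions * dim, sd = archetype$delta / 2), n_lesions, dim)
      },
      clustered = {
        # sub-cluster centers follow the scattered spatial law at ~80% of
        # its scale, so between-phenotype merges happen high but
        # systematically below scattered merge heights
        m <- archetype$n_subclusters
        centers <- matrix(rnorm(m * dim, sd = archetype$delta / 2.4), m, dim)
        assign <- rep_len(seq_len(m), n_lesions)
        centers[assign, , drop = FALSE] +
          matrix(rnorm(n_lesions * dim, sd = archetype$sigma_within), n_lesions, dim)
      }
    )
    sweep(base, 2L, center, "+")
  })
  structure(
    list(
      patient_id = as.character(patient_id),
      points = points,
      lesion_ids = paste0("L", seq_len(n_lesions))
    ),
    class = "point_cloud"
  )
}

#' Simulate a synthetic radiomic cohort
#'
#' Generates a lesion-level feature table with the structure the pipeline
#' assumes: per patient, a latent lesion cloud drawn from their archetype;
#' per view, the observed features are a linear map of two latent
#' coordinates plus a shared per-view, per-lesion factor (inducing the
#' within-view correlation typical of texture families) plus independent
#' noise. Missing values are injected completely at random at
#' `missing_rate`. The true archetype labels are returned for validation.
#'
#' @param n_patients Number of patients.
#' @param archetype_mix Named proportions over archetypes (must sum to 1).
#' @param p Total feature count (split as evenly as possible over views).
#' @param views Number of views (default 6).
#' @param missing_rate Fraction of feature cells set missing.
#' @param seed Master seed; the whole cohort is a pure function of the
#'   arguments.
#' @param specs Optional named list of [archetype_spec()] overrides.
#' @return A list of class `synthetic_cohort`: `table` (a
#'   `radiomic_table`), `truth` (tibble patient_id / archetype /
#'   n_lesions), `schema`, `seed`.
#' @export
simulate_radiomic_table <- function(n_patients = 30L,
                                    archetype_mix = c(
                                      homogeneous = 1 / 3,
                                      clustered = 1 / 3,
                                      scattered = 1 / 3
                                    ),
                                    p = 40L, views = 6L, missing_rate = 0,
                                    seed = 1L, specs = NULL) {
  if (abs(sum(archetype_mix) - 1) > 1e-8) {
    stop_hetree("`archetype_mix` proportions must sum to 1.", "hetree_config_error")
  }
  per_view <- diff(round(seq(0, p, length.out = views + 1L)))
  if (any(per_view < 2L)) {
    stop_hetree(
      "`p` must allow at least 2 features per view.",
      "hetree_config_error"
    )
  }
  view_names <- c("firstorder", "shape", "glcm", "glrlm", "glzlm", "ngldm")
  view_names <- if (views <= 6L) {
    view_names[seq_len(views)]
  } else {
    c(view_names, paste0("view", seq_len(views - 6L)))
  }
  schema <- view_schema(unlist(purrr::map2(
    view_names, per_view,
    function(v, k) setNames(rep(v, k), paste0(v, "_f", seq_len(k)))
  )), view_names)

  arch_names <- names(archetype_mix)
  counts <- floor(archetype_mix * n_patients)
  rem <- n_patients - sum(counts)
  if (rem > 0) counts[seq_len(rem)] <- counts[seq_len(rem)] + 1
  assignment <- rep(arch_names, counts)
  dim_latent <- 2L * views

  rows <- with_seed(derive_seed(seed, 1L), {
    # fixed per-view loading maps (2 latent -> per_view features)
    maps <- purrr::map(per_view, function(k) matrix(rnorm(k * 2L), 2L, k))
    purrr::map_dfr(seq_len(n_patients), function(i) {
      arch_name <- assignment[i]
      spec <- if (!is.null(specs) && !is.null(specs[[arch_name]])) {
        specs[[arch_name]]
      } else {
        archetype_spec(arch_name)
      }
      n_i <- rtrunc_pois(1L, spec$lesion_lambda, spec$lesion_range)
      cloud <- simulate_point_cloud(spec, n_i,
        dim = dim_latent,
        seed = derive_seed(seed, 1000L + i), patient_id = paste0("P", i)
      )
      feats <- purrr::imap(maps, function(map, j) {
        z <- cloud$points[, c(2L * j - 1L, 2L * j), drop = FALSE]
        # per-view, per-lesion factor inducing within-view correlation; kept
        # well below the homogeneous latent spread so it does not mask the
        # archetype contrast
        shared <- rnorm(n_i, sd = 0.05)
        z %*% map + shared + matrix(rnorm(n_i * ncol(map), sd = 0.05), n_i)
      })
      x <- do.call(cbind, feats)
      colnames(x) <- schema_features(schema)
      # lesion volumes: log-normal, mildly larger for spread-out clouds
      vol <- exp(rnorm(n_i, mean = 1 + 0.1 * sqrt(rowSums(cloud$points^2)), sd = 0.5))
      dplyr::bind_cols(
        tibble::tibble(
          patient_id = paste0("P", i),
          lesion_id = cloud$lesion_ids,
          volume_ml = vol
        ),
        tibble::as_tibble(x)
      )
    })
  })
  if (missing_rate > 0) {
    rows <- with_seed(derive_seed(seed, 2L), {
      feats <- schema_features(schema)
      n_cells <- nrow(rows) * length(feats)
      holes <- which(runif(n_cells) < missing_rate)
      for (h in holes) {
        r <- ((h - 1L) %% nrow(rows)) + 1L
        f <- feats[((h - 1L) %/% nrow(rows)) + 1L]
        # never blank out an entire column
        if (sum(!is.na(rows[[f]])) > 1L) rows[[r, f]] <- NA_real_
      }
      rows
    })
  }
  truth <- rows |>
    dplyr::count(.data$patient_id, name = "n_lesions") |>
    dplyr::left_join(
      tibble::tibble(patient_id = paste0("P", seq_len(n_patients)), archetype = assignment),
      by = "patient_id"
    ) |>
    dplyr::arrange(match(.data$patient_id, paste0("P", seq_len(n_patients))))
  structure(
    list(
      table = as_radiomic_table(rows, schema),
      truth = truth, schema = schema, seed = seed
    ),
    class = "synthetic_cohort"
  )
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("<synthetic_cohort> ", nrow(x$truth), " patients, ",
    nrow(x$table), " lesions, seed ", x$seed, "\n",
    sep = ""
  )
  print(table(x$truth$archetype))
  invisible(x)
}

#' Simulate clinical covariates for a labelled cohort
#'
#' Draws per-patient clinical covariates with configurable group effects,
#' for exercising the characterization battery and the survival
#' comparison: numeric covariates are normal with per-archetype mean
#' shifts, time to therapy response is exponential with per-archetype
#' rates, and administrative censoring is applied at `followup`.
#'
#' @param truth Tibble with `patient_id` and `archetype` (see
#'   [simulate_radiomic_table()]).
#' @param effect_spec List with optional entries `psa_shift`,
#'   `gleason_shift` (named per-archetype numeric shifts) and
#'   `response_rate` (named per-archetype exponential rates; rate 0 means
#'   no responses).
#' @param followup Censoring horizon.
#' @param seed Integer seed.
#' @return A tibble of per-patient covariates: `psa`, `gleason`,
#'   `time_to_response`, `response` and flags.
#' @export
simulate_clinical <- function(truth,
                              effect_spec = list(),
                              followup = 24,
                              seed = 1L) {
  default_rates <- c(homogeneous = 0.067, clustered = 0.021, scattered = 0.0044)
  shifts <- function(name, default = 0) {
    s <- effect_spec[[name]]
    vapply(truth$archetype, function(a) {
      if (!is.null(s) && !is.null(s[[a]])) {
        s[[a]]
      } else if (identical(name, "response_rate") && a %in% names(default_rates)) {
        default_rates[[a]]
      } else {
        default
      }
    }, numeric(1))
  }
  with_seed(seed, {
    n <- nrow(truth)
    rate <- shifts("response_rate", default = 0.1)
    t_raw <- ifelse(rate > 0, rexp(n, rate = pmax(rate, 1e-12)), Inf)
    tibble::tibble(
      patient_id = truth$patient_id,
      archetype = truth$archetype,
      psa = rnorm(n, mean = 10 + shifts("psa_shift"), sd = 2),
      gleason = pmin(pmax(round(rnorm(n, mean = 7 + shifts("gleason_shift"), sd = 1)), 2), 10),
      n_lesions = truth$n_lesions,
      oligo3 = truth$n_lesions <= 3L,
      oligo5 = truth$n_lesions <= 5L,
      time_to_response = pmin(t_raw, followup),
      response = as.integer(t_raw <= followup)
    )
  })
}

#' Random merge trees for metric-property fixtures
#'
#' Generates a merge tree with a uniformly random agglomeration topology:
#' starting from `n_leaves` singleton blocks at height 0, repeatedly merges
#' two uniformly chosen blocks at a height exceeding the previous merge by
#' a positive increment drawn from `weight_law`.
#'
#' @param n_leaves Number of leaves (>= 1).
#' @param weight_law Function `n -> n positive increments` (default
#'   `rexp`).
#' @param seed Integer seed.
#' @return A [merge_tree()].
#' @export
random_merge_tree <- function(n_leaves, weight_law = rexp, seed = 1L) {
  if (n_leaves < 1L) stop_hetree("`n_leaves` must be >= 1.", "hetree_config_error")
  if (n_leaves == 1L) {
    return(merge_tree(0, 0L, "L1"))
  }
  with_seed(seed, {
    increments <- abs(weight_law(n_leaves - 1L))
    heights_merge <- cumsum(increments)
    n_all <- 2L * n_leaves - 1L
    height <- c(rep(0, n_leaves), heights_merge)
    parent <- integer(n_all)
    blocks <- seq_len(n_leaves)
    for (i in seq_len(n_leaves - 1L)) {
      pick <- sample(length(blocks), 2L)
      v <- n_leaves + i
      parent[blocks[pick]] <- v
      blocks <- c(blocks[-pick], v)
    }
    parent[n_all] <- 0L
    merge_tree(height, parent, c(paste0("L", seq_len(n_leaves)), rep(NA, n_leaves - 1L)))
  })
}
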