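#' Ward clustering of patients from a precomputed distance matrix
#'
#' Agglomerative clustering (ward linkage, `ward.D2`) on the
#' patient-to-patient distance matrix, with the number of clusters selected
#' over a range (default 2 to 5). The selection rule is explicit: maximize
#' the mean silhouette width; candidates within `tie_tol` of the best
#' count as tied, and ties resolve toward the smallest tied `k` (the
#' interpretability side of the trade-off) unless a therapy-response
#' vector is supplied, in which case the tied candidate with the highest
#' mutual information with the response wins. The full selection trace
#' (silhouette and concordance per candidate `k`) is always returned for
#' inspection.
#'
#' @param D Symmetric distance matrix with patient ids as dimnames.
#' @param k_range Candidate numbers of clusters (default `2:5`).
#' @param response Optional per-patient response vector (factor-like) for
#'   the concordance tie-break.
#' @param tie_tol Silhouette margin within which candidates count as tied.
#' @return An object of class `tree_clustering` with fields `labels` (named
#'   integer vector, values `1..k`), `k`, `silhouette`, `linkage`, `trace`
#'   (a tibble) and the `hclust` object.
#' @export
ward_cluster <- function(D, k_range = 2:5, response = NULL, tie_tol = 0.03) {
  D <- as.matrix(D)
  n <- nrow(D)
  if (n < 3L) {
    stop_hetree("Need at least 3 patients to cluster.", "hetree_capacity_error")
  }
  if (any(abs(D - t(D)) > 1e-8)) {
    stop_hetree("Distance matrix must be symmetric.", "hetree_integrity_error")
  }
  k_range <- k_range[k_range >= 2 & k_range <= n - 1L]
  if (length(k_range) == 0L) {
    stop_hetree("Fewer patients than the smallest candidate k.", "hetree_capacity_error")
  }
  ids <- rownames(D)
  if (is.null(ids)) ids <- paste0("p", seq_len(n))
  hc <- hclust(as.dist(D), method = "ward.D2")
  degenerate <- all(D < 1e-12)
  trace <- purrr::map_dfr(k_range, function(k) {
    labels <- cutree(hc, k = k)
    sil <- if (degenerate) {
      NA_real_
    } else {
      mean(cluster::silhouette(labels, dmatrix = D)[, "sil_width"])
    }
    mi <- if (is.null(response)) NA_real_ else mutual_information(labels, response)
    tibble::tibble(k = k, silhouette = sil, concordance = mi)
  })
  if (degenerate) {
    warn("Distance matrix is identically zero; returning the smallest k.")
    k_best <- min(k_range)
  } else {
    best_sil <- max(trace$silhouette)
    tied <- trace$k[trace$silhouette >= best_sil - tie_tol]
    k_best <- if (length(tied) > 1L && !is.null(response)) {
      # concordance arbitration with the same parsimony band: among tied
      # candidates, the smallest k whose concordance is within 0.02 of the
      # best concordance
      conc <- trace$concordance[match(tied, trace$k)]
      min(tied[conc >= max(conc) - 0.02])
    } else {
      tied[1]
    }
  }
  labels <- cutree(hc, k = k_best)
  names(labels) <- ids
  structure(
    list(
      labels = labels, k = k_best,
      silhouette = trace$silhouette[match(k_best, trace$k)],
      linkage = "ward.D2", trace = trace, hclust = hc
    ),
    class = "tree_clustering"
  )
}

#' @export
print.tree_clustering <- function(x, ...) {
  cat("<tree_clustering> k = ", x$k, " (", x$linkage, "), silhouette ",
    format(x$silhouette, digits = 4), "\n",
    sep = ""
  )
  print(table(cluster = x$labels))
  invisible(x)
}

#' @export
tidy.tree_clustering <- function(x, ...) {
  tibble::tibble(patient_id = names(x$labels), cluster = unname(x$labels))
}

#' @export
glance.tree_clustering <- function(x, ...) {
  tibble::tibble(k = x$k, silhouette = x$silhouette, linkage = x$linkage)
}

# normalized mutual information between two label vectors; raw MI grows
# with partition refinement, so concordance is normalized by the geometric
# mean of the entropies to compare different k fairly
mutual_information <- function(a, b) {
  tab <- table(a, b)
  p <- tab / sum(tab)
  pa <- rowSums(p)
  pb <- colSums(p)
  idx <- p > 0
  mi <- sum(p[idx] * log(p[idx] / outer(pa, pb)[idx]))
  ha <- -sum(pa[pa > 0] * log(pa[pa > 0]))
  hb <- -sum(pb[pb > 0] * log(pb[pb > 0]))
  if (ha <= 0 || hb <= 0) return(0)
  mi / sqrt(ha * hb)
}

#' Density-based noise check on a distance matrix
#'
#' Runs DBSCAN directly on the precomputed distance matrix as a robustness
#' check of the hierarchical stratification: clusters found by ward linkage
#' that DBSCAN marks as noise (label 0) have no consistent density
#' characterization and should be interpreted with caution.
#'
#' @param D Symmetric distance matrix.
#' @param eps Neighbourhood radius (distance units of `D`).
#' @param min_samples Minimum neighbourhood size (self included) for a core
#'   point.
#' @param reference Optional labels (e.g. from [ward_cluster()]) to report
#'   agreement against.
#' @return A list with `labels` (0 = noise), `n_clusters`, and, when a
#'   reference is given, `agreement` (Rand index on non-noise points) and
#'   `noise_by_reference`.
#' @export
dbscan_noise_check <- function(D, eps, min_samples = 3L, reference = NULL) {
  D <- as.matrix(D)
  if (eps <= 0) stop_hetree("`eps` must be positive.", "hetree_validation_error")
  n <- nrow(D)
  labels <- integer(n) # 0 = unvisited/noise
  visited <- logical(n)
  cl <- 0L
  neighbours <- function(i) which(D[i, ] <= eps)
  for (i in seq_len(n)) {
    if (visited[i]) next
    visited[i] <- TRUE
    nb <- neighbours(i)
    if (length(nb) < min_samples) next # noise (may be claimed later)
    cl <- cl + 1L
    labels[i] <- cl
    queue <- setdiff(nb, i)
    while (length(queue) > 0L) {
      j <- queue[1]
      queue <- queue[-1]
      if (!visited[j]) {
        visited[j] <- TRUE
        nbj <- neighbours(j)
        if (length(nbj) >= min_samples) queue <- c(queue, setdiff(nbj, j))
      }
      if (labels[j] == 0L) labels[j] <- cl
    }
  }
  names(labels) <- rownames(D)
  out <- list(labels = labels, n_clusters = cl)
  if (!is.null(reference)) {
    keep <- labels != 0L
    out$agreement <- if (sum(keep) >= 2L) {
      compare_partitions(labels[keep], reference[keep])
    } else {
      NA_real_
    }
    out$noise_by_reference <- table(reference = reference, noise = labels == 0L)
  }
  out
}

#' Rand index between two partitions
#'
#' Pair-counting agreement: the fraction of patient pairs on which the two
#' partitions agree (together in both, or separated in both). 1 means
#' identical partitions up to relabeling.
#'
#' @param a,b Label vectors over the same patients.
#' @return A number in `[0, 1]`.
#' @export
compare_partitions <- function(a, b) {
  if (length(a) != length(b)) {
    stop_hetree("Partitions must cover the same patients.", "hetree_validation_error")
  }
  n <- length(a)
  if (n < 2L) {
    return(1)
  }
  same_a <- outer(a, a, "==")[upper.tri(diag(n))]
  same_b <- outer(b, b, "==")[upper.tri(diag(n))]
  mean(same_a == same_b)
}

#' Single-lesion and mean-profile baseline stratifications
#'
#' Two standard radiomics strategies, used as comparators for the tree-based
#' pipeline:
#' * `baseline_biggest_lesion()`: each patient is represented by the reduced
#'   vector of their largest-volume lesion (ties broken by lowest lesion
#'   id); patients are then clustered on the Euclidean distance matrix with
#'   ward linkage.
#' * `baseline_mean_vector()`: each patient is represented by the
#'   arithmetic mean of their reduced lesion vectors, then clustered the
#'   same way. Averaging discards dispersion information, so cohorts whose
#'   groups differ in heterogeneity but not in mean profile defeat it.
#'
#' @param reduced A `reduced_matrix` (with `volume_ml` present for the
#'   biggest-lesion baseline).
#' @inheritParams ward_cluster
#' @return A `tree_clustering` (see [ward_cluster()]) with an added
#'   `representative` tibble.
#' @export
baseline_biggest_lesion <- function(reduced, k_range = 2:5, response = NULL) {
  if (anyNA(reduced$volume_ml)) {
    stop_hetree(
      "Missing lesion volumes; cannot select the biggest lesion.",
      "hetree_data_error"
    )
  }
  cols <- reduced_score_columns(reduced)
  rep_rows <- reduced |>
    tibble::as_tibble() |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::arrange(dplyr::desc(.data$volume_ml), .data$lesion_id, .by_group = TRUE) |>
    dplyr::slice(1L) |>
    dplyr::ungroup()
  baseline_from_vectors(rep_rows, cols, k_range, response)
}

#' @rdname baseline_biggest_lesion
#' @export
baseline_mean_vector <- function(reduced, k_range = 2:5, response = NULL) {
  cols <- reduced_score_columns(reduced)
  rep_rows <- reduced |>
    tibble::as_tibble() |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::summarise(dplyr::across(dplyr::all_of(cols), mean), .groups = "drop")
  baseline_from_vectors(rep_rows, cols, k_range, response)
}

baseline_from_vectors <- function(rep_rows, cols, k_range, response) {
  X <- as.matrix(rep_rows[, cols])
  rownames(X) <- rep_rows$patient_id
  D <- as.matrix(dist(X))
  out <- ward_cluster(D, k_range = k_range, response = response)
  out$representative <- rep_rows
  out
}
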