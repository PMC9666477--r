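#' Clinical characterization of patient clusters
#'
#' Profiles a stratification against exogenous clinical covariates with a
#' battery of pairwise two-group tests, one battery per ordered cluster
#' pair. For numeric variables, normality of each group is gated by the
#' Shapiro test (at 0.05): when both groups pass, the parametric pair
#' (t-test for means, Bartlett for variances) is used, otherwise the
#' non-parametric pair (Mann-Whitney for distributions, Levene for
#' variances). Categorical variables get a chi-squared independence test.
#' Groups too small for the Shapiro gate (n < 3) fall back to the
#' non-parametric tests with a warning.
#'
#' One-sided p-values (oriented by the observed direction of the
#' difference) are reported alongside the two-sided ones; significance
#' flags use the two-sided p-value at `alpha`, keeping the false-positive
#' rate of the battery at its nominal level. Raw p-values are reported;
#' Benjamini-Hochberg adjustment across the battery is available behind
#' `adjust`.
#'
#' @param labels Named cluster labels (e.g. from [ward_cluster()]).
#' @param clinical A data frame with `patient_id` and covariate columns.
#' @param alpha Significance level (default 0.1, chosen to limit type II
#'   errors in small cohorts).
#' @param var_types Optional named character vector
#'   (`"numeric"`/`"categorical"`); guessed from column types otherwise.
#' @param adjust If `TRUE`, add BH-adjusted p-values across the battery.
#' @return A tibble of class `cluster_report`: one row per (variable,
#'   cluster pair, test family) with columns `variable`, `group_a`,
#'   `group_b`, `family` (location / scale / independence), `test`,
#'   `statistic`, `p_value` (two-sided), `p_one_sided`, `direction`, and
#'   `significant`.
#' @export
characterize_clusters <- function(labels, clinical, alpha = 0.1, var_types = NULL,
                                  adjust = FALSE) {
  if (is.null(names(labels))) {
    stopifnot(nrow(clinical) == length(labels))
    names(labels) <- clinical$patient_id
  }
  clinical <- clinical[match(names(labels), clinical$patient_id), , drop = FALSE]
  groups <- sort(unique(labels))
  if (length(groups) < 2L) {
    stop_hetree("Need at least two clusters to characterize.", "hetree_validation_error")
  }
  vars <- setdiff(names(clinical), "patient_id")
  if (is.null(var_types)) {
    var_types <- vapply(clinical[vars], function(x) {
      if (is.numeric(x) && length(unique(stats::na.omit(x))) > 2L) "numeric" else "categorical"
    }, character(1))
  }
  pairs <- utils::combn(groups, 2L, simplify = FALSE)
  rows <- purrr::map_dfr(vars, function(v) {
    purrr::map_dfr(pairs, function(gp) {
      x <- clinical[[v]][labels == gp[1]]
      y <- clinical[[v]][labels == gp[2]]
      if (var_types[[v]] == "numeric") {
        dplyr::bind_rows(
          location_test(v, gp, x, y),
          scale_test(v, gp, x, y)
        )
      } else {
        independence_test(v, gp, x, y)
      }
    })
  })
  rows$significant <- !is.na(rows$p_value) & rows$p_value < alpha
  if (adjust) {
    rows$p_adjusted <- stats::p.adjust(rows$p_value, method = "BH")
  }
  structure(rows, alpha = alpha, class = c("cluster_report", class(rows)))
}

normality_gate <- function(x, y) {
  x <- stats::na.omit(x)
  y <- stats::na.omit(y)
  if (length(x) < 3L || length(y) < 3L) {
    warn("Group too small for the Shapiro gate; falling back to non-parametric tests.")
    return(FALSE)
  }
  if (sd(x) == 0 || sd(y) == 0) {
    return(FALSE)
  }
  shapiro.test(x)$p.value > 0.05 && shapiro.test(y)$p.value > 0.05
}

safe_test <- function(expr) {
  tryCatch(suppressWarnings(expr), error = function(e) NULL)
}

location_test <- function(v, gp, x, y) {
  normal <- normality_gate(x, y)
  direction <- if (isTRUE(mean(x, na.rm = TRUE) < mean(y, na.rm = TRUE))) "less" else "greater"
  if (normal) {
    two <- safe_test(t.test(x, y))
    one <- safe_test(t.test(x, y, alternative = direction))
    test <- "t"
  } else {
    two <- safe_test(wilcox.test(x, y, exact = FALSE))
    one <- safe_test(wilcox.test(x, y, alternative = direction, exact = FALSE))
    test <- "mann-whitney"
  }
  tibble::tibble(
    variable = v, group_a = gp[1], group_b = gp[2], family = "location",
    test = test,
    statistic = if (is.null(two)) NA_real_ else unname(two$statistic),
    p_value = if (is.null(two)) NA_real_ else two$p.value,
    p_one_sided = if (is.null(one)) NA_real_ else one$p.value,
    direction = direction
  )
}

scale_test <- function(v, gp, x, y) {
  normal <- normality_gate(x, y)
  g <- factor(rep(c("a", "b"), c(length(x), length(y))))
  z <- c(x, y)
  keep <- !is.na(z)
  if (normal) {
    fit <- safe_test(bartlett.test(z[keep], g[keep]))
    test <- "bartlett"
    stat <- if (is.null(fit)) NA_real_ else unname(fit$statistic)
    p <- if (is.null(fit)) NA_real_ else fit$p.value
  } else {
    fit <- safe_test(car::leveneTest(z[keep] ~ g[keep]))
    test <- "levene"
    stat <- if (is.null(fit)) NA_real_ else fit$`F value`[1]
    p <- if (is.null(fit)) NA_real_ else fit$`Pr(>F)`[1]
  }
  direction <- if (isTRUE(stats::var(x, na.rm = TRUE) < stats::var(y, na.rm = TRUE))) "less" else "greater"
  tibble::tibble(
    variable = v, group_a = gp[1], group_b = gp[2], family = "scale",
    test = test, statistic = stat, p_value = p,
    p_one_sided = NA_real_, direction = direction
  )
}

independence_test <- function(v, gp, x, y) {
  tab <- table(
    value = c(as.character(x), as.character(y)),
    group = rep(c("a", "b"), c(length(x), length(y)))
  )
  fit <- if (nrow(tab) >= 2L && ncol(tab) == 2L) {
    safe_test(chisq.test(tab))
  } else {
    NULL # constant variable: independence undefined, reported as NA
  }
  tibble::tibble(
    variable = v, group_a = gp[1], group_b = gp[2], family = "independence",
    test = "chi-squared",
    statistic = if (is.null(fit)) NA_real_ else unname(fit$statistic),
    p_value = if (is.null(fit)) NA_real_ else fit$p.value,
    p_one_sided = NA_real_, direction = NA_character_
  )
}

#' Group-wise height-count curves with permutation inference
#'
#' Summarizes each cluster by the pointwise mean and standard deviation of
#' its members' height-count curves ([height_count_curve()]), and tests for
#' group differences with a pointwise permutation F-test: at each grid
#' threshold the between/within-group F statistic is compared to its
#' distribution under label permutation. Adjusted p-values use the
#' max-statistic (Westfall-Young style) envelope over the grid, a
#' permutation analogue of interval-wise functional testing.
#'
#' @param trees Named list of merge trees.
#' @param labels Cluster labels aligned with `trees`.
#' @param grid Ascending thresholds.
#' @param n_permutations Number of label permutations (default 500).
#' @param seed RNG seed for the permutations.
#' @return A list of class `height_curve_summary`: `summary` (tibble of
#'   group, threshold, mean, sd), `pointwise_p`, `adjusted_p`, `grid`.
#' @export
group_height_curves <- function(trees, labels, grid, n_permutations = 500L, seed = 1L) {
  stopifnot(length(trees) == length(labels))
  if (length(unique(labels)) < 2L) {
    stop_hetree("Need at least two groups.", "hetree_validation_error")
  }
  counts <- t(vapply(
    trees,
    function(tr) height_count_curve(tr, grid)$count,
    numeric(length(grid))
  ))
  labels <- as.factor(labels)
  summary <- tibble::as_tibble(expand.grid(
    group = levels(labels), threshold = grid,
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  ))
  summary$mean <- purrr::map2_dbl(
    summary$group, match(summary$threshold, grid),
    function(g, j) mean(counts[labels == g, j])
  )
  summary$sd <- purrr::map2_dbl(
    summary$group, match(summary$threshold, grid),
    function(g, j) sd(counts[labels == g, j])
  )
  f_obs <- pointwise_f(counts, labels)
  perm <- with_seed(seed, {
    replicate(n_permutations, pointwise_f(counts, sample(labels)))
  })
  perm <- matrix(perm, nrow = length(grid))
  pointwise_p <- vapply(seq_along(grid), function(j) {
    (1 + sum(perm[j, ] >= f_obs[j] - 1e-12)) / (n_permutations + 1)
  }, numeric(1))
  max_perm <- apply(perm, 2, max, na.rm = TRUE)
  adjusted_p <- vapply(seq_along(grid), function(j) {
    (1 + sum(max_perm >= f_obs[j] - 1e-12)) / (n_permutations + 1)
  }, numeric(1))
  structure(
    list(
      summary = summary, grid = grid, f = f_obs,
      pointwise_p = pointwise_p, adjusted_p = adjusted_p
    ),
    class = "height_curve_summary"
  )
}

# one-way F statistic at every grid point; NA-free by construction, returns
# 0 where there is no variance at all
pointwise_f <- function(counts, labels) {
  vapply(seq_len(ncol(counts)), function(j) {
    x <- counts[, j]
    gm <- tapply(x, labels, mean)
    gn <- tapply(x, labels, length)
    between <- sum(gn * (gm - mean(x))^2) / (length(gm) - 1L)
    within_ss <- sum((x - gm[labels])^2)
    dfw <- length(x) - length(gm)
    within <- if (dfw > 0) within_ss / dfw else 0
    if (within <= 1e-300) {
      if (between <= 1e-300) 0 else Inf
    } else {
      between / within
    }
  }, numeric(1))
}

#' Kaplan-Meier curves and log-rank test by cluster
#'
#' Product-limit estimates of time to therapy response per cluster with a
#' log-rank test across clusters. Empty groups are dropped with a warning.
#'
#' @param labels Cluster labels.
#' @param time Non-negative times to response/censoring.
#' @param event Binary event indicators (1 = response observed).
#' @return A list of class `km_result`: `fit` (a [survival::survfit]
#'   object), `p_value` (log-rank), `n_groups`.
#' @export
km_logrank <- function(labels, time, event) {
  stopifnot(length(labels) == length(time), length(time) == length(event))
  if (any(time < 0, na.rm = TRUE)) {
    stop_hetree("Times must be non-negative.", "hetree_data_error")
  }
  keep <- !is.na(labels) & !is.na(time) & !is.na(event)
  if (any(!keep)) warn("Dropping observations with missing survival data.")
  labels <- droplevels(as.factor(labels[keep]))
  time <- time[keep]
  event <- as.integer(event[keep])
  df <- data.frame(time = time, event = event, group = labels)
  fit <- survival::survfit(survival::Surv(time, event) ~ group, data = df)
  p <- if (nlevels(labels) >= 2L && sum(event) > 0L) {
    sd_fit <- survival::survdiff(survival::Surv(time, event) ~ group, data = df)
    1 - stats::pchisq(sd_fit$chisq, df = nlevels(labels) - 1L)
  } else {
    NA_real_
  }
  structure(
    list(fit = fit, p_value = p, n_groups = nlevels(labels), data = df),
    class = "km_result"
  )
}

#' @export
glance.km_result <- function(x, ...) {
  tibble::tibble(n_groups = x$n_groups, p_logrank = x$p_value)
}

#' @export
print.km_result <- function(x, ...) {
  cat("<km_result> ", x$n_groups, " group(s), log-rank p = ",
    format(x$p_value, digits = 4), "\n",
    sep = ""
  )
  invisible(x)
}
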