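#' Weighting measures over pruning thresholds
#'
#' The pruned edit distance averages the edit distance between
#' \eqn{\varepsilon}-pruned trees over a finite measure \eqn{\mu} on the
#' threshold axis. Since the definition is an expectation, the measure is
#' always normalized to total mass 1 before use. Three families are
#' supported:
#'
#' * `beta_measure(alpha, beta)` -- a Beta density on `[0, 1]`, for trees
#'   whose heights have been rescaled to `[0, 1]`. The default
#'   `beta_measure(2.5, 15)` has mean `2.5/17.5 ~= 0.143`, placing most of
#'   its weight near the saddle that typically separates the
#'   within-phenotype (homogeneous, low) and between-phenotype
#'   (heterogeneous, high) components of pooled dendrogram heights.
#' * `point_mass(at)` -- a single atom; recovers the plain edit distance of
#'   trees pruned at one fixed threshold (at `0`, the unpruned edit
#'   distance when all weights are positive).
#' * `discrete_measure(at, mass)` -- arbitrary atoms, e.g. a quadrature or
#'   equal-mass discretization of a continuous measure.
#'
#' @param alpha,beta Positive Beta shape parameters.
#' @return An object of class `tree_measure`.
#' @export
beta_measure <- function(alpha = 2.5, beta = 15) {
  if (alpha <= 0 || beta <= 0) {
    stop_hetree("Beta shape parameters must be positive.", "hetree_measure_error")
  }
  structure(
    list(family = "beta", alpha = alpha, beta = beta, support = c(0, 1)),
    class = "tree_measure"
  )
}

#' @rdname beta_measure
#' @param at Atom location(s), non-negative.
#' @export
point_mass <- function(at = 0) {
  if (length(at) != 1L || at < 0) {
    stop_hetree("`at` must be a single non-negative number.", "hetree_measure_error")
  }
  discrete_measure(at, 1)
}

#' @rdname beta_measure
#' @param mass Atom masses, positive, finite total (normalized internally).
#' @export
discrete_measure <- function(at, mass = rep(1, length(at))) {
  if (length(at) != length(mass) || any(mass < 0) || sum(mass) <= 0 ||
    !all(is.finite(c(at, mass))) || any(at < 0)) {
    stop_hetree(
      "Discrete measure needs non-negative atoms with positive finite total mass.",
      "hetree_measure_error"
    )
  }
  o <- order(at)
  structure(
    list(
      family = "discrete", at = at[o], mass = mass[o] / sum(mass),
      support = range(at)
    ),
    class = "tree_measure"
  )
}

#' @export
print.tree_measure <- function(x, ...) {
  if (x$family == "beta") {
    cat("<tree_measure> Beta(", x$alpha, ", ", x$beta, "), mean ",
      format(x$alpha / (x$alpha + x$beta), digits = 4), "\n",
      sep = ""
    )
  } else {
    cat("<tree_measure> discrete, ", length(x$at), " atom(s)\n", sep = "")
  }
  invisible(x)
}

# mass of the right-open interval [lo, hi); hi = Inf for the last segment
measure_interval_mass <- function(mu, lo, hi) {
  if (mu$family == "beta") {
    pbeta(min(hi, 1), mu$alpha, mu$beta) - pbeta(min(lo, 1), mu$alpha, mu$beta)
  } else {
    sum(mu$mass[mu$at >= lo - 1e-15 & mu$at < hi - 1e-15])
  }
}

#' Discretize a measure into equal-mass atoms
#'
#' Replaces a continuous measure by `k` atoms at the quantiles
#' `(i - 1/2)/k` with mass `1/k` each. The discretizations converge weakly
#' to the original measure as `k` grows, and the pruned edit distance is
#' continuous under weak convergence, so distances computed with the atoms
#' converge to the exact value.
#'
#' @param mu A `tree_measure`.
#' @param k Number of atoms.
#' @return A discrete `tree_measure`.
#' @export
discretize_measure <- function(mu, k) {
  probs <- (seq_len(k) - 0.5) / k
  if (mu$family == "beta") {
    discrete_measure(qbeta(probs, mu$alpha, mu$beta), rep(1 / k, k))
  } else {
    # quantiles of a discrete measure
    cum <- cumsum(mu$mass)
    idx <- findInterval(probs, c(0, head(cum, -1)), rightmost.closed = FALSE)
    discrete_measure(mu$at[pmax(idx, 1L)], rep(1 / k, k))
  }
}

#' Fit the weighting measure from cohort dendrogram heights
#'
#' Pools the internal-vertex heights of all (rescaled) patient trees,
#' estimates their density by a Gaussian kernel, and looks for the saddle --
#' the local density minimum between the two largest modes -- that separates
#' the homogeneous (near-zero heights, lesions of one phenotype merging) and
#' heterogeneous (large heights, distinct phenotypes merging) components.
#' The returned Beta measure is centered there: with `alpha` fixed, the mean
#' constraint `alpha/(alpha+beta) = s` gives `beta = alpha (1 - s) / s`.
#'
#' If the pooled density has no interior local minimum (unimodal heights),
#' the default `beta_measure(2.5, 15)` is returned with a warning.
#'
#' @param trees List of merge trees rescaled to `[0, 1]`.
#' @param fixed_alpha Fixed Beta `alpha` (default 2.5).
#' @return A `tree_measure` with attribute `saddle` (when fitted).
#' @export
fit_mu <- function(trees = NULL, fixed_alpha = 2.5) {
  if (is.null(trees) || length(trees) == 0L) {
    return(beta_measure(fixed_alpha, 15))
  }
  heights <- unlist(lapply(trees, function(tr) {
    internal <- unique(tr$parent[tr$parent != 0L])
    tr$height[internal]
  }))
  heights <- heights[is.finite(heights)]
  if (length(heights) < 2L) {
    warn("Too few internal heights to fit the measure; using the default Beta(2.5, 15).")
    return(beta_measure(fixed_alpha, 15))
  }
  d <- density(heights, from = 0, to = 1, n = 512)
  y <- d$y
  interior <- 2:(length(y) - 1L)
  minima <- interior[y[interior] < y[interior - 1L] & y[interior] <= y[interior + 1L]]
  maxima <- interior[y[interior] > y[interior - 1L] & y[interior] >= y[interior + 1L]]
  # only modes carrying real mass count (flat tails wiggle numerically)
  maxima <- maxima[y[maxima] >= 0.1 * max(y)]
  saddle <- NA_real_
  if (length(maxima) >= 2L && length(minima) >= 1L) {
    top2 <- sort(maxima[order(y[maxima], decreasing = TRUE)][1:2])
    between <- minima[minima > top2[1] & minima < top2[2]]
    if (length(between) > 0L) saddle <- d$x[between[which.min(y[between])]]
  }
  if (is.na(saddle) || saddle <= 0 || saddle >= 1) {
    warn("Pooled height density has no interior saddle; using the default Beta(2.5, 15).")
    return(beta_measure(fixed_alpha, 15))
  }
  out <- beta_measure(fixed_alpha, fixed_alpha * (1 - saddle) / saddle)
  attr(out, "saddle") <- saddle
  out
}
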