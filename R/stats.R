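#' Tukey IQR outlier flags
#'
#' Flags each value against Tukey fences: beyond `Q3 + k * IQR` (or below
#' `Q1 - k * IQR`) with `k = k_normal` (1.5, the liberal rule) gives a
#' `normal` outlier, with `k = k_extreme` (3.0, the conservative rule) an
#' `extreme` outlier. Quartiles use linear-interpolation quantiles
#' (`stats::quantile` type 7). Values exactly on a fence are not outliers, so
#' constant data (IQR 0) yields no flags. Flags are invariant under affine
#' transforms of the data.
#'
#' @param values numeric vector, length >= 4.
#' @param k_normal,k_extreme fence multipliers (defaults 1.5 and 3.0).
#' @return list of class `outlier_flags`: `flags` (factor
#'   none/normal/extreme per value), `q1`, `q3`, `iqr`, `inner_fences`,
#'   `outer_fences`.
#' @export
iqr_outliers <- function(values, k_normal = 1.5, k_extreme = 3.0) {
  values <- as.numeric(values)
  if (length(values) < 4L) stop("need at least 4 values for IQR fences")
  q <- stats::quantile(values, c(0.25, 0.75), names = FALSE, type = 7)
  iqr <- q[2L] - q[1L]
  inner <- c(q[1L] - k_normal * iqr, q[2L] + k_normal * iqr)
  outer <- c(q[1L] - k_extreme * iqr, q[2L] + k_extreme * iqr)
  flags <- rep("none", length(values))
  flags[values < inner[1L] | values > inner[2L]] <- "normal"
  flags[values < outer[1L] | values > outer[2L]] <- "extreme"
  structure(list(flags = factor(flags, levels = c("none", "normal", "extreme")),
                 q1 = q[1L], q3 = q[2L], iqr = iqr,
                 inner_fences = inner, outer_fences = outer),
            class = "outlier_flags")
}

check_test_samples <- function(a, b) {
  if (length(a) < 2L || length(b) < 2L) {
    stop("each sample needs at least 2 values")
  }
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    stop("variance is zero in both samples; the test statistic is undefined")
  }
}

#' Welch two-sample t test
#'
#' Two-sided Welch test (unequal variances) with Welch-Satterthwaite degrees
#' of freedom, for comparing exactly two independent groups.
#'
#' @param sample_a,sample_b numeric vectors (>= 2 values each; variance must
#'   be nonzero in at least one).
#' @return list of class `test_result`: `statistic`, `df` (fractional),
#'   `p_value`, `method`.
#' @export
welch_t <- function(sample_a, sample_b) {
  check_test_samples(sample_a, sample_b)
  ht <- stats::t.test(sample_a, sample_b, var.equal = FALSE)
  structure(list(statistic = unname(ht$statistic), df = unname(ht$parameter),
                 p_value = ht$p.value, method = "Welch two-sample t test"),
            class = "test_result")
}

#' One-way analysis of variance
#'
#' Classic fixed-effects one-way ANOVA (`F = MS_between / MS_within` on
#' `g - 1`, `N - g` degrees of freedom), for more than two independent groups.
#'
#' @param groups list of numeric vectors, >= 2 groups with >= 2 values each.
#' @return a `test_result` with `df` of length 2.
#' @export
anova_oneway <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L) stop("need at least 2 groups")
  if (any(vapply(groups, length, integer(1)) < 2L)) {
    stop("every group needs at least 2 values")
  }
  y <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), vapply(groups, length, integer(1))))
  ht <- stats::oneway.test(y ~ g, var.equal = TRUE)
  structure(list(statistic = unname(ht$statistic),
                 df = unname(ht$parameter), p_value = ht$p.value,
                 method = "one-way ANOVA"),
            class = "test_result")
}

#' Chi-square test on a contingency table
#'
#' Pearson chi-square on an r x c count table, df `(r-1)(c-1)`, optional Yates
#' continuity correction for 2 x 2 tables (off by default).
#'
#' @param table matrix of counts; all row and column margins must be positive.
#' @param yates apply Yates correction (2 x 2 only).
#' @return a `test_result`.
#' @export
chi_square <- function(table, yates = FALSE) {
  tab <- as.matrix(table)
  if (any(tab < 0)) stop("counts must be non-negative")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop("zero row or column margin; expected counts would be zero")
  }
  ht <- suppressWarnings(stats::chisq.test(tab, correct = yates))
  structure(list(statistic = unname(ht$statistic),
                 df = unname(ht$parameter), p_value = ht$p.value,
                 method = if (yates) "chi-square (Yates)" else "chi-square"),
            class = "test_result")
}

#' Pearson product-moment correlation
#'
#' @param x,y numeric vectors of equal length >= 3, neither constant.
#' @return the correlation coefficient `r` in `[-1, 1]`.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3L) stop("need at least 3 pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("correlation is undefined for constant input")
  }
  stats::cor(x, y, method = "pearson")
}

#' @export
print.test_result <- function(x, ...) {
  cat(sprintf("%s: statistic = %.6g, df = %s, p = %.6g\n", x$method,
              x$statistic, paste(signif(x$df, 6), collapse = ", "),
              x$p_value))
  invisible(x)
}

#' Univariate k-means clustering
#'
#' Best-of-`n_init` k-means on one-dimensional values, deterministic under
#' `seed`; centers are returned sorted ascending and assignments relabelled
#' accordingly.
#'
#' @param values numeric vector.
#' @param k number of clusters, `1 <= k <=` number of distinct values.
#' @param seed integer RNG seed.
#' @param n_init number of random restarts (default 10).
#' @return list of class `cluster_result`: `k`, `centers` (sorted),
#'   `assignments`, `wss` (total within-cluster sum of squares).
#' @export
kmeans_1d <- function(values, k, seed = 1L, n_init = 10L) {
  values <- as.numeric(values)
  ndist <- length(unique(values))
  if (k < 1L) stop("k must be >= 1")
  if (k > ndist) {
    stop(sprintf("k = %d exceeds the %d distinct values", k, ndist))
  }
  if (k == ndist) {
    # exact solution: every distinct value is its own center
    centers <- sort(unique(values))
    return(structure(list(k = k, centers = centers,
                          assignments = match(values, centers), wss = 0),
                     class = "cluster_result"))
  }
  fit <- local_seed(seed, {
    stats::kmeans(values, centers = k, nstart = n_init, iter.max = 100L)
  })
  ord <- order(fit$centers[, 1L])
  relabel <- match(seq_len(k), ord)
  structure(list(k = k, centers = unname(sort(fit$centers[, 1L])),
                 assignments = relabel[fit$cluster],
                 wss = fit$tot.withinss),
            class = "cluster_result")
}

#' Elbow-criterion cluster-count selection
#'
#' Scans `k = 1..k_max`, records the total within-cluster sum of squares
#' (WSS), and selects the `k` with the largest second difference of the WSS
#' curve (the sharpest bend); ties go to the smaller `k`. The selection is
#' flagged low-confidence when the bend is weak: when the largest second
#' difference is below `confidence_min` times the total WSS drop over the
#' scanned range (no elbow dominates, as for a single compact cluster), or
#' when the top two bends are numerically tied.
#'
#' @param values numeric vector with at least `k_max` distinct values.
#' @param k_max largest cluster count scanned (>= 3).
#' @param seed RNG seed (restarts in the underlying [kmeans_1d()]).
#' @param n_init restarts per k.
#' @param confidence_min dominance threshold for the confidence flag
#'   (default 0.8).
#' @return integer `k`, with attributes `wss` (per-k curve), `second_diff` and
#'   `low_confidence` (logical).
#' @export
elbow_select <- function(values, k_max = 6L, seed = 1L, n_init = 10L,
                         confidence_min = 0.8) {
  values <- as.numeric(values)
  if (k_max < 3L) stop("k_max must be >= 3")
  if (length(unique(values)) < k_max) {
    stop("too few distinct values to scan k up to ", k_max)
  }
  wss <- vapply(seq_len(k_max), function(k) {
    kmeans_1d(values, k, seed = seed + k, n_init = n_init)$wss
  }, numeric(1))
  ks <- 2:(k_max - 1L)
  sd2 <- wss[ks - 1L] - 2 * wss[ks] + wss[ks + 1L]
  best <- which.max(sd2) # first maximum: ties go to the smaller k
  drop_total <- wss[1L] - wss[k_max]
  tied <- sum(abs(sd2 - sd2[best]) <= 1e-9 * max(abs(sd2[best]), 1e-300)) > 1L
  low_conf <- tied || drop_total <= 0 ||
    sd2[best] < confidence_min * drop_total
  structure(ks[best], wss = wss, second_diff = sd2,
            low_confidence = low_conf)
}
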