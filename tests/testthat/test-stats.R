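test_that("IQR fences match a brute-force computation and flag correctly", {
  x <- c(1, 2, 3, 4, 100)
  fl <- iqr_outliers(x)
  q1 <- oracle_quantile(x, 0.25)
  q3 <- oracle_quantile(x, 0.75)
  expect_equal(fl$q1, q1, tolerance = 1e-12)
  expect_equal(fl$q3, q3, tolerance = 1e-12)
  expect_equal(fl$outer_fences[2], q3 + 3 * (q3 - q1), tolerance = 1e-12)
  expect_equal(as.character(fl$flags), c(rep("none", 4), "extreme"))

  # constant data: no outliers
  expect_true(all(iqr_outliers(rep(5, 10))$flags == "none"))

  # a value engineered between the fences is a normal, not extreme, outlier
  base <- c(1, 2, 3, 4, 5, 6, 7, 8)
  q <- stats::quantile(base, c(0.25, 0.75), names = FALSE)
  mild <- q[2] + 2 * (q[2] - q[1])
  fl2 <- iqr_outliers(c(base, mild))
  expect_equal(as.character(fl2$flags[9]), "normal")
  expect_error(iqr_outliers(c(1, 2, 3)), "4 values")
})

test_that("outlier flags are invariant under affine transforms", {
  set.seed(19)
  for (i in 1:20) {
    x <- stats::rnorm(30)
    x[1] <- 10 # force an outlier
    a <- stats::runif(1, 0.1, 5)
    b <- stats::rnorm(1, sd = 10)
    expect_identical(iqr_outliers(x)$flags, iqr_outliers(a * x + b)$flags)
    expect_identical(iqr_outliers(x)$flags, iqr_outliers(-x)$flags)
  }
})

test_that("Welch test matches the textbook formula on random draws", {
  set.seed(5)
  for (i in 1:100) {
    a <- stats::rnorm(sample(3:12, 1), sd = stats::runif(1, 0.5, 3))
    b <- stats::rnorm(sample(3:12, 1), mean = stats::rnorm(1),
                      sd = stats::runif(1, 0.5, 3))
    got <- welch_t(a, b)
    want <- oracle_welch(a, b)
    expect_equal(got$statistic, want$t, tolerance = 1e-9)
    expect_equal(got$df, want$df, tolerance = 1e-9)
    expect_equal(got$p_value, want$p, tolerance = 1e-9)
  }
  # identical samples: t = 0, p = 1
  same <- welch_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  # shifted copy: |t| from the hand formula
  sh <- welch_t(c(1, 2, 3), c(11, 12, 13))
  expect_equal(sh$statistic, oracle_welch(c(1, 2, 3), c(11, 12, 13))$t,
               tolerance = 1e-12)
  expect_error(welch_t(c(1, 1, 1), c(2, 2)), "variance")
})

test_that("Welch equals Student t in the equal-variance equal-n case", {
  # equal n and exactly equal sample variances: the two statistics coincide
  a <- c(1, 2, 3, 4)
  b <- c(2.5, 3.5, 4.5, 5.5)
  got <- welch_t(a, b)
  st <- stats::t.test(a, b, var.equal = TRUE)
  expect_equal(got$statistic, unname(st$statistic), tolerance = 1e-12)
  expect_equal(got$df, unname(st$parameter), tolerance = 1e-12)
})

test_that("one-way ANOVA matches the sums-of-squares oracle", {
  set.seed(6)
  for (i in 1:100) {
    k <- sample(2:5, 1)
    groups <- lapply(seq_len(k), function(j) {
      stats::rnorm(sample(3:9, 1), mean = stats::rnorm(1))
    })
    got <- anova_oneway(groups)
    want <- oracle_anova(groups)
    expect_equal(got$statistic, want$f, tolerance = 1e-9)
    expect_equal(unname(got$df), c(want$df1, want$df2), tolerance = 1e-12)
    expect_equal(got$p_value, want$p, tolerance = 1e-9)
  }
  # identical groups: F = 0, p = 1
  same <- anova_oneway(list(c(1, 2, 3), c(1, 2, 3), c(1, 2, 3)))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  # two groups: F = t^2 of the pooled-variance t test
  a <- c(1.2, 3.4, 2.2, 4.1)
  b <- c(2.5, 5.1, 3.3)
  f2 <- anova_oneway(list(a, b))
  tt <- stats::t.test(a, b, var.equal = TRUE)
  expect_equal(f2$statistic, unname(tt$statistic)^2, tolerance = 1e-9)
  expect_error(anova_oneway(list(c(1, 2), c(3))), "at least 2 values")
})

test_that("chi-square matches the expected-count oracle and 2x2 identity", {
  set.seed(7)
  for (i in 1:100) {
    r <- sample(2:4, 1)
    cc <- sample(2:4, 1)
    tab <- matrix(stats::rpois(r * cc, 8) + 1, r, cc)
    got <- chi_square(tab)
    want <- oracle_chisq(tab)
    expect_equal(got$statistic, want$stat, tolerance = 1e-9)
    expect_equal(got$df, want$df)
    expect_equal(got$p_value, want$p, tolerance = 1e-9)
  }
  # uniform table: statistic 0, p 1
  u <- chi_square(matrix(10, 2, 2))
  expect_equal(u$statistic, 0)
  expect_equal(u$p_value, 1)
  # diagonal 2x2: hand value 40
  d <- chi_square(rbind(c(20, 0), c(0, 20)))
  expect_equal(d$statistic, 40)
  expect_equal(d$df, 1)
  # closed-form 2x2 identity: N(ad - bc)^2 / product of margins
  for (i in 1:20) {
    t2 <- matrix(stats::rpois(4, 10) + 1, 2, 2)
    want2 <- sum(t2) * (t2[1, 1] * t2[2, 2] - t2[1, 2] * t2[2, 1])^2 /
      prod(c(rowSums(t2), colSums(t2)))
    expect_equal(chi_square(t2)$statistic, want2, tolerance = 1e-9)
  }
  expect_error(chi_square(rbind(c(0, 0), c(1, 2))), "margin")
})

test_that("Pearson r matches the covariance oracle and the exact cases", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(pearson_r(x, 2 * x + 1), 1)
  expect_equal(pearson_r(x, -x), -1)
  y <- c(2.1, 3.9, 6.2, 7.8, 10.5)
  expect_equal(pearson_r(x, y), oracle_pearson(x, y), tolerance = 1e-12)
  set.seed(8)
  for (i in 1:50) {
    a <- stats::rnorm(sample(3:20, 1))
    b <- stats::rnorm(length(a))
    expect_equal(pearson_r(a, b), oracle_pearson(a, b), tolerance = 1e-9)
  }
  expect_error(pearson_r(c(1, 1, 1), c(1, 2, 3)), "constant")
})

test_that("1-D k-means finds separated masses and is deterministic", {
  x <- c(rep(0, 10), rep(100, 10))
  cl <- kmeans_1d(x, 2, seed = 1)
  expect_equal(cl$centers, c(0, 100))
  expect_equal(cl$assignments, rep(c(1L, 2L), each = 10))
  expect_equal(cl$wss, 0)
  # k = 1: center is the mean
  one <- kmeans_1d(c(1, 2, 6), 1)
  expect_equal(one$centers, 3)
  # k = number of distinct values: zero within-cluster scatter
  full <- kmeans_1d(c(1, 2, 6), 3)
  expect_equal(full$wss, 0)
  expect_error(kmeans_1d(c(1, 1, 2), 3), "distinct")
  # deterministic under seed
  set.seed(99)
  y <- stats::rnorm(60)
  a <- kmeans_1d(y, 3, seed = 42)
  b <- kmeans_1d(y, 3, seed = 42)
  expect_identical(a$centers, b$centers)
  expect_identical(a$assignments, b$assignments)
  # assignments map each value to its nearest center
  near <- apply(abs(outer(y, a$centers, `-`)), 1, which.min)
  expect_equal(a$assignments, as.integer(near))
})

test_that("k-means WSS is non-increasing in k", {
  set.seed(12)
  y <- c(stats::rnorm(40), stats::rnorm(40, mean = 6))
  wss <- vapply(1:6, function(k) kmeans_1d(y, k, seed = 3)$wss, numeric(1))
  expect_true(all(diff(wss) <= 1e-9))
})

test_that("elbow selection finds two well-separated clusters", {
  set.seed(13)
  y <- c(stats::rnorm(50, 0, 1), stats::rnorm(50, 10, 1)) # 10 SDs apart
  k <- elbow_select(y, k_max = 6, seed = 2)
  expect_equal(as.integer(k), 2L)
  expect_false(attr(k, "low_confidence"))
})

test_that("a single compact cluster yields a low-confidence elbow", {
  set.seed(14)
  y <- stats::rnorm(80, 0, 0.1)
  k <- elbow_select(y, k_max = 6, seed = 2)
  expect_equal(as.integer(k), 2L) # smallest k wins when no elbow dominates
  expect_true(attr(k, "low_confidence"))
  expect_error(elbow_select(c(1, 1, 2, 2), k_max = 3), "distinct")
  expect_error(elbow_select(stats::rnorm(10), k_max = 2), "k_max")
})
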