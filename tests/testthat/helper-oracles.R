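# Brute-force textbook oracles, kept independent of the implementation path.

oracle_quantile <- function(x, p) {
  # linear-interpolation quantile on sorted order statistics
  s <- sort(x)
  h <- (length(s) - 1) * p + 1
  lo <- floor(h)
  s[lo] + (h - lo) * (s[min(lo + 1, length(s))] - s[lo])
}

oracle_welch <- function(a, b) {
  va <- sum((a - mean(a))^2) / (length(a) - 1)
  vb <- sum((b - mean(b))^2) / (length(b) - 1)
  sa <- va / length(a)
  sb <- vb / length(b)
  t <- (mean(a) - mean(b)) / sqrt(sa + sb)
  df <- (sa + sb)^2 / (sa^2 / (length(a) - 1) + sb^2 / (length(b) - 1))
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

oracle_anova <- function(groups) {
  N <- sum(lengths(groups))
  g <- length(groups)
  grand <- mean(unlist(groups))
  ssb <- sum(vapply(groups, function(x) length(x) * (mean(x) - grand)^2,
                    numeric(1)))
  ssw <- sum(vapply(groups, function(x) sum((x - mean(x))^2), numeric(1)))
  f <- (ssb / (g - 1)) / (ssw / (N - g))
  list(f = f, df1 = g - 1, df2 = N - g,
       p = stats::pf(f, g - 1, N - g, lower.tail = FALSE))
}

oracle_chisq <- function(tab) {
  exp_tab <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  stat <- sum((tab - exp_tab)^2 / exp_tab)
  df <- (nrow(tab) - 1) * (ncol(tab) - 1)
  list(stat = stat, df = df,
       p = stats::pchisq(stat, df, lower.tail = FALSE))
}

oracle_pearson <- function(x, y) {
  sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
}

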