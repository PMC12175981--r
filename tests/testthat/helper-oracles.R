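# Independent oracles kept deliberately naive: they check the implementation
# by a different computational route.

# two-pass covariance Pearson r
oracle_pearson <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n
  my <- sum(y) / n
  sxy <- sxx <- syy <- 0
  for (i in seq_len(n)) {
    sxy <- sxy + (x[i] - mx) * (y[i] - my)
    sxx <- sxx + (x[i] - mx)^2
    syy <- syy + (y[i] - my)^2
  }
  sxy / sqrt(sxx * syy)
}

# brute-force minimizer of sum((y - m*x)^2) by interval halving: the SSE
# derivative is proportional to -sum(x * (y - m*x)), monotone decreasing in m,
# so halving on its sign localizes the minimum to floating-point precision
# (direct ternary search on the SSE stalls at the ~sqrt(eps) plateau)
oracle_origin_slope <- function(y, x, lo = -1e6, hi = 1e6, iters = 220) {
  slope_down <- function(m) sum(x * (y - m * x)) > 0
  for (i in seq_len(iters)) {
    mid <- (lo + hi) / 2
    if (slope_down(mid)) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

# spreadsheet no-intercept statistics via R's own modeling route
oracle_origin_stats <- function(y, x) {
  s <- summary(stats::lm(y ~ x - 1))
  list(m = unname(s$coefficients[1, 1]), se_m = unname(s$coefficients[1, 2]),
       r2 = s$r.squared)
}

tiny_profiles <- function() {
  profile_matrix(matrix(c(60, 40, 0, 30, 50, 20, 10, 30, 60), 3, 3,
                        byrow = TRUE,
                        dimnames = list(c("p1", "p2", "p3"),
                                        c("ethanol", "ethyl acetate", "sorbic acid"))))
}

# subset rows of a profile_matrix without losing class
pm_rows <- function(m, ids) profile_matrix(unclass(m)[ids, , drop = FALSE])
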