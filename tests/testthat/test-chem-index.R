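test_that("origin_least_squares matches hand-derived and library statistics", {
  f1 <- origin_least_squares(c(1, 2, 3), c(1, 2, 3))
  expect_equal(f1$m, 1)
  expect_equal(f1$se_m, 0)
  expect_equal(f1$r2, 1)

  f2 <- origin_least_squares(c(2, 4, 6), c(1, 2, 3))
  expect_equal(f2$m, 2)
  expect_equal(f2$se_m, 0)
  expect_equal(f2$r2, 1)

  # exact fractions: m = 17/14, SSE = 5/14, se = sqrt(5/392), r2 = 1 - 5/294
  f3 <- origin_least_squares(c(1, 2, 4), c(1, 2, 3))
  expect_equal(f3$m, 17 / 14, tolerance = 1e-12)
  expect_equal(f3$se_m, sqrt(5 / 392), tolerance = 1e-12)
  expect_equal(f3$r2, 1 - 5 / 294, tolerance = 1e-12)
  expect_equal(f3$se_m, 0.11294, tolerance = 1e-4)
  expect_equal(f3$r2, 0.98299, tolerance = 1e-5)

  expect_error(origin_least_squares(c(1, 2), c(0, 0)), "all zeros")
  f0 <- origin_least_squares(c(0, 0), c(1, 2))
  expect_equal(f0$m, 0)
  expect_equal(f0$r2, 0)
  expect_true(f0$degenerate_y)
})

test_that("origin_least_squares agrees with lm and a grid-refinement minimizer", {
  set.seed(17)
  for (i in 1:40) {
    n <- sample(2:30, 1)
    x <- rnorm(n, sd = 2)
    if (all(x == 0)) x[1] <- 1
    y <- rnorm(n, sd = 3)
    fit <- origin_least_squares(y, x)
    ora <- oracle_origin_stats(y, x)
    expect_equal(fit$m, ora$m, tolerance = 1e-10)
    expect_equal(fit$se_m, ora$se_m, tolerance = 1e-10)
    expect_equal(fit$r2, ora$r2, tolerance = 1e-10)
    expect_equal(fit$m, oracle_origin_slope(y, x), tolerance = 1e-10)
  }
})

test_that("chem_index penalizes scaling, scatter and noise, and is permutation invariant", {
  expect_equal(chem_index(c(3, 1, 4), c(3, 1, 4)), 0)
  expect_equal(chem_index(c(2, 4, 6), c(1, 2, 3)), 1)       # pure doubling
  expect_equal(chem_index(c(1, 2, 4), c(1, 2, 3)),
               3 / 14 + 5 / 294 + sqrt(5 / 392), tolerance = 1e-12)
  # note: summing the individually rounded components gives 0.34424; the
  # exact value of 3/14 + 5/294 + sqrt(5/392) is 0.3442310
  expect_equal(chem_index(c(1, 2, 4), c(1, 2, 3)), 0.34423, tolerance = 1e-4)

  set.seed(5)
  for (i in 1:20) {
    x <- runif(12, 0.1, 10)
    y <- runif(12, 0.1, 10)
    p <- sample(12)
    expect_equal(chem_index(y[p], x[p]), chem_index(y, x), tolerance = 1e-12)
    cc <- runif(1, 0.1, 5)
    expect_equal(chem_index(cc * x, x), abs(cc - 1), tolerance = 1e-10)
  }
})

test_that("chem_index_model validates inputs and estimate_rank scores blinds", {
  m <- profile_matrix(matrix(c(50, 30, 20,
                               20, 30, 50,
                               40, 40, 20), 3, 3, byrow = TRUE,
                             dimnames = list(c("b1", "b2", "b3"),
                                             c("x", "y", "z"))))
  means <- setNames(c(0.8, 0.5, 0.2), c("b1", "b2", "b3"))
  rk <- volatrank:::rank_from_means(means)
  mod <- chem_index_model(m, rk, c("x", "y", "z"))
  expect_equal(unname(mod$benchmark_ranks[c("b1", "b2", "b3")]), 1:3)

  # blind identical to benchmark b3 (rank 3): chem-index 0, estimated rank 3
  res <- estimate_rank(c(x = 40, y = 40, z = 20), mod)
  expect_equal(res$chem_index, 0)
  expect_equal(res$estimated_rank, 3)
  expect_equal(res$best_benchmark, "b3")
  expect_false(res$tie)

  # ties resolve toward the more attractive rank and are flagged
  m2 <- profile_matrix(matrix(c(10, 20, 30,
                                30, 20, 10,
                                10, 20, 30), 3, 3, byrow = TRUE,
                              dimnames = list(c("b1", "b2", "b3"),
                                              c("x", "y", "z"))))
  mod2 <- chem_index_model(m2, rk, c("x", "y", "z"))
  res2 <- estimate_rank(c(x = 10, y = 20, z = 30), mod2)
  expect_true(res2$tie)
  expect_equal(res2$estimated_rank, 1)

  # panel compounds absent from the blind are read as 0
  res3 <- estimate_rank(c(x = 40, y = 40), mod)
  expect_equal(res3$per_benchmark$chem_index,
               vapply(c("b1", "b2", "b3"),
                      function(b) chem_index(c(40, 40, 0), unclass(m)[b, ]),
                      numeric(1)), ignore_attr = TRUE)
})

test_that("rank estimation brackets a blind planted between benchmarks at low noise", {
  hits <- vapply(1:200, function(s) {
    cfg <- synth_config(n_products = 9L, noise_sd = 0.01, seed = s)
    g <- generate_profiles(cfg, blind_latents = function(a) {
      so <- sort(a, decreasing = TRUE)
      mean(so[4:5])
    })
    tr <- g$truth
    cfg0 <- synth_config(n_products = 9L, noise_sd = 0, seed = s)
    rk <- rank_products(generate_choice_trials(tr, cfg0))
    mod <- chem_index_model(pm_rows(g$profiles, tr$benchmarks), rk,
                            c(tr$planted_positive, tr$planted_negative))
    res <- estimate_rank(pm_rows(g$profiles, tr$blinds), mod,
                         blind_id = tr$blinds)
    res$estimated_rank %in% c(4, 5)
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("rank-recovery accuracy degrades gracefully to 100% as noise vanishes", {
  acc <- vapply(c(0.1, 0.02, 0), function(ns) {
    mean(vapply(1:40, function(s) {
      cfg <- synth_config(n_products = 9L, noise_sd = ns, seed = s)
      g <- generate_profiles(cfg, blind_latents = function(a) {
        so <- sort(a, decreasing = TRUE)
        mean(so[4:5])
      })
      tr <- g$truth
      cfg0 <- synth_config(n_products = 9L, noise_sd = 0, seed = s)
      rk <- rank_products(generate_choice_trials(tr, cfg0))
      mod <- chem_index_model(pm_rows(g$profiles, tr$benchmarks), rk,
                              c(tr$planted_positive, tr$planted_negative))
      estimate_rank(pm_rows(g$profiles, tr$blinds), mod,
                    blind_id = tr$blinds)$estimated_rank %in% c(4, 5)
    }, logical(1)))
  }, numeric(1))
  expect_true(all(diff(acc) >= 0))
  expect_equal(acc[3], 1)
})
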