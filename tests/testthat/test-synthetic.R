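test_that("synth_config validates its fields", {
  cfg <- synth_config()
  expect_equal(cfg$n_products, 9L)
  expect_equal(cfg$n_compounds, 110L)
  expect_equal(cfg$n_pos + cfg$n_neg, 14L)
  expect_equal(cfg$panel_block, 21L)
  expect_error(synth_config(n_pos = 100, n_neg = 50), "exceeds n_compounds")
  expect_error(synth_config(p_nochoice = 1.2), "p_nochoice")
  expect_error(synth_config(n_products = 1), "at least 2")
  expect_error(synth_config(noise_sd = -1), "noise_sd")
})

test_that("generators are pure functions of (config, seed)", {
  cfg <- synth_config(n_blinds = 2L, seed = 123L)
  g1 <- generate_profiles(cfg)
  g2 <- generate_profiles(cfg)
  expect_identical(g1, g2)
  expect_identical(generate_choice_trials(g1$truth, cfg),
                   generate_choice_trials(g2$truth, cfg))
  pairs <- data.frame(sample_1 = c("s01", "b01"), sample_2 = c("s02", "b02"))
  expect_identical(generate_trap_trials(g1$truth, cfg, pairs),
                   generate_trap_trials(g2$truth, cfg, pairs))
  g3 <- generate_profiles(synth_config(n_blinds = 2L, seed = 124L))
  expect_false(identical(unclass(g1$profiles), unclass(g3$profiles)))
})

test_that("generated profiles satisfy the profile-matrix contract", {
  for (s in c(1L, 2L)) {
    g <- generate_profiles(synth_config(n_blinds = 1L, seed = s))
    m <- g$profiles
    expect_s3_class(m, "profile_matrix")
    expect_equal(dim(m), c(10L, 110L))
    expect_true(all(unclass(m) >= 0))
    expect_equal(unname(rowSums(m)), rep(100, 10), tolerance = 1e-6)
    expect_equal(unclass(normalize_proportions(m)), unclass(m),
                 tolerance = 1e-12)
    expect_equal(g$truth$true_ranking,
                 names(sort(-g$truth$latent_attractiveness[g$truth$benchmarks])))
  }
})

test_that("noiseless planted compounds track the score; planted beat null on average", {
  cfg <- synth_config(noise_sd = 0, seed = 2L)
  g <- generate_profiles(cfg)
  rk <- rank_products(generate_choice_trials(g$truth, cfg))
  sc <- suppressWarnings(correlate_with_ranking(g$profiles, rk))
  pos_r <- sc$r[sc$compound %in% g$truth$planted_positive]
  neg_r <- sc$r[sc$compound %in% g$truth$planted_negative]
  # monotone response to a jittered latent vs an integer score: |r| is high
  # but not exactly 1 (closure + nonlinearity), see methods vignette
  expect_true(all(pos_r > 0.95))
  expect_true(all(neg_r < -0.95))
  # unloaded compounds are exactly constant in the noiseless limit
  null_cmp <- setdiff(compounds(g$profiles),
                      c(g$truth$planted_positive, g$truth$planted_negative,
                        g$truth$planted_panel))
  expect_true(all(sc$skipped[sc$compound %in% null_cmp]))

  # under default noise, planted compounds out-correlate null compounds
  absr <- function(s) {
    cfg <- synth_config(seed = s)
    g <- generate_profiles(cfg)
    rk <- rank_products(generate_choice_trials(g$truth, cfg))
    sc <- suppressWarnings(correlate_with_ranking(g$profiles, rk))
    planted <- c(g$truth$planted_positive, g$truth$planted_negative)
    nl <- setdiff(compounds(g$profiles), c(planted, g$truth$planted_panel))
    c(mean(abs(sc$r[sc$compound %in% planted])),
      mean(abs(sc$r[sc$compound %in% nl]), na.rm = TRUE))
  }
  res <- vapply(1:30, absr, numeric(2))
  expect_gt(mean(res[1, ]), mean(res[2, ]))
})

test_that("choice trials respect indifference, saturation, and a no-trial edge", {
  tr0 <- generate_profiles(synth_config(seed = 1L))$truth
  # beta = 0: expected choosing ratio 1/2 (binomial check across all trials)
  cfg0 <- synth_config(choice_beta = 0, p_nochoice = 0, n_flies = 200L, seed = 1L)
  trials <- generate_choice_trials(tr0, cfg0)
  ratio <- sum(trials$n_a) / sum(trials$n_a + trials$n_b)
  expect_equal(ratio, 0.5, tolerance = 0.02)
  # large beta, no no-choice: the better arm takes every fly
  cfgS <- synth_config(n_products = 2L, choice_beta = 500, p_nochoice = 0,
                       seed = 1L)
  trS <- generate_profiles(cfgS)$truth
  ts <- generate_choice_trials(trS, cfgS)
  lat <- trS$latent_attractiveness
  winner_a <- lat[ts$sample_a] > lat[ts$sample_b]
  expect_true(all(ifelse(winner_a, ts$n_a, ts$n_b) == cfgS$n_flies))
})

test_that("trap trials are symmetric for equal latents and reject unknown products", {
  g <- generate_profiles(synth_config(seed = 3L))
  tr <- g$truth
  tr$latent_attractiveness[c("s01", "s02")] <- 0.5  # force equal pair
  cfg <- synth_config(p_nochoice = 0, n_flies = 4000L, seed = 3L)
  traps <- generate_trap_trials(tr, cfg,
                                data.frame(sample_1 = "s01", sample_2 = "s02"))
  expect_equal(traps$n_1 / (traps$n_1 + traps$n_2), 0.5, tolerance = 0.05)
  expect_equal(traps$n_1 + traps$n_2 + traps$n_none, 4000L)
  expect_error(generate_trap_trials(tr, cfg,
                                    data.frame(sample_1 = "s01", sample_2 = "nope")),
               "unknown product")
})

test_that("full pipeline at zero noise recovers memberships and true ranks exactly", {
  cfg <- synth_config(noise_sd = 0, seed = 7L)
  g <- generate_profiles(cfg)
  tr <- g$truth
  rk <- rank_products(generate_choice_trials(tr, cfg))
  expect_equal(rk$product_id, tr$true_ranking)
  sc <- suppressWarnings(correlate_with_ranking(g$profiles, rk))
  expect_setequal(sc$compound[sc$selected & sc$sign == "positive"],
                  tr$planted_positive)
  expect_setequal(sc$compound[sc$selected & sc$sign == "negative"],
                  tr$planted_negative)
  panel <- sc$compound[sc$selected]
  mod <- chem_index_model(g$profiles, rk, panel)
  est <- vapply(tr$benchmarks, function(p)
    estimate_rank(pm_rows(g$profiles, p), mod, blind_id = p)$estimated_rank,
    numeric(1))
  expect_equal(est, tr$true_ranks[names(est)], ignore_attr = TRUE)
})
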