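#' Configuration for the synthetic-data generator
#'
#' Defaults mirror the dimensions of the modeled study system: 9 ranked
#' benchmark products, 110 identified volatile compounds of which 10 load
#' positively and 4 negatively on a latent attractiveness axis, and a
#' 21-compound key-odorant block sharing a second latent factor.
#'
#' @param n_products number of benchmark products (default 9).
#' @param n_blinds number of additional unknown products (default 0).
#' @param n_compounds total compounds (default 110).
#' @param n_pos,n_neg compounds loaded positively / negatively on
#'   attractiveness (defaults 10, 4).
#' @param panel_block size of the correlated key-odorant block (default 21),
#'   disjoint from the loaded compounds.
#' @param effect loading magnitude on the log-abundance scale (default 1,
#'   i.e. about an e-fold swing across the attractiveness range).
#' @param noise_sd lognormal noise scale on abundances (default 0.25, a
#'   typical GC-MS proportion CV); `noise_sd = 0` selects the fully
#'   noiseless world, in which behavioral sampling also becomes
#'   deterministic.
#' @param choice_beta softmax sharpness of fly choice on the latent axis
#'   (default 3: an extreme product pair splits roughly 95:5).
#' @param p_nochoice probability a fly does not respond (default 0.4;
#'   participation in these assays is low).
#' @param n_flies flies released per trial (default 40).
#' @param seed RNG seed; every generator is a pure function of (config,
#'   seed).
#' @return a validated `synth_config` list.
#' @export
synth_config <- function(n_products = 9L, n_blinds = 0L, n_compounds = 110L,
                         n_pos = 10L, n_neg = 4L, panel_block = 21L,
                         effect = 1, noise_sd = 0.25, choice_beta = 3,
                         p_nochoice = 0.4, n_flies = 40L, seed = 1L) {
  cfg <- list(n_products = as.integer(n_products), n_blinds = as.integer(n_blinds),
              n_compounds = as.integer(n_compounds), n_pos = as.integer(n_pos),
              n_neg = as.integer(n_neg), panel_block = as.integer(panel_block),
              effect = effect, noise_sd = noise_sd, choice_beta = choice_beta,
              p_nochoice = p_nochoice, n_flies = as.integer(n_flies),
              seed = as.integer(seed))
  counts <- unlist(cfg[c("n_products", "n_blinds", "n_compounds", "n_pos",
                         "n_neg", "panel_block", "n_flies")])
  if (any(counts < 0)) stop("counts must be non-negative")
  if (cfg$n_products < 2L) stop("need at least 2 products")
  if (cfg$n_pos + cfg$n_neg + cfg$panel_block > cfg$n_compounds) {
    stop("n_pos + n_neg + panel_block exceeds n_compounds")
  }
  if (cfg$p_nochoice < 0 || cfg$p_nochoice > 1) stop("p_nochoice must be in [0,1]")
  if (cfg$noise_sd < 0 || cfg$effect < 0) stop("effect and noise_sd must be >= 0")
  structure(cfg, class = "synth_config")
}

# group abundances b_j * exp(load_j * latent_i + noise), rescaled so each
# product's group total equals the baseline total: closure to 100% then
# leaves compounds outside the group untouched in the noiseless limit
synth_group <- function(latent, b, load, noise_sd) {
  raw <- outer(latent, load, function(a, l) exp(l * a)) *
    matrix(exp(stats::rnorm(length(latent) * length(b), 0, noise_sd)),
           length(latent), length(b))
  raw <- sweep(raw, 2L, b, `*`)
  sweep(raw, 1L, sum(b) / rowSums(raw), `*`)
}

#' Generate a volatile profile matrix with planted structure
#'
#' Draws latent attractiveness values evenly spaced then jittered, plants
#' three compound groups — positively loaded, negatively loaded, and a
#' correlated key-odorant block driven by a second factor generated
#' orthogonal to the attractiveness axis — on a lognormal abundance scale,
#' and closes every row to 100%. The loaded group and the block are each
#' rescaled to a constant per-product total before closure, so that in the
#' noiseless limit unloaded compounds are exactly constant (closure would
#' otherwise leak the planted signal into every compound).
#'
#' @param cfg a [synth_config()].
#' @param blind_latents optional latent attractiveness values for the blind
#'   products: a numeric vector (overrides `cfg$n_blinds`) or a function of
#'   the benchmark latent vector returning one.
#' @return list with `profiles` (a [profile_matrix()] of benchmarks then
#'   blinds) and `truth`, a `synth_truth` list: `benchmarks`, `blinds`,
#'   `latent_attractiveness`, `block_factor`, `planted_positive`,
#'   `planted_negative`, `planted_panel`, `panel_seeds` (first five block
#'   members), `true_ranking` (benchmark ids, most attractive first) and
#'   `true_ranks`.
#' @export
generate_profiles <- function(cfg, blind_latents = NULL) {
  stopifnot(inherits(cfg, "synth_config"))
  set.seed(cfg$seed)
  n <- cfg$n_products
  spacing <- 1 / max(1L, n - 1L)
  a <- seq(1, 0, length.out = n) + stats::rnorm(n, 0, 0.25 * spacing)
  if (is.function(blind_latents)) blind_latents <- blind_latents(a)
  if (is.null(blind_latents)) {
    blind_latents <- if (cfg$n_blinds > 0L)
      stats::runif(cfg$n_blinds, min(a), max(a)) else numeric(0)
  }
  n_blind <- length(blind_latents)
  lat <- c(a, blind_latents)
  ids <- c(sprintf("s%02d", seq_len(n)),
           if (n_blind) sprintf("b%02d", seq_len(n_blind)))
  names(lat) <- ids

  # block factor: orthogonalized against the attractiveness axis (value and
  # rank) so the two planted structures stay statistically separable
  f_raw <- stats::rnorm(n)
  f <- stats::residuals(stats::lm(f_raw ~ a + rank(a)))
  if (stats::sd(f) == 0) f <- f_raw - mean(f_raw)
  f <- f / max(stats::sd(f), 1e-12)
  f <- c(f, stats::rnorm(n_blind))
  names(f) <- ids

  comps <- sprintf("cmp%03d", seq_len(cfg$n_compounds))
  i_pos <- seq_len(cfg$n_pos)
  i_neg <- cfg$n_pos + seq_len(cfg$n_neg)
  i_blk <- cfg$n_pos + cfg$n_neg + seq_len(cfg$panel_block)
  b <- exp(stats::rnorm(cfg$n_compounds, 0, 1))  # baseline abundances

  vals <- matrix(rep(b, each = length(lat)), length(lat), cfg$n_compounds,
                 dimnames = list(ids, comps))
  if (cfg$n_pos + cfg$n_neg > 0L) {
    load_pn <- c(rep(cfg$effect, cfg$n_pos), rep(-cfg$effect, cfg$n_neg))
    vals[, c(i_pos, i_neg)] <- synth_group(lat, b[c(i_pos, i_neg)], load_pn,
                                           cfg$noise_sd)
  }
  if (cfg$panel_block > 0L) {
    n_up <- ceiling(cfg$panel_block / 2)
    load_blk <- c(rep(cfg$effect, n_up), rep(-cfg$effect, cfg$panel_block - n_up))
    vals[, i_blk] <- synth_group(f, b[i_blk], load_blk, cfg$noise_sd)
  }
  null_idx <- setdiff(seq_len(cfg$n_compounds), c(i_pos, i_neg, i_blk))
  if (length(null_idx) && cfg$noise_sd > 0) {
    vals[, null_idx] <- vals[, null_idx] *
      exp(stats::rnorm(length(lat) * length(null_idx), 0, cfg$noise_sd))
  }
  profiles <- normalize_proportions(profile_matrix(vals))

  bench_ids <- ids[seq_len(n)]
  ord <- order(-a, bench_ids)
  truth <- structure(list(
    benchmarks = bench_ids,
    blinds = if (n_blind) ids[n + seq_len(n_blind)] else character(0),
    latent_attractiveness = lat,
    block_factor = f,
    planted_positive = comps[i_pos],
    planted_negative = comps[i_neg],
    planted_panel = comps[i_blk],
    panel_seeds = comps[i_blk][seq_len(min(5L, cfg$panel_block))],
    true_ranking = bench_ids[ord],
    true_ranks = stats::setNames(order(ord), bench_ids)
  ), class = "synth_truth")
  list(profiles = profiles, truth = truth)
}

# one two-choice outcome: counts (n_a, n_b, n_none); noiseless world is
# fully deterministic (all responders take the more attractive arm)
sample_choice <- function(a1, a2, cfg) {
  if (cfg$noise_sd == 0) {
    n_none <- round(cfg$p_nochoice * cfg$n_flies)
    resp <- cfg$n_flies - n_none
    n1 <- if (a1 >= a2) resp else 0L
    return(c(n1, resp - n1, n_none))
  }
  n_none <- stats::rbinom(1L, cfg$n_flies, cfg$p_nochoice)
  resp <- cfg$n_flies - n_none
  p1 <- 1 / (1 + exp(-cfg$choice_beta * (a1 - a2)))
  n1 <- stats::rbinom(1L, resp, p1)
  c(n1, resp - n1, n_none)
}

#' Generate two-choice T-maze trials from planted attractiveness
#'
#' Each released fly independently fails to respond with probability
#' `p_nochoice`; responders choose an arm with probability proportional to
#' `exp(choice_beta * latent)`. Designs: `round_robin` runs every unordered
#' product pair once; `calibrator` emulates the sequential calibration
#' scheme — rounds proceed worst-first, the round's calibrator (the least
#' attractive remaining product) is tested against every remaining product
#' and then excluded from later rounds.
#'
#' @param truth a `synth_truth` from [generate_profiles()].
#' @param cfg the same [synth_config()].
#' @param design `"round_robin"` (default) or `"calibrator"`.
#' @return a trials data.frame accepted by [rank_products()].
#' @export
generate_choice_trials <- function(truth, cfg,
                                   design = c("round_robin", "calibrator")) {
  design <- match.arg(design)
  stopifnot(inherits(truth, "synth_truth"), inherits(cfg, "synth_config"))
  set.seed(cfg$seed + 1L)
  lat <- truth$latent_attractiveness[truth$benchmarks]
  ids <- truth$benchmarks
  rows <- list()
  if (design == "round_robin") {
    for (i in seq_len(length(ids) - 1L)) for (j in (i + 1L):length(ids)) {
      cnt <- sample_choice(lat[i], lat[j], cfg)
      rows[[length(rows) + 1L]] <- data.frame(
        round_id = 1L, sample_a = ids[i], sample_b = ids[j],
        n_a = cnt[1], n_b = cnt[2], n_none = cnt[3], calibrator = NA_character_)
    }
  } else {
    worst_first <- ids[order(lat, ids)]
    for (r in seq_len(length(ids) - 1L)) {
      cal <- worst_first[r]
      for (op in worst_first[(r + 1L):length(ids)]) {
        cnt <- sample_choice(lat[cal], lat[op], cfg)
        rows[[length(rows) + 1L]] <- data.frame(
          round_id = r, sample_a = cal, sample_b = op,
          n_a = cnt[1], n_b = cnt[2], n_none = cnt[3], calibrator = cal)
      }
    }
  }
  do.call(rbind, rows)
}

#' Generate paired trap-arena trials
#'
#' Allocates `n_flies` per pair among (trap 1, trap 2, no choice) by a
#' multinomial draw: no-choice with probability `p_nochoice`, the remainder
#' split with odds proportional to `exp(choice_beta * latent)`. Noiseless
#' configs (`noise_sd = 0`) allocate deterministically.
#'
#' @param truth a `synth_truth` (blind and benchmark products both allowed).
#' @param cfg the [synth_config()].
#' @param pairs data.frame with columns `sample_1`, `sample_2` (product
#'   ids), optionally `pair_id`.
#' @return a trap table accepted by [trap_index()].
#' @export
generate_trap_trials <- function(truth, cfg, pairs) {
  stopifnot(inherits(truth, "synth_truth"), inherits(cfg, "synth_config"))
  pairs <- as.data.frame(pairs)
  names(pairs) <- clean_name(names(pairs))
  stopifnot(all(c("sample_1", "sample_2") %in% names(pairs)))
  if (!"pair_id" %in% names(pairs)) pairs$pair_id <- paste0("pair", seq_len(nrow(pairs)))
  set.seed(cfg$seed + 2L)
  lat <- truth$latent_attractiveness
  for (col in c("sample_1", "sample_2")) {
    pairs[[col]] <- clean_name(pairs[[col]])
    unknown <- setdiff(pairs[[col]], names(lat))
    if (length(unknown)) stop("unknown product(s): ", paste(unknown, collapse = ", "))
  }
  rows <- lapply(seq_len(nrow(pairs)), function(i) {
    a1 <- lat[pairs$sample_1[i]]; a2 <- lat[pairs$sample_2[i]]
    if (cfg$noise_sd == 0) {
      cnt <- sample_choice(a1, a2, cfg)
    } else {
      p1 <- 1 / (1 + exp(-cfg$choice_beta * (a1 - a2)))
      pr <- c((1 - cfg$p_nochoice) * p1, (1 - cfg$p_nochoice) * (1 - p1),
              cfg$p_nochoice)
      cnt <- as.integer(stats::rmultinom(1L, cfg$n_flies, pr))
    }
    data.frame(pair_id = pairs$pair_id[i], sample_1 = pairs$sample_1[i],
               sample_2 = pairs$sample_2[i],
               n_1 = cnt[1], n_2 = cnt[2], n_none = cnt[3])
  })
  do.call(rbind, rows)
}
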