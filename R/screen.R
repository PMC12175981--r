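#' Pearson correlation with a t-based p-value
#'
#' Product-moment correlation r between two vectors, with the two-sided
#' p-value from t = r * sqrt((n - 2) / (1 - r^2)) on n - 2 degrees of
#' freedom. Constant input yields `r = NA` with a warning (screens skip such
#' compounds) rather than an error.
#'
#' @param x,y numeric vectors of equal length, n >= 3.
#' @return list with elements `r`, `p`, `n`.
#' @examples
#' pearson_r(c(1, 2, 4), c(2, 1, 5))
#' @export
pearson_r <- function(x, y) {
  stopifnot(is.numeric(x), is.numeric(y), length(x) == length(y))
  n <- length(x)
  if (n < 3L) stop("pearson_r needs n >= 3")
  if (any(!is.finite(x)) || any(!is.finite(y))) stop("non-finite input")
  xd <- x - mean(x)
  yd <- y - mean(y)
  sx <- sqrt(sum(xd^2))
  sy <- sqrt(sum(yd^2))
  if (sx == 0 || sy == 0) {
    warning("constant vector: correlation undefined")
    return(list(r = NA_real_, p = NA_real_, n = n))
  }
  r <- sum(xd * yd) / (sx * sy)
  r <- max(-1, min(1, r))
  if (abs(r) == 1) {
    p <- 0
  } else {
    tstat <- r * sqrt((n - 2) / (1 - r^2))
    p <- 2 * stats::pt(abs(tstat), df = n - 2, lower.tail = FALSE)
  }
  list(r = r, p = p, n = n)
}

match_ranking_products <- function(m, ranking) {
  score <- attractiveness_scores(ranking)
  missing_m <- setdiff(names(score), products(m))
  missing_r <- setdiff(products(m), names(score))
  if (length(missing_m) || length(missing_r)) {
    stop("product sets differ; missing from profiles: [",
         paste(missing_m, collapse = ", "), "]; missing from ranking: [",
         paste(missing_r, collapse = ", "), "]")
  }
  score[products(m)]
}

#' Correlate every compound with the attractiveness ranking
#'
#' Screens each compound's proportion vector against the products'
#' attractiveness scores with [pearson_r()]. Compounds constant across
#' products are flagged `skipped` (r undefined) and excluded from selection.
#'
#' @param m a [profile_matrix()] whose products match `ranking`.
#' @param ranking an `attractiveness_ranking` from [rank_products()].
#' @param alpha significance level for the `selected` flag (default 0.05; no
#'   multiple-testing correction, see `p_adjust`).
#' @param p_adjust p-value adjustment method passed to [stats::p.adjust()];
#'   default `"none"`.
#' @return a `correlation_screen` data.frame: `compound`, `r`, `p`, `sign`
#'   (`"positive"`/`"negative"`), `selected`, `skipped`, sorted by
#'   descending r (skipped compounds last).
#' @export
correlate_with_ranking <- function(m, ranking, alpha = 0.05, p_adjust = "none") {
  stopifnot(inherits(m, "profile_matrix"))
  score <- match_ranking_products(m, ranking)
  res <- lapply(compounds(m), function(cmp) {
    v <- unclass(m)[, cmp]
    if (stats::sd(v) == 0) {
      return(data.frame(compound = cmp, r = NA_real_, p = NA_real_,
                        sign = NA_character_, skipped = TRUE))
    }
    pr <- pearson_r(v, as.numeric(score))
    data.frame(compound = cmp, r = pr$r, p = pr$p,
               sign = if (pr$r >= 0) "positive" else "negative",
               skipped = FALSE)
  })
  out <- do.call(rbind, res)
  n_skip <- sum(out$skipped)
  if (n_skip > 0) {
    warning(n_skip, " constant compound(s) skipped in correlation screen")
  }
  out$p <- stats::p.adjust(out$p, method = p_adjust)
  out$selected <- !out$skipped & out$p < alpha
  out <- out[order(out$skipped, -ifelse(out$skipped, -Inf, out$r)), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("correlation_screen", "data.frame")
  out
}

#' Top positively / negatively correlated compounds of a screen
#'
#' @param screen a `correlation_screen`.
#' @param k how many compounds per sign.
#' @return list with character vectors `positive` (k largest r) and
#'   `negative` (k most negative r), skipped compounds excluded.
#' @export
top_correlates <- function(screen, k) {
  stopifnot(inherits(screen, "correlation_screen"), k >= 1)
  ok <- screen[!screen$skipped, , drop = FALSE]
  ok <- ok[order(-ok$r), , drop = FALSE]
  list(positive = utils::head(ok$compound, k),
       negative = rev(utils::tail(ok$compound, k)))
}

#' Per-odorant regression of attractiveness on proportion
#'
#' For each compound, ordinary least squares (with intercept) of
#' attractiveness score on the compound's proportion; the compound is
#' `selected` when the slope's two-sided t-test p-value is below `alpha`.
#' No multiple-testing correction by default; set `p_adjust = "BH"` for a
#' Benjamini-Hochberg variant.
#'
#' @inheritParams correlate_with_ranking
#' @param alpha selection level on the slope p-value (default 0.05).
#' @return a `regression_screen` data.frame: `compound`, `slope`,
#'   `intercept`, `p_slope`, `selected`, `skipped`.
#' @export
regress_rank_on_odorant <- function(m, ranking, alpha = 0.05, p_adjust = "none") {
  stopifnot(inherits(m, "profile_matrix"), nrow(m) >= 3L)
  score <- as.numeric(match_ranking_products(m, ranking))
  res <- lapply(compounds(m), function(cmp) {
    v <- unclass(m)[, cmp]
    if (stats::sd(v) == 0) {
      return(data.frame(compound = cmp, slope = NA_real_, intercept = NA_real_,
                        p_slope = NA_real_, skipped = TRUE))
    }
    fit <- summary(stats::lm(score ~ v))$coefficients
    data.frame(compound = cmp, slope = fit["v", "Estimate"],
               intercept = fit["(Intercept)", "Estimate"],
               p_slope = fit["v", "Pr(>|t|)"], skipped = FALSE)
  })
  out <- do.call(rbind, res)
  out$p_slope <- stats::p.adjust(out$p_slope, method = p_adjust)
  out$selected <- !out$skipped & out$p_slope < alpha
  rownames(out) <- NULL
  class(out) <- c("regression_screen", "data.frame")
  out
}

#' Expand seed odorants into a key-odorant biomarker panel
#'
#' For each seed compound, every other compound is correlated (Pearson r)
#' against the seed's proportion vector across products; the `top_k` best
#' correlates under the sign rule are kept, discarding those below `min_r`
#' (`positive_only`: keep by descending r, drop r < min_r; `absolute`: keep
#' by descending |r|, drop |r| < min_r). The panel is the deduplicated union
#' of the seeds and all kept correlates, ordered by descending mean
#' proportion across products.
#'
#' Compositional data caution: because proportions are closed to 100%, a
#' block of compounds driven by one shared factor necessarily contains
#' members moving in opposite relative directions; `sign_rule = "absolute"`
#' recovers both sides of such a block.
#'
#' @param m a [profile_matrix()].
#' @param seeds character vector of seed compounds, all present in `m`.
#' @param top_k maximum correlates kept per seed (>= 1).
#' @param min_r correlation floor (default 0).
#' @param sign_rule `"positive_only"` (default) or `"absolute"`.
#' @return a `biomarker_panel` list: `seeds`, `per_seed_top` (per seed a
#'   data.frame of compound, r), and `panel` (ordered character vector).
#' @export
pattern_search <- function(m, seeds, top_k = 25L, min_r = 0,
                           sign_rule = c("positive_only", "absolute")) {
  sign_rule <- match.arg(sign_rule)
  stopifnot(inherits(m, "profile_matrix"))
  if (!is.numeric(top_k) || top_k < 1L) stop("top_k must be >= 1")
  seeds <- clean_name(seeds)
  missing <- setdiff(seeds, compounds(m))
  if (length(missing)) stop("seed(s) not in matrix: ", paste(missing, collapse = ", "))
  vals <- unclass(m)
  per_seed <- lapply(seeds, function(s) {
    sv <- vals[, s]
    if (stats::sd(sv) == 0) stop("seed '", s, "' is constant across products")
    others <- setdiff(compounds(m), s)
    rs <- vapply(others, function(cmp) {
      v <- vals[, cmp]
      if (stats::sd(v) == 0) return(NA_real_)
      suppressWarnings(pearson_r(v, sv)$r)
    }, numeric(1))
    tab <- data.frame(compound = others, r = rs)
    tab <- tab[!is.na(tab$r), , drop = FALSE]
    key <- if (sign_rule == "absolute") abs(tab$r) else tab$r
    tab <- tab[key >= min_r, , drop = FALSE]
    key <- if (sign_rule == "absolute") abs(tab$r) else tab$r
    tab <- tab[order(-key, tab$compound), , drop = FALSE]
    utils::head(tab, top_k)
  })
  names(per_seed) <- seeds
  members <- unique(c(seeds, unlist(lapply(per_seed, `[[`, "compound"),
                                    use.names = FALSE)))
  mean_prop <- colMeans(vals)[members]
  panel <- members[order(-mean_prop, members)]
  structure(list(seeds = seeds, per_seed_top = per_seed, panel = panel),
            class = "biomarker_panel")
}

#' @export
print.biomarker_panel <- function(x, ...) {
  cat("biomarker_panel: ", length(x$panel), " compounds from ",
      length(x$seeds), " seeds\n", sep = "")
  cat("seeds:", paste(x$seeds, collapse = ", "), "\n")
  cat("panel (by descending mean proportion):\n ",
      paste(x$panel, collapse = ", "), "\n")
  invisible(x)
}
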