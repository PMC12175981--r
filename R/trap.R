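#' Validate a table of trap-arena trials
#'
#' One row per paired trapping test: `pair_id`, the two products
#' (`sample_1`, `sample_2`), the catches in each trap (`n_1`, `n_2`) and the
#' non-responders (`n_none`).
#'
#' @param traps data.frame with the columns above (`n_none` optional,
#'   defaults to 0).
#' @return validated data.frame with normalized names.
#' @export
as_trap_trials <- function(traps) {
  traps <- as.data.frame(traps)
  names(traps) <- clean_name(names(traps))
  need <- c("pair_id", "sample_1", "sample_2", "n_1", "n_2")
  if (!all(need %in% names(traps))) {
    stop("trap table needs columns: ", paste(need, collapse = ", "))
  }
  if (!"n_none" %in% names(traps)) traps$n_none <- 0L
  for (col in c("sample_1", "sample_2")) traps[[col]] <- clean_name(traps[[col]])
  counts <- as.matrix(traps[c("n_1", "n_2", "n_none")])
  if (any(!is.finite(counts)) || any(counts < 0) || any(counts != round(counts))) {
    stop("trap counts must be non-negative integers")
  }
  if (any(same <- traps$sample_1 == traps$sample_2)) {
    stop("sample_1 equals sample_2 in pair(s) ",
         paste(traps$pair_id[same], collapse = ", "))
  }
  traps
}

#' Trap-index of a paired trapping test
#'
#' Fraction of flies caught in each product's trap; `"responders"` (default)
#' excludes no-choice flies so the two indices sum to 1.
#'
#' @param traps a trap table (see [as_trap_trials()]); vectorized over rows.
#' @param denominator `"responders"` or `"all"`.
#' @return data.frame with columns `index_1`, `index_2`.
#' @export
trap_index <- function(traps, denominator = c("responders", "all")) {
  denominator <- match.arg(denominator)
  traps <- as_trap_trials(traps)
  den <- if (denominator == "responders") traps$n_1 + traps$n_2 else
    traps$n_1 + traps$n_2 + traps$n_none
  if (any(den == 0)) {
    bad <- which(den == 0)[1]
    stop("zero ", denominator, " denominator in pair ", traps$pair_id[bad],
         " (", traps$sample_1[bad], " vs ", traps$sample_2[bad], ")")
  }
  data.frame(index_1 = traps$n_1 / den, index_2 = traps$n_2 / den)
}

chem_vs_top <- function(res) {
  # a blind product's chem-index against the rank-1 benchmark
  tab <- res$per_benchmark
  tab$chem_index[tab$rank == 1L]
}

#' Model-side coordinate for a trapped product pair
#'
#' Reduces the chem-index results of the two products of a trapping pair to
#' one number to regress trap-indices on:
#' \describe{
#'   \item{score_difference}{(default) difference in attractiveness score
#'     implied by the estimated ranks, `score(sample_1) - score(sample_2)`
#'     with score = n + 1 - rank; positive when the model predicts sample 1
#'     more attractive.}
#'   \item{index_difference}{`chem_index(sample_2) - chem_index(sample_1)`,
#'     each computed against the rank-1 benchmark; positive when sample 1 is
#'     more similar to the most attractive benchmark.}
#'   \item{sample1_similarity_to_top}{`-chem_index(sample_1 vs rank-1
#'     benchmark)`; 0 when sample 1 is the top benchmark itself.}
#' }
#'
#' @param traps a trap table; vectorized over rows.
#' @param results named list of `chem_index_result` objects (one per product
#'   appearing in `traps`), as returned by [estimate_rank()].
#' @param mode pairing rule, see above.
#' @return numeric vector, one chem-value per pair; the mode is attached as
#'   attribute `"mode"`.
#' @export
pair_chem_value <- function(traps, results,
                            mode = c("score_difference", "index_difference",
                                     "sample1_similarity_to_top")) {
  mode <- match.arg(mode)
  traps <- as_trap_trials(traps)
  names(results) <- clean_name(names(results))
  missing <- setdiff(unique(c(traps$sample_1, traps$sample_2)), names(results))
  if (length(missing)) {
    stop("no chem-index result for product(s): ", paste(missing, collapse = ", "))
  }
  n_bench <- nrow(results[[1]]$per_benchmark)
  val <- vapply(seq_len(nrow(traps)), function(i) {
    r1 <- results[[traps$sample_1[i]]]
    r2 <- results[[traps$sample_2[i]]]
    switch(mode,
      score_difference = (n_bench + 1 - r1$estimated_rank) -
                         (n_bench + 1 - r2$estimated_rank),
      index_difference = chem_vs_top(r2) - chem_vs_top(r1),
      sample1_similarity_to_top = -chem_vs_top(r1))
  }, numeric(1))
  attr(val, "mode") <- mode
  val
}

#' Regress trap-indices on model chem-values
#'
#' Ordinary least squares (with intercept) of the behavioral trap-index on
#' the model-side chem-value, the blind-test validation statistic. Reports
#' r2 (squared Pearson correlation), the F statistic
#' `f = r2 * (n - 2) / (1 - r2)` on (1, n - 2) degrees of freedom, and its
#' upper-tail p-value.
#'
#' @param chem_value numeric predictor (one per pair), non-constant.
#' @param trap_index numeric response (one per pair).
#' @param pair_id optional labels carried into the output.
#' @return a `validation_result` list: `points` (data.frame of pair_id,
#'   chem_value, trap_index), `slope`, `intercept`, `r2`, `f_stat`,
#'   `df` (= c(1, n - 2)), `p_value`, `n`.
#' @export
validate_traps <- function(chem_value, trap_index, pair_id = NULL) {
  stopifnot(is.numeric(chem_value), is.numeric(trap_index),
            length(chem_value) == length(trap_index))
  n <- length(chem_value)
  if (n < 3L) stop("validation regression needs n >= 3 points")
  if (stats::sd(chem_value) == 0) stop("constant chem-value predictor")
  if (is.null(pair_id)) pair_id <- paste0("pair", seq_len(n))
  fit <- stats::lm(trap_index ~ chem_value)
  co <- stats::coef(fit)
  r <- suppressWarnings(pearson_r(chem_value, trap_index)$r)
  r2 <- if (is.na(r)) 0 else r^2
  f_stat <- r2 * (n - 2) / (1 - r2)
  p <- stats::pf(f_stat, 1, n - 2, lower.tail = FALSE)
  structure(list(points = data.frame(pair_id = pair_id, chem_value = chem_value,
                                     trap_index = trap_index),
                 slope = unname(co["chem_value"]),
                 intercept = unname(co["(Intercept)"]),
                 r2 = r2, f_stat = f_stat, df = c(1, n - 2), p_value = p, n = n),
            class = "validation_result")
}

#' @export
print.validation_result <- function(x, ...) {
  cat(sprintf(paste0("validation regression (n = %d): trap_index = %.4g + %.4g",
                     " * chem_value\nR2 = %.4f, F(%d,%d) = %.4g, p = %.4g\n"),
              x$n, x$intercept, x$slope, x$r2, x$df[1], x$df[2],
              x$f_stat, x$p_value))
  invisible(x)
}
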