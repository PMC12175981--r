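#' Zero-intercept least squares with spreadsheet conventions
#'
#' Fits y = m * x through the origin: m = sum(x*y) / sum(x^2). The ancillary
#' statistics follow the convention of spreadsheet least-squares fits with
#' the intercept suppressed: residual degrees of freedom n - 1 (one estimated
#' parameter), se_m = sqrt((sum(e^2) / (n - 1)) / sum(x^2)), and the
#' *uncentered* coefficient of determination r2 = 1 - sum(e^2) / sum(y^2).
#'
#' @param y numeric regressand (blind product's panel proportions).
#' @param x numeric regressor (benchmark product's panel proportions), same
#'   length, n >= 2, not all zero.
#' @return an `origin_fit` list: `m`, `se_m`, `r2`, `n`, and `degenerate_y`
#'   (TRUE when y is all zeros, in which case m = 0 and r2 = 0 by
#'   convention).
#' @examples
#' origin_least_squares(c(1, 2, 4), c(1, 2, 3))
#' @export
origin_least_squares <- function(y, x) {
  stopifnot(is.numeric(x), is.numeric(y), length(x) == length(y))
  n <- length(x)
  if (n < 2L) stop("origin_least_squares needs n >= 2")
  if (any(!is.finite(x)) || any(!is.finite(y))) stop("non-finite input")
  # x * x rather than x^2: guarantees m == 1 bit-exactly when y is x
  sxx <- sum(x * x)
  if (sxx == 0) stop("regressor x is all zeros: no-intercept fit undefined")
  syy <- sum(y * y)
  if (syy == 0) {
    return(structure(list(m = 0, se_m = 0, r2 = 0, n = n, degenerate_y = TRUE),
                     class = "origin_fit"))
  }
  m <- sum(x * y) / sxx
  e <- y - m * x
  sse <- sum(e^2)
  se_m <- sqrt((sse / (n - 1)) / sxx)
  r2 <- 1 - sse / syy
  structure(list(m = m, se_m = se_m, r2 = r2, n = n, degenerate_y = FALSE),
            class = "origin_fit")
}

#' @export
print.origin_fit <- function(x, ...) {
  cat(sprintf("origin fit (n = %d): m = %.6g, se_m = %.6g, r2 = %.6g\n",
              x$n, x$m, x$se_m, x$r2))
  if (isTRUE(x$degenerate_y)) cat("note: y all zeros; m = 0 and r2 = 0 by convention\n")
  invisible(x)
}

#' Chem-index: compositional similarity of a blind product to a benchmark
#'
#' The similarity score is built from the zero-intercept fit of the blind
#' product's panel proportions (y) on the benchmark's (x):
#' \deqn{chem = |m - 1| + |R^2 - 1| + se_m}
#' Each term penalizes one departure from identity: slope away from 1
#' (systematic scaling), uncentered R-squared below 1 (scatter around the
#' line), and slope standard error (noise in the proportionality). The index
#' is 0 exactly when the two profiles are identical.
#'
#' @param y blind product's panel proportions.
#' @param x benchmark product's panel proportions.
#' @return non-negative numeric similarity index (0 = identical).
#' @examples
#' chem_index(c(2, 4, 6), c(1, 2, 3))  # pure doubling: |2 - 1| = 1
#' @export
chem_index <- function(y, x) {
  fit <- origin_least_squares(y, x)
  abs(fit$m - 1) + abs(fit$r2 - 1) + fit$se_m
}

#' Build a chem-index attractiveness model
#'
#' Bundles the key-odorant panel, the benchmark products' panel proportions,
#' and the benchmarks' attractiveness ranks into the object used to score
#' unknown (blind) products.
#'
#' @param benchmarks a [profile_matrix()] of the ranked benchmark products.
#' @param ranking an `attractiveness_ranking` covering exactly the benchmark
#'   products.
#' @param panel character vector of key odorant names (or a
#'   `biomarker_panel`, whose `$panel` is used).
#' @return a `chem_index_model` list: `panel`, `benchmarks` (benchmarks
#'   aligned to the panel), `benchmark_ranks` (named integer vector), and
#'   `n_benchmarks`.
#' @export
chem_index_model <- function(benchmarks, ranking, panel) {
  if (inherits(panel, "biomarker_panel")) panel <- panel$panel
  panel <- clean_name(panel)
  stopifnot(inherits(benchmarks, "profile_matrix"),
            inherits(ranking, "attractiveness_ranking"))
  match_ranking_products(benchmarks, ranking)  # errors on mismatch
  aligned <- align_panel(benchmarks, panel)
  if (length(attr(aligned, "zero_filled"))) {
    warning("panel compound(s) absent from benchmarks, zero-filled: ",
            paste(attr(aligned, "zero_filled"), collapse = ", "))
  }
  ranks <- stats::setNames(ranking$rank, ranking$product_id)[products(benchmarks)]
  structure(list(panel = panel, benchmarks = aligned,
                 benchmark_ranks = ranks, n_benchmarks = nrow(aligned)),
            class = "chem_index_model")
}

#' @export
print.chem_index_model <- function(x, ...) {
  cat("chem_index_model: ", x$n_benchmarks, " benchmarks x ",
      length(x$panel), " panel odorants\n", sep = "")
  print(data.frame(benchmark = names(x$benchmark_ranks),
                   rank = unname(x$benchmark_ranks)), row.names = FALSE)
  invisible(x)
}

#' Estimate the attractiveness rank of a blind product
#'
#' Computes the chem-index of the blind product against every benchmark and
#' assigns the rank of the most similar (minimal-index) benchmark. Ties in
#' the minimum are resolved toward the more attractive (smaller) rank and
#' flagged.
#'
#' @param blind either a named numeric vector of panel proportions, a
#'   one-row [profile_matrix()], or a [profile_matrix()] row selected by
#'   `blind_id`; compounds are aligned to the model panel (missing panel
#'   compounds read as 0).
#' @param model a [chem_index_model()].
#' @param blind_id optional product id when `blind` is a multi-row matrix.
#' @return a `chem_index_result` list: `blind_id`, `per_benchmark` (a
#'   data.frame of benchmark, rank, m, se_m, r2, chem_index), `best_benchmark`,
#'   `chem_index` (the minimal value), `estimated_rank`, and `tie` (TRUE if
#'   the argmin was tied).
#' @export
estimate_rank <- function(blind, model, blind_id = NULL) {
  stopifnot(inherits(model, "chem_index_model"))
  if (inherits(blind, "profile_matrix")) {
    if (is.null(blind_id)) {
      if (nrow(blind) != 1L) stop("give blind_id when blind has several rows")
      blind_id <- products(blind)
    }
    aligned <- align_panel(blind, model$panel)
    y <- unclass(aligned)[clean_name(blind_id), ]
  } else {
    if (is.null(names(blind))) {
      if (length(blind) != length(model$panel)) {
        stop("unnamed blind vector must have length ", length(model$panel))
      }
      y <- as.numeric(blind)
    } else {
      names(blind) <- clean_name(names(blind))
      y <- ifelse(model$panel %in% names(blind), blind[model$panel], 0)
      y <- as.numeric(y)
    }
    if (is.null(blind_id)) blind_id <- "blind"
  }
  bm <- unclass(model$benchmarks)
  per <- lapply(rownames(bm), function(b) {
    fit <- origin_least_squares(y, bm[b, ])
    data.frame(benchmark = b, rank = unname(model$benchmark_ranks[b]),
               m = fit$m, se_m = fit$se_m, r2 = fit$r2,
               chem_index = abs(fit$m - 1) + abs(fit$r2 - 1) + fit$se_m)
  })
  per <- do.call(rbind, per)
  best_val <- min(per$chem_index)
  hits <- per[per$chem_index == best_val, , drop = FALSE]
  tie <- nrow(hits) > 1L
  best <- hits[which.min(hits$rank), , drop = FALSE]
  structure(list(blind_id = blind_id, per_benchmark = per,
                 best_benchmark = best$benchmark, chem_index = best_val,
                 estimated_rank = best$rank, tie = tie),
            class = "chem_index_result")
}

#' @export
print.chem_index_result <- function(x, ...) {
  cat("chem_index_result for '", x$blind_id, "': chem-index ",
      format(x$chem_index, digits = 5), ", estimated rank ", x$estimated_rank,
      " (benchmark ", x$best_benchmark, if (x$tie) ", tie resolved toward better rank" else "",
      ")\n", sep = "")
  print(x$per_benchmark[order(x$per_benchmark$chem_index), ], row.names = FALSE)
  invisible(x)
}
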