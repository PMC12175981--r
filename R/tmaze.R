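#' Validate a table of two-choice T-maze trials
#'
#' A trials table has one row per two-choice trial: `round_id`, the two arm
#' samples `sample_a` / `sample_b`, the counts of flies choosing each arm
#' (`n_a`, `n_b`), the non-responders (`n_none`), and optionally `calibrator`,
#' the product anchoring that round (NA elsewhere).
#'
#' @param trials data.frame with the columns above (`n_none` and `calibrator`
#'   optional; they default to 0 and NA).
#' @return the validated data.frame with normalized names.
#' @export
as_choice_trials <- function(trials) {
  trials <- as.data.frame(trials)
  names(trials) <- clean_name(names(trials))
  need <- c("round_id", "sample_a", "sample_b", "n_a", "n_b")
  if (!all(need %in% names(trials))) {
    stop("trials table needs columns: ", paste(need, collapse = ", "))
  }
  if (!"n_none" %in% names(trials)) trials$n_none <- 0L
  if (!"calibrator" %in% names(trials)) trials$calibrator <- NA_character_
  for (col in c("sample_a", "sample_b")) trials[[col]] <- clean_name(trials[[col]])
  trials$calibrator <- ifelse(is.na(trials$calibrator) | trials$calibrator == "",
                              NA_character_, clean_name(trials$calibrator))
  counts <- as.matrix(trials[c("n_a", "n_b", "n_none")])
  if (any(!is.finite(counts)) || any(counts < 0) || any(counts != round(counts))) {
    stop("trial counts must be non-negative integers")
  }
  if (any(same <- trials$sample_a == trials$sample_b)) {
    stop("sample_a equals sample_b in trial row(s) ", paste(which(same), collapse = ", "))
  }
  trials
}

#' Choosing ratio of a two-choice trial
#'
#' The fraction of flies selecting each arm. With `denominator =
#' "responders"` (default) non-responding flies are excluded, so the two
#' ratios sum to 1; with `"all"` they are retained in the denominator, so the
#' ratios sum to at most 1. Responders is the default because participation
#' in these assays is typically low and no-choice flies would otherwise
#' dominate the ratio.
#'
#' @param trials a trials table (see [as_choice_trials()]); vectorized over
#'   rows.
#' @param denominator `"responders"` or `"all"`.
#' @return data.frame with columns `ratio_a`, `ratio_b`.
#' @examples
#' choosing_ratio(data.frame(round_id = 1, sample_a = "A", sample_b = "B",
#'                           n_a = 30, n_b = 10, n_none = 10))
#' @export
choosing_ratio <- function(trials, denominator = c("responders", "all")) {
  denominator <- match.arg(denominator)
  trials <- as_choice_trials(trials)
  den <- if (denominator == "responders") trials$n_a + trials$n_b else
    trials$n_a + trials$n_b + trials$n_none
  if (any(den == 0)) {
    bad <- which(den == 0)[1]
    stop("zero ", denominator, " denominator in trial row ", bad, " (",
         trials$sample_a[bad], " vs ", trials$sample_b[bad], ", round ",
         trials$round_id[bad], ")")
  }
  data.frame(ratio_a = trials$n_a / den, ratio_b = trials$n_b / den)
}

# build an attractiveness_ranking from per-product mean choosing ratios
rank_from_means <- function(means) {
  ids <- names(means)
  ord <- order(-means, ids)  # descending mean, lexicographic tie-break
  ranked <- data.frame(product_id = ids[ord],
                       rank = seq_along(ord),
                       mean_choosing_ratio = unname(means[ord]))
  n <- nrow(ranked)
  ranked$attractiveness_score <- n + 1 - ranked$rank
  ties <- ranked$product_id[duplicated(ranked$mean_choosing_ratio) |
                              duplicated(ranked$mean_choosing_ratio, fromLast = TRUE)]
  structure(ranked, class = c("attractiveness_ranking", "data.frame"),
            ties = ties)
}

#' Rank products by T-maze attractiveness
#'
#' Converts two-choice trial counts into a full attractiveness ranking.
#' Rank 1 is the most attractive product; the numeric response variable used
#' downstream is `attractiveness_score = n + 1 - rank`, so that compounds
#' enriched in attractive products correlate *positively* with it.
#'
#' Two aggregation modes:
#' \describe{
#'   \item{pooled}{each product's mean choosing ratio is averaged over every
#'     trial it appears in, regardless of round; invariant to trial order.}
#'   \item{calibrator}{rounds are processed in order; each round names
#'     exactly one calibrator whose accumulated mean choosing ratio is frozen
#'     at the end of its round, after which it may not reappear. Products
#'     never serving as calibrator freeze after the final round. Ranking is
#'     by the frozen means.}
#' }
#' Ties in mean ratio are broken lexicographically by product id and listed
#' in the `"ties"` attribute.
#'
#' @param trials a trials table (see [as_choice_trials()]).
#' @param mode `"pooled"` (default) or `"calibrator"`.
#' @param denominator passed to [choosing_ratio()].
#' @return an `attractiveness_ranking`: a data.frame with columns
#'   `product_id`, `rank`, `mean_choosing_ratio`, `attractiveness_score`,
#'   sorted by rank.
#' @export
rank_products <- function(trials, mode = c("pooled", "calibrator"),
                          denominator = c("responders", "all")) {
  mode <- match.arg(mode)
  trials <- as_choice_trials(trials)
  ratios <- choosing_ratio(trials, denominator)
  long <- data.frame(
    round_id = rep(trials$round_id, 2L),
    product_id = c(trials$sample_a, trials$sample_b),
    ratio = c(ratios$ratio_a, ratios$ratio_b))
  prods <- sort(unique(long$product_id))
  if (length(prods) < 2L) stop("trials must cover at least 2 distinct products")

  if (mode == "pooled") {
    means <- tapply(long$ratio, long$product_id, mean)
    return(rank_from_means(means[prods]))
  }

  rounds <- sort(unique(trials$round_id))
  frozen <- c()
  acc <- split(long$ratio, long$product_id)  # will rebuild per round below
  acc <- stats::setNames(vector("list", length(prods)), prods)
  for (r in rounds) {
    cal <- unique(trials$calibrator[trials$round_id == r])
    cal <- cal[!is.na(cal)]
    if (length(cal) != 1L) {
      stop("round ", r, " must name exactly one calibrator (found ",
           length(cal), ")")
    }
    in_round <- long$round_id == r
    seen <- unique(long$product_id[in_round])
    gone <- intersect(seen, names(frozen))
    if (length(gone)) {
      stop("calibrator(s) ", paste(gone, collapse = ", "),
           " reappear in round ", r, " after exclusion")
    }
    for (p in seen) acc[[p]] <- c(acc[[p]], long$ratio[in_round & long$product_id == p])
    if (!cal %in% seen) stop("calibrator ", cal, " has no trial in round ", r)
    frozen[cal] <- mean(acc[[cal]])
  }
  rest <- setdiff(prods, names(frozen))
  for (p in rest) {
    if (length(acc[[p]]) == 0L) {
      warning("product ", p, " has no trials; excluded from ranking")
      next
    }
    frozen[p] <- mean(acc[[p]])
  }
  rank_from_means(frozen)
}

#' @export
print.attractiveness_ranking <- function(x, ...) {
  cat("attractiveness_ranking (rank 1 = most attractive)\n")
  print(as.data.frame(x), row.names = FALSE, ...)
  ties <- attr(x, "ties")
  if (length(ties)) {
    cat("ties broken lexicographically among:", paste(ties, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Attractiveness scores as a named vector
#'
#' @param ranking an `attractiveness_ranking`.
#' @return named numeric vector, `product_id` -> `attractiveness_score`
#'   (`n + 1 - rank`).
#' @export
attractiveness_scores <- function(ranking) {
  stopifnot(inherits(ranking, "attractiveness_ranking"))
  stats::setNames(ranking$attractiveness_score, ranking$product_id)
}
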