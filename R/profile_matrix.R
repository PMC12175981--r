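#' Construct a volatile profile matrix
#'
#' A `profile_matrix` holds one row per product and one column per identified
#' volatile compound; cells are proportions, i.e. each compound's peak area as
#' a percentage of the product's total peak area (0-100 scale).
#'
#' @param values numeric matrix (or object coercible to one) with product ids
#'   as row names and compound names as column names.
#' @return a `profile_matrix`: a numeric matrix with class attribute
#'   `"profile_matrix"`, validated for finite non-negative cells and unique,
#'   non-empty dimnames.
#' @examples
#' m <- profile_matrix(matrix(c(60, 40, 30, 70), 2, 2,
#'   dimnames = list(c("P1", "P2"), c("ethanol", "ethyl acetate"))))
#' products(m)
#' compounds(m)
#' @export
profile_matrix <- function(values) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("profile_matrix needs product ids as row names and compound names as column names")
  }
  rownames(values) <- clean_name(rownames(values))
  colnames(values) <- clean_name(colnames(values))
  validate_profile_matrix(values)
  structure(values, class = c("profile_matrix", class(values)))
}

# shared name normalization: exact match after whitespace trim + case fold
clean_name <- function(x) tolower(trimws(as.character(x)))

validate_profile_matrix <- function(values) {
  if (anyDuplicated(rownames(values))) {
    stop("duplicate product_ids: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]), collapse = ", "))
  }
  if (anyDuplicated(colnames(values))) {
    stop("duplicate compound names: ",
         paste(unique(colnames(values)[duplicated(colnames(values))]), collapse = ", "))
  }
  if (any(!is.finite(values))) {
    bad <- which(!is.finite(values), arr.ind = TRUE)[1, ]
    stop("non-finite proportion for product '", rownames(values)[bad[1]],
         "', compound '", colnames(values)[bad[2]], "'")
  }
  if (any(values < 0)) {
    bad <- which(values < 0, arr.ind = TRUE)[1, ]
    stop("negative proportion for product '", rownames(values)[bad[1]],
         "', compound '", colnames(values)[bad[2]], "'")
  }
  invisible(values)
}

#' @rdname profile_matrix
#' @param m a `profile_matrix`.
#' @export
products <- function(m) rownames(m)

#' @rdname profile_matrix
#' @export
compounds <- function(m) colnames(m)

#' @export
print.profile_matrix <- function(x, ...) {
  cat("profile_matrix: ", nrow(x), " products x ", ncol(x), " compounds\n", sep = "")
  cat("row sums: ", paste(format(round(rowSums(x), 2)), collapse = ", "), "\n", sep = "")
  nshow <- min(ncol(x), 6L)
  print(unclass(x)[, seq_len(nshow), drop = FALSE], ...)
  if (ncol(x) > nshow) cat("... ", ncol(x) - nshow, " more compounds\n", sep = "")
  invisible(x)
}

#' Read a volatile profile table
#'
#' Reads a delimited text table of peak-area proportions into a
#' [profile_matrix()]. Two dialects are supported: `wide` (first column the
#' product id, one column per compound) and `long` (columns `product_id`,
#' `compound`, `proportion`). The delimiter is auto-detected from the file
#' extension (`.csv` = comma, anything else = tab).
#'
#' Compound/product names are matched exactly after whitespace trimming and
#' case folding; a compound not listed for a product in the long dialect is
#' recorded as 0% (undetected), because proportions-of-total make "absent"
#' and "zero" the same statement.
#'
#' @param source path to a delimited text file, or a connection.
#' @param dialect `"wide"` or `"long"`.
#' @param sep field separator; `NULL` (default) auto-detects from the file
#'   extension.
#' @return a [profile_matrix()].
#' @export
read_profile_table <- function(source, dialect = c("wide", "long"), sep = NULL) {
  dialect <- match.arg(dialect)
  if (is.null(sep)) {
    sep <- if (is.character(source) && grepl("\\.csv$", source, ignore.case = TRUE)) "," else "\t"
  }
  df <- utils::read.table(source, header = TRUE, sep = sep, quote = "\"",
                          check.names = FALSE, stringsAsFactors = FALSE,
                          comment.char = "", fileEncoding = "UTF-8")
  if (dialect == "wide") {
    if (ncol(df) < 2L) stop("wide table needs a product_id column plus at least one compound")
    ids <- clean_name(df[[1]])
    vals <- as.matrix(df[, -1, drop = FALSE])
    if (!is.numeric(vals)) {
      bad <- which(!vapply(df[-1], is.numeric, logical(1)))[1]
      stop("non-numeric proportion column '", names(df)[-1][bad], "'")
    }
    rownames(vals) <- ids
    return(profile_matrix(vals))
  }
  need <- c("product_id", "compound", "proportion")
  names(df) <- clean_name(names(df))
  if (!all(need %in% names(df))) {
    stop("long table needs columns: ", paste(need, collapse = ", "))
  }
  df$product_id <- clean_name(df$product_id)
  df$compound <- clean_name(df$compound)
  if (!is.numeric(df$proportion)) stop("proportion column is not numeric")
  if (any(neg <- df$proportion < 0)) {
    stop("negative proportion in row(s) ", paste(which(neg), collapse = ", "),
         " (product ", paste(unique(df$product_id[neg]), collapse = ", "), ")")
  }
  key <- paste(df$product_id, df$compound, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- which(duplicated(key))[1]
    stop("duplicate (product, compound) cell in row ", dup, ": ",
         df$product_id[dup], " / ", df$compound[dup])
  }
  prods <- unique(df$product_id)
  comps <- unique(df$compound)
  vals <- matrix(0, length(prods), length(comps), dimnames = list(prods, comps))
  vals[cbind(match(df$product_id, prods), match(df$compound, comps))] <- df$proportion
  profile_matrix(vals)
}

#' Write a volatile profile table
#'
#' Inverse of [read_profile_table()]: serializes a [profile_matrix()] back to
#' delimited text so that read -> write -> read round-trips.
#'
#' @param m a [profile_matrix()].
#' @param path output file path; `.csv` writes comma-separated, otherwise TSV.
#' @param dialect `"wide"` or `"long"`; long drops zero cells (the fill rule
#'   restores them on read).
#' @return `path`, invisibly.
#' @export
write_profile_table <- function(m, path, dialect = c("wide", "long")) {
  dialect <- match.arg(dialect)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  if (dialect == "wide") {
    df <- data.frame(product_id = products(m), unclass(m),
                     check.names = FALSE, row.names = NULL)
  } else {
    idx <- which(unclass(m) != 0, arr.ind = TRUE)
    df <- data.frame(product_id = products(m)[idx[, 1]],
                     compound = compounds(m)[idx[, 2]],
                     proportion = m[idx], row.names = NULL)
    df <- df[order(match(df$product_id, products(m)),
                   match(df$compound, compounds(m))), , drop = FALSE]
  }
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Renormalize each product row to 100%
#'
#' Enforces the proportion-of-total convention: every product's compound
#' proportions are rescaled to sum to 100, leaving relative composition
#' untouched. Idempotent. Whether the 100% denominator covers all detected
#' peaks or only identified compounds is a property of the upstream table;
#' call this only when the supplied compounds are meant to be exhaustive.
#'
#' @param m a [profile_matrix()].
#' @return a [profile_matrix()] whose rows each sum to 100.
#' @export
normalize_proportions <- function(m) {
  stopifnot(inherits(m, "profile_matrix"))
  rs <- rowSums(m)
  if (any(rs <= 0)) {
    stop("all-zero proportion row for product(s): ",
         paste(products(m)[rs <= 0], collapse = ", "))
  }
  out <- unclass(m) * (100 / rs)
  profile_matrix(out)
}

#' Restrict a profile matrix to a compound panel
#'
#' Projects `m` onto `panel`, in panel order. Panel compounds missing from
#' `m` are zero-filled (undetected) and reported via the `"zero_filled"`
#' attribute rather than raising an error, so a model panel can be applied
#' to any blind product table.
#'
#' @param m a [profile_matrix()].
#' @param panel character vector of compound names (ordered; matching is
#'   whitespace/case-insensitive).
#' @return a [profile_matrix()] with columns `panel`; attribute
#'   `"zero_filled"` lists the panel compounds absent from `m`.
#' @export
align_panel <- function(m, panel) {
  stopifnot(inherits(m, "profile_matrix"))
  panel <- clean_name(panel)
  if (length(panel) == 0L) stop("panel is empty")
  if (anyDuplicated(panel)) stop("panel has duplicate compounds")
  hit <- match(panel, compounds(m))
  out <- matrix(0, nrow(m), length(panel), dimnames = list(products(m), panel))
  out[, !is.na(hit)] <- unclass(m)[, hit[!is.na(hit)], drop = FALSE]
  res <- profile_matrix(out)
  attr(res, "zero_filled") <- panel[is.na(hit)]
  res
}
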