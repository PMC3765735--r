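#' Validate an expression table
#'
#' Expression tables are plain tibbles: a `feature_id` character column
#' followed by one numeric column per library. All downstream functions use
#' this layout, so validation is strict: unique feature ids, no missing
#' values, no negative measurements, and (for count layers) integer values.
#'
#' @param x A data frame in feature-by-library layout.
#' @param integer If `TRUE`, require all measurement columns to hold
#'   non-negative integers (count layers).
#' @return `x` as a validated tibble (invisibly usable in pipes).
#' @export
validate_expression <- function(x, integer = FALSE) {
  x <- tibble::as_tibble(x)
  if (ncol(x) < 2L) abort("expression table needs a feature id column plus at least one library column")
  names(x)[1] <- "feature_id"
  x$feature_id <- as.character(x$feature_id)
  if (anyDuplicated(x$feature_id)) {
    dup <- x$feature_id[duplicated(x$feature_id)][1]
    abort(paste0("duplicate feature id: ", dup))
  }
  vals <- x[-1]
  if (!all(vapply(vals, is.numeric, logical(1)))) abort("library columns must be numeric")
  if (anyNA(vals)) abort("missing values in expression table")
  m <- as.matrix(vals)
  if (any(m < 0)) abort("negative values in expression table")
  if (integer && any(m != round(m))) abort("count layer contains non-integer values")
  x
}

#' @rdname validate_expression
#' @export
library_ids <- function(x) names(x)[-1]

# feature-by-library numeric matrix with feature_id rownames
expr_values <- function(x) {
  m <- as.matrix(x[-1])
  rownames(m) <- x[[1]]
  m
}

expr_tibble <- function(m, feature_ids = rownames(m)) {
  out <- tibble::as_tibble(as.data.frame(m))
  tibble::add_column(out, feature_id = feature_ids, .before = 1)
}

#' Read and write expression tables
#'
#' Tab-separated text with a header of library ids and feature ids in the
#' first column. Parsing is strict: ragged rows, duplicate ids, missing or
#' negative values are all errors that name the offending line or feature.
#'
#' @param path File path.
#' @param integer Require integer counts (see [validate_expression()]).
#' @return A validated expression tibble.
#' @export
read_expression_matrix <- function(path, integer = FALSE) {
  x <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                       progress = FALSE)
  pb <- readr::problems(x)
  if (nrow(pb) > 0) {
    abort(paste0("parse error in ", path, " at line ", pb$row[1] + 1L, ": ", pb$expected[1]))
  }
  for (j in seq_along(x)[-1]) {
    v <- suppressWarnings(as.numeric(x[[j]]))
    bad <- which(is.na(v) | is.na(x[[j]]))
    if (length(bad) > 0) {
      abort(paste0("parse error in ", path, " at line ", bad[1] + 1L,
                   ": non-numeric or missing value in column ", names(x)[j]))
    }
    x[[j]] <- v
  }
  validate_expression(x, integer = integer)
}

#' @rdname read_expression_matrix
#' @param x A validated expression tibble.
#' @export
write_expression_matrix <- function(x, path) {
  x <- validate_expression(x)
  readr::write_tsv(x, path, progress = FALSE)
  invisible(path)
}

#' Per-million normalization
#'
#' Scales each library column so that its total equals one million, the
#' standard depth normalization for un-replicated tag libraries. Columns
#' with zero totals are an error (an empty library carries no information).
#'
#' @param x Expression tibble (feature id column + library columns).
#' @return Tibble of the same shape with per-million values.
#' @export
normalize_per_million <- function(x) {
  x <- validate_expression(x)
  m <- expr_values(x)
  tot <- colSums(m)
  if (any(tot <= 0)) {
    abort(paste0("library with zero total: ", colnames(m)[tot <= 0][1]))
  }
  expr_tibble(sweep(m, 2, tot, "/") * 1e6)
}

# per-library median scaling for intensity layers (proteins): each column is
# divided by its median over detected (positive) features and re-centred on
# the global median, then values enter correlations as log2(x + 1)
median_scale <- function(x) {
  x <- validate_expression(x)
  m <- expr_values(x)
  med <- apply(m, 2, function(v) median(v[v > 0]))
  if (anyNA(med)) abort("library with no detected features cannot be median-scaled")
  expr_tibble(sweep(m, 2, med, "/") * exp(mean(log(med))))
}
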