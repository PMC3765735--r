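#' Round half away from zero
#'
#' Plain decimal rounding (0.005 -> 0.01), matching how percentages are
#' conventionally printed in assembly and annotation reports, unlike base
#' R's round-half-even.
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Rounded vector.
#' @export
round_half_up <- function(x, digits = 0) {
  s <- 10^digits
  sign(x) * floor(abs(x) * s + 0.5) / s
}

#' Summary statistics of a length table
#'
#' Count, total length, mean length (rounded to the nearest bp), N50 (the
#' length at which the cumulative sum of lengths sorted in descending order
#' first reaches half the total), and optionally the percentage of features
#' within a length window (2 decimals).
#'
#' @param lengths Positive integer vector of feature lengths (bp), or a
#'   two-column table (feature id, length).
#' @param window Optional `c(lo, hi)` length window (inclusive).
#' @return One-row tibble: `n`, `total_bp`, `mean_bp`, `n50_bp` and, with a
#'   window, `window_share_pct`.
#' @export
summarize_lengths <- function(lengths, window = NULL) {
  if (is.data.frame(lengths)) lengths <- lengths[[2]]
  if (length(lengths) == 0) abort("empty length table")
  if (any(lengths <= 0) || any(lengths != round(lengths))) {
    abort("lengths must be positive integers")
  }
  total <- sum(lengths)
  srt <- sort(lengths, decreasing = TRUE)
  n50 <- srt[which(cumsum(srt) >= total / 2)[1]]
  out <- tibble::tibble(
    n = length(lengths), total_bp = total,
    mean_bp = round_half_up(total / length(lengths)),
    n50_bp = n50)
  if (!is.null(window)) {
    out$window_share_pct <- round_half_up(
      100 * sum(lengths >= window[1] & lengths <= window[2]) / length(lengths), 2)
  }
  out
}

#' Mean feature length from printed totals
#'
#' Report arithmetic for published summary tables: total length divided by
#' feature count, rounded to the nearest bp.
#'
#' @param total_bp Total length in bp.
#' @param n Feature count.
#' @return Mean length in bp (integer-valued).
#' @export
mean_length_bp <- function(total_bp, n) {
  if (n <= 0) abort("feature count must be positive")
  round_half_up(total_bp / n)
}

#' Percentage share per category
#'
#' `100 * count / total` rounded half up to 2 decimals; after rounding the
#' shares sum to 100 within 0.05.
#'
#' @param counts Non-negative (optionally named) count vector with a
#'   positive total.
#' @return Tibble with `category`, `count`, `share_pct`.
#' @export
category_share <- function(counts) {
  if (any(counts < 0)) abort("counts must be non-negative")
  total <- sum(counts)
  if (total <= 0) abort("zero total")
  tibble::tibble(
    category = names(counts) %||% as.character(seq_along(counts)),
    count = as.vector(counts),
    share_pct = unname(round_half_up(100 * counts / total, 2)))
}
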