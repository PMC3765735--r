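#' Differential-expression thresholds
#'
#' The gates used to call a feature differentially expressed between two
#' libraries: raw p-value at most `p_max`, Benjamini-Hochberg q-value at
#' most `fdr_max`, and absolute log2 fold change at least `min_abs_log2fc`.
#' Fold changes are computed on per-million values with `pseudocount` added
#' to both sides so that zero counts give finite ratios.
#'
#' @param p_max,fdr_max,min_abs_log2fc,pseudocount Positive scalars.
#' @return A list of class `de_thresholds`.
#' @export
de_thresholds <- function(p_max = 0.01, fdr_max = 0.001, min_abs_log2fc = 1,
                          pseudocount = 1) {
  stopifnot(p_max > 0, fdr_max > 0, min_abs_log2fc > 0, pseudocount > 0)
  structure(list(p_max = p_max, fdr_max = fdr_max,
                 min_abs_log2fc = min_abs_log2fc, pseudocount = pseudocount),
            class = "de_thresholds")
}

#' Exact conditional test for two tag counts
#'
#' Compares counts `x` (library of size `n1`) and `y` (library of size `n2`)
#' under the null hypothesis that the feature has the same relative
#' abundance in both libraries. Conditional on the observed total
#' `t = x + y`, the second count follows Binomial(t, n2/(n1+n2)); the
#' two-sided p-value sums the probability of every outcome whose conditional
#' probability does not exceed that of the observed split. The computation
#' works on log probabilities throughout and is stable for totals well
#' beyond 10^6. The test is exactly symmetric under swapping the libraries.
#'
#' @param x,y Non-negative integer counts (vectorized).
#' @param n1,n2 Positive library totals (clean tag counts).
#' @return Vector of two-sided p-values in (0, 1].
#' @export
exact_tag_test <- function(x, y, n1, n2) {
  k <- max(length(x), length(y), length(n1), length(n2))
  x <- rep_len(x, k); y <- rep_len(y, k)
  n1 <- rep_len(n1, k); n2 <- rep_len(n2, k)
  if (any(x < 0 | y < 0)) abort("counts must be non-negative")
  if (any(x != round(x) | y != round(y))) abort("counts must be integers")
  if (any(n1 <= 0 | n2 <= 0)) abort("library sizes must be positive")
  vapply(seq_len(k), function(i) {
    .exact_tag_one(x[i], y[i], n1[i], n2[i])
  }, numeric(1))
}

# minlike two-sided tail of Binomial(t, pr); the density is unimodal in y,
# so the acceptance set {y': P(y') > P(y)} is a contiguous interval around
# the mode found by binary search on each flank
.exact_tag_one <- function(x, y, n1, n2) {
  t <- x + y
  if (t == 0) return(1)
  pr <- n2 / (n1 + n2)
  ld0 <- dbinom(y, t, pr, log = TRUE)
  mode <- floor((t + 1) * pr)
  relfuzz <- 1e-7
  lcut <- ld0 + log1p(relfuzz)
  if (dbinom(mode, t, pr, log = TRUE) <= lcut) return(1)
  if (y < mode) {
    # right flank: densities decrease for y' >= mode; find smallest such
    # y' with log density <= lcut
    lo <- mode; hi <- t
    if (dbinom(t, t, pr, log = TRUE) > lcut) {
      b <- t + 1L
    } else {
      while (hi - lo > 1L) {
        mid <- (lo + hi) %/% 2L
        if (dbinom(mid, t, pr, log = TRUE) <= lcut) hi <- mid else lo <- mid
      }
      b <- hi
    }
    p <- pbinom(y, t, pr) + pbinom(b - 1, t, pr, lower.tail = FALSE)
  } else {
    # left flank: densities increase for y' <= mode; find largest y' with
    # log density <= lcut
    lo <- 0L; hi <- mode
    if (dbinom(0L, t, pr, log = TRUE) > lcut) {
      a <- -1L
    } else {
      while (hi - lo > 1L) {
        mid <- (lo + hi) %/% 2L
        if (dbinom(mid, t, pr, log = TRUE) <= lcut) lo <- mid else hi <- mid
      }
      a <- lo
    }
    p <- pbinom(y - 1, t, pr, lower.tail = FALSE) + (if (a >= 0) pbinom(a, t, pr) else 0)
  }
  min(1, p)
}

#' Benjamini-Hochberg q-values
#'
#' Step-up false-discovery-rate adjustment. A thin validated wrapper around
#' [stats::p.adjust()] so that every stage shares one entry point.
#'
#' @param p Vector of p-values in \[0, 1\].
#' @return q-values of the same length and order.
#' @export
bh_fdr <- function(p) {
  if (length(p) == 0) return(numeric(0))
  if (anyNA(p) || any(p < 0 | p > 1)) abort("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Pairwise differential-expression calls
#'
#' Runs the exact conditional tag test for every requested pair of
#' libraries (all 15 unordered pairs by default for six libraries), adjusts
#' p-values per comparison with Benjamini-Hochberg, computes log2 fold
#' changes on per-million values with a pseudocount, and applies the
#' thresholds. Features with zero counts in both members of a pair are
#' excluded from that pair's testing universe (their fold change is
#' undefined and the test carries no information).
#'
#' @param counts Count expression tibble (feature id + library columns).
#' @param thresholds A [de_thresholds()] object.
#' @param pairs Optional two-column matrix or data frame of library id
#'   pairs; defaults to all unordered pairs in column order.
#' @return A tibble of class `culm_de` with one row per feature and pair:
#'   `lib_a`, `lib_b`, `feature_id`, `x`, `y`, `tpm_a`, `tpm_b`, `log2fc`,
#'   `p_value`, `q_value`, `de_call` (`"up"`, `"down"`, `"none"`; up means
#'   higher in `lib_b`).
#' @export
call_de <- function(counts, thresholds = de_thresholds(), pairs = NULL) {
  counts <- validate_expression(counts, integer = TRUE)
  libs <- library_ids(counts)
  if (is.null(pairs)) {
    pairs <- t(combn(libs, 2))
  }
  pairs <- as.matrix(pairs)
  if (!all(pairs %in% libs)) {
    abort(paste0("unknown library id: ", setdiff(as.vector(pairs), libs)[1]))
  }
  m <- expr_values(counts)
  tot <- colSums(m)
  pm <- sweep(m, 2, tot, "/") * 1e6
  ps <- thresholds$pseudocount
  res <- purrr::map(seq_len(nrow(pairs)), function(i) {
    a <- pairs[i, 1]; b <- pairs[i, 2]
    x <- m[, a]; y <- m[, b]
    keep <- x + y > 0
    p <- exact_tag_test(x[keep], y[keep], tot[a], tot[b])
    lfc <- log2((pm[keep, b] + ps) / (pm[keep, a] + ps))
    q <- bh_fdr(p)
    call <- ifelse(
      p <= thresholds$p_max & q <= thresholds$fdr_max &
        abs(lfc) >= thresholds$min_abs_log2fc,
      ifelse(lfc > 0, "up", "down"), "none")
    tibble::tibble(
      lib_a = a, lib_b = b, feature_id = rownames(m)[keep],
      x = unname(x[keep]), y = unname(y[keep]),
      tpm_a = unname(pm[keep, a]), tpm_b = unname(pm[keep, b]),
      log2fc = unname(lfc), p_value = p, q_value = q, de_call = unname(call))
  })
  out <- dplyr::bind_rows(res)
  class(out) <- c("culm_de", class(out))
  out
}

#' Union of differentially expressed features
#'
#' @param de A [call_de()] result.
#' @return Character vector of features called DE in at least one pair.
#' @export
de_union <- function(de) {
  sort(unique(de$feature_id[de$de_call != "none"]))
}

#' Up/down counts per library pair
#'
#' @param de A [call_de()] result.
#' @return Tibble with `lib_a`, `lib_b`, `n_up`, `n_down`, `n_tested`.
#' @export
de_summary <- function(de) {
  de |>
    dplyr::group_by(.data$lib_a, .data$lib_b) |>
    dplyr::summarise(
      n_up = sum(.data$de_call == "up"),
      n_down = sum(.data$de_call == "down"),
      n_tested = dplyr::n(), .groups = "drop")
}

#' Sequencing saturation curve
#'
#' Subsamples a library's tags without replacement at increasing depths and
#' counts how many features are detected (count > 0) at each depth. Depths
#' are nested (a deeper subsample contains the shallower one), so the
#' realized curve is monotone non-decreasing. Deterministic under `seed`.
#'
#' @param counts Named non-negative integer vector (feature counts for one
#'   library) or a two-column tibble (feature id, count).
#' @param depths Vector of subsampling depths, each at most the column total.
#' @param seed Integer seed.
#' @return Tibble with `depth` and `n_detected`.
#' @export
saturation_curve <- function(counts, depths, seed = 1L) {
  if (is.data.frame(counts)) counts <- setNames(counts[[2]], counts[[1]])
  if (any(counts < 0) || any(counts != round(counts))) abort("counts must be non-negative integers")
  total <- sum(counts)
  depths <- as.integer(sort(unique(depths)))
  if (any(depths < 0)) abort("depths must be non-negative")
  if (any(depths > total)) abort("depth exceeds column total")
  tags <- rep.int(seq_along(counts), counts)
  perm <- withr::with_seed(seed, sample(tags))
  first_seen <- rep.int(NA_integer_, length(counts))
  idx <- !duplicated(perm)
  first_seen[perm[idx]] <- which(idx)
  n_det <- vapply(depths, function(d) sum(first_seen <= d, na.rm = TRUE), integer(1))
  tibble::tibble(depth = depths, n_detected = n_det)
}
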