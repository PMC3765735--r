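#' Pearson correlation with a two-sided p-value
#'
#' The p-value comes from `t = r * sqrt(n-2) / sqrt(1-r^2)` against the t
#' distribution with `n-2` degrees of freedom. For `|r| = 1` the statistic
#' diverges and the p-value is the limiting value 0.
#'
#' @param x,y Numeric vectors of equal length, at least 3 points, each with
#'   non-zero variance.
#' @return Tibble with one row: `r`, `p`, `n`.
#' @export
pearson_with_p <- function(x, y) {
  n <- length(x)
  if (length(y) != n) abort("series must have equal length")
  if (n < 3) abort("need at least 3 points")
  if (sd(x) == 0 || sd(y) == 0) abort("zero-variance series: correlation undefined")
  r <- cor(x, y)
  tibble::tibble(r = r, p = .cor_p(r, n), n = n)
}

.cor_p <- function(r, n) {
  r2 <- pmin(r^2, 1)
  ifelse(r2 >= 1, 0, {
    t <- abs(r) * sqrt((n - 2) / (1 - r2))
    2 * pt(t, n - 2, lower.tail = FALSE)
  })
}

#' Critical correlation magnitude
#'
#' The smallest `|r|` whose two-sided p-value reaches `alpha` for series of
#' length `n`; with six sample-matched libraries and `alpha = 0.05` this is
#' 0.811, the magnitude behind the screen threshold 0.81.
#'
#' @param n Series length (at least 3).
#' @param alpha Two-sided significance level in (0, 1).
#' @return Critical `|r|`.
#' @export
critical_r <- function(n, alpha = 0.05) {
  if (n < 3) abort("need at least 3 points")
  if (alpha <= 0 || alpha >= 1) abort("alpha must lie in (0, 1)")
  tc <- qt(1 - alpha / 2, df = n - 2)
  tc / sqrt(n - 2 + tc^2)
}

#' Correlation-screen thresholds
#'
#' Pairs pass the negative screen when `r < -r_threshold` and `p <= alpha`;
#' the positive screen mirrors it with `r > r_threshold`. Inequalities on
#' `r` are strict.
#'
#' @param r_threshold Screen magnitude in (0, 1).
#' @param alpha Correlation p-value threshold.
#' @param min_present Minimum number of libraries in which a feature must
#'   be non-zero to count as expressed.
#' @return A list of class `screen_thresholds`.
#' @export
screen_thresholds <- function(r_threshold = 0.81, alpha = 0.05, min_present = 2) {
  stopifnot(r_threshold > 0, r_threshold < 1, alpha > 0, alpha <= 1, min_present >= 0)
  structure(list(r_threshold = r_threshold, alpha = alpha,
                 min_present = min_present),
            class = "screen_thresholds")
}

# log2-transformed sample-matched value matrix for correlation screens;
# counts are per-million normalized, intensities median-scaled
.screen_values <- function(x, layer = c("count", "intensity")) {
  layer <- match.arg(layer)
  x <- validate_expression(x)
  norm <- if (layer == "count") normalize_per_million(x) else median_scale(x)
  raw <- expr_values(x)
  list(values = log2(expr_values(norm) + 1), present = rowSums(raw > 0))
}

#' Screen regulator-target pairs by sample-matched correlation
#'
#' Computes the Pearson correlation of every mapped pair across the shared
#' library columns of the two layers and flags pairs passing the screen:
#' negative (`r < -threshold`, miRNA to target mRNA) or positive
#' (`r > threshold`, mRNA to protein), both with `p <= alpha`. Values enter
#' the correlation as `log2(per-million + 1)` (counts) or
#' `log2(median-scaled intensity + 1)` (proteins). Features non-zero in
#' fewer than `min_present` libraries are treated as unexpressed and their
#' pairs are dropped; pairs referencing absent features or zero-variance
#' series are skipped with a warning.
#'
#' @param source Expression tibble of the regulator layer (miRNA counts for
#'   the negative screen, mRNA counts for the positive screen).
#' @param target Expression tibble of the target layer (mRNA counts, or
#'   protein intensities for the positive screen).
#' @param pair_map Two-column tibble (source id, target id).
#' @param type `"negative"` or `"positive"`.
#' @param thresholds A [screen_thresholds()].
#' @return Tibble of class `culm_pairs`: `source_id`, `target_id`, `r`,
#'   `p`, `type`, `passes_screen`.
#' @export
screen_pairs <- function(source, target, pair_map,
                         type = c("negative", "positive"),
                         thresholds = screen_thresholds()) {
  type <- match.arg(type)
  target_layer <- if (type == "positive") "intensity" else "count"
  sv <- .screen_values(source, "count")
  tv <- .screen_values(target, target_layer)
  shared <- intersect(colnames(sv$values), colnames(tv$values))
  if (length(shared) < 3) abort("layers share fewer than 3 library columns")
  pm <- tibble::as_tibble(pair_map)
  names(pm)[1:2] <- c("source_id", "target_id")

  absent <- !(pm$source_id %in% rownames(sv$values)) |
    !(pm$target_id %in% rownames(tv$values))
  if (any(absent)) {
    warn(paste0(sum(absent), " pair(s) reference absent features; skipped"))
    pm <- pm[!absent, ]
  }
  expressed <- sv$present[pm$source_id] >= thresholds$min_present &
    tv$present[pm$target_id] >= thresholds$min_present
  pm <- pm[expressed, ]
  if (nrow(pm) == 0) {
    out <- tibble::tibble(source_id = character(), target_id = character(),
                          r = numeric(), p = numeric(), type = character(),
                          passes_screen = logical())
    class(out) <- c("culm_pairs", class(out))
    return(out)
  }
  S <- sv$values[pm$source_id, shared, drop = FALSE]
  T_ <- tv$values[pm$target_id, shared, drop = FALSE]
  degen <- apply(S, 1, sd) == 0 | apply(T_, 1, sd) == 0
  if (any(degen)) {
    warn(paste0(sum(degen), " pair(s) with zero-variance series; skipped"))
    pm <- pm[!degen, ]; S <- S[!degen, , drop = FALSE]; T_ <- T_[!degen, , drop = FALSE]
  }
  n <- length(shared)
  r <- vapply(seq_len(nrow(pm)), function(i) cor(S[i, ], T_[i, ]), numeric(1))
  p <- .cor_p(r, n)
  passes <- if (type == "negative") {
    r < -thresholds$r_threshold & p <= thresholds$alpha
  } else {
    r > thresholds$r_threshold & p <= thresholds$alpha
  }
  out <- tibble::tibble(source_id = pm$source_id, target_id = pm$target_id,
                        r = r, p = p, type = type, passes_screen = passes)
  class(out) <- c("culm_pairs", class(out))
  out
}

# one-sided (greater) Fisher's exact p for the 2x2 table
#   [a b; c d]  rows: target / non-target, cols: negative / not negative
# computed as the hypergeometric upper tail in log space
.fisher_greater <- function(a, b, c, d) {
  m <- a + b        # targets
  n2 <- c + d       # non-targets
  k <- a + c        # negatively correlated
  if (m == 0 || n2 == 0 || k == 0 || (b + d) == 0) return(1)
  hi <- min(m, k)
  ks <- seq.int(a, hi)
  lt <- lchoose(m, ks) + lchoose(n2, k - ks) - lchoose(m + n2, k)
  mx <- max(lt)
  min(1, exp(mx + log(sum(exp(lt - mx)))))
}

.fisher_twosided <- function(a, b, c, d) {
  m <- a + b; n2 <- c + d; k <- a + c
  if (m == 0 || n2 == 0 || k == 0 || (b + d) == 0) return(1)
  lo <- max(0, k - n2); hi <- min(m, k)
  ks <- seq.int(lo, hi)
  lt <- lchoose(m, ks) + lchoose(n2, k - ks) - lchoose(m + n2, k)
  l0 <- lt[ks == a] + log1p(1e-7)
  mx <- max(lt)
  min(1, sum(exp(lt - mx)[lt <= l0]) * exp(mx))
}

#' Per-miRNA enrichment of negatively correlated targets
#'
#' For one miRNA, every expressed mRNA is labelled target / non-target
#' (from the prediction map) and negatively correlated / not
#' (`r < 0` and `p <= alpha` against that miRNA); Fisher's exact test on
#' the resulting 2x2 table measures whether predicted targets are enriched
#' for negative correlation. One-sided (greater) by default, matching the
#' enrichment question; two-sided by flag.
#'
#' @param mirna,mrna Count expression tibbles sharing library columns.
#' @param target_map Two-column tibble (miRNA id, target mRNA id).
#' @param alpha Correlation p-value threshold for the negative label.
#' @param alternative `"greater"` or `"two.sided"`.
#' @param min_present Expressed filter as in [screen_pairs()].
#' @return Tibble: `mirna_id`, counts of the 2x2 table
#'   (`n_neg_target`, `n_target`, `n_neg_nontarget`, `n_nontarget`) and
#'   `p_value`. Degenerate tables (a zero margin) give p = 1 with a warning.
#' @export
mirna_target_enrichment <- function(mirna, mrna, target_map, alpha = 0.05,
                                    alternative = c("greater", "two.sided"),
                                    min_present = 2) {
  alternative <- match.arg(alternative)
  sv <- .screen_values(mirna, "count")
  tv <- .screen_values(mrna, "count")
  shared <- intersect(colnames(sv$values), colnames(tv$values))
  if (length(shared) < 3) abort("layers share fewer than 3 library columns")
  tm <- tibble::as_tibble(target_map)
  names(tm)[1:2] <- c("mirna_id", "gene_id")
  genes <- rownames(tv$values)[tv$present >= min_present]
  G <- tv$values[genes, shared, drop = FALSE]
  g_sd <- apply(G, 1, sd)
  n <- length(shared)
  mirnas <- rownames(sv$values)[sv$present >= min_present]
  res <- purrr::map(mirnas, function(mid) {
    s <- sv$values[mid, shared]
    if (sd(s) == 0) return(NULL)
    ok <- g_sd > 0
    r <- as.vector(cor(s, t(G[ok, , drop = FALSE])))
    p <- .cor_p(r, n)
    neg <- r < 0 & p <= alpha
    is_target <- genes[ok] %in% tm$gene_id[tm$mirna_id == mid]
    a <- sum(neg & is_target); b <- sum(!neg & is_target)
    cc <- sum(neg & !is_target); d <- sum(!neg & !is_target)
    pv <- if (alternative == "greater") .fisher_greater(a, b, cc, d) else .fisher_twosided(a, b, cc, d)
    tibble::tibble(mirna_id = mid, n_neg_target = a, n_target = a + b,
                   n_neg_nontarget = cc, n_nontarget = cc + d, p_value = pv)
  })
  out <- dplyr::bind_rows(res)
  if (nrow(out) > 0 &&
      any(out$n_target == 0 | out$n_nontarget == 0 |
            (out$n_neg_target + out$n_neg_nontarget) == 0)) {
    warn("degenerate 2x2 table(s): enrichment p set to 1")
  }
  out
}

#' Intersect screened pairs with significant profile membership
#'
#' Retains screened pairs whose gene belongs to a significant temporal
#' profile of the mRNA layer (and, when miRNA profile membership is
#' supplied, whose miRNA belongs to a significant miRNA profile). The gene
#' of a negative pair is its target; the gene of a positive pair is its
#' source.
#'
#' @param negative,positive [screen_pairs()] results (either may be `NULL`).
#' @param mrna_members Character vector of genes in significant mRNA
#'   profiles ([profile_members()]).
#' @param mirna_members Optional miRNA membership; when supplied, negative
#'   pairs must also have their miRNA in it.
#' @param alpha Correlation significance flag threshold for retained pairs.
#' @return An object of class `integrated_set`: list with `pairs` (tibble
#'   with `cor_significant` flag), `genes`, `mirnas_known`, `mirnas_novel`,
#'   `proteins`.
#' @export
integrate_pairs <- function(negative = NULL, positive = NULL, mrna_members,
                            mirna_members = NULL, alpha = 0.05) {
  empty <- tibble::tibble(source_id = character(), target_id = character(),
                          r = numeric(), p = numeric(), type = character(),
                          passes_screen = logical())
  neg <- if (is.null(negative)) empty else negative[negative$passes_screen, ]
  pos <- if (is.null(positive)) empty else positive[positive$passes_screen, ]
  neg <- neg[neg$target_id %in% mrna_members, ]
  if (!is.null(mirna_members)) neg <- neg[neg$source_id %in% mirna_members, ]
  pos <- pos[pos$source_id %in% mrna_members, ]
  pairs <- dplyr::bind_rows(neg, pos)
  pairs$cor_significant <- pairs$p <= alpha
  mirnas <- unique(pairs$source_id[pairs$type == "negative"])
  structure(list(
    pairs = pairs,
    genes = sort(unique(c(pairs$target_id[pairs$type == "negative"],
                          pairs$source_id[pairs$type == "positive"]))),
    mirnas_known = sort(mirnas[!startsWith(mirnas, "novel-")]),
    mirnas_novel = sort(mirnas[startsWith(mirnas, "novel-")]),
    proteins = sort(unique(pairs$target_id[pairs$type == "positive"]))),
    class = "integrated_set")
}

#' @export
print.integrated_set <- function(x, ...) {
  cat("Integrated set:", nrow(x$pairs), "pairs |", length(x$genes), "genes,",
      length(x$mirnas_known), "known +", length(x$mirnas_novel),
      "novel miRNAs,", length(x$proteins), "proteins\n")
  invisible(x)
}
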