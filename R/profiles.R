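#' Short time-series clustering configuration
#'
#' Parameters of the model-profile clustering stage: candidate profiles are
#' integer series starting at 0 whose successive changes are bounded by
#' `max_step` units; `n_models` of them are retained by greedy max-min
#' selection; profile significance is a binomial tail against the
#' permutation-expected count, with all time-point permutations enumerated
#' when the series has at most `max_exact_t` points (otherwise `n_perm`
#' sampled permutations).
#'
#' @param max_step Maximum unit change between consecutive time points.
#' @param n_models Number of model profiles retained.
#' @param alpha Significance threshold for profiles.
#' @param pseudocount Added to per-million values before log2 ratios.
#' @param max_exact_t Largest series length for exhaustive permutations.
#' @param n_perm Number of sampled permutations beyond that.
#' @return A list of class `stem_config`.
#' @export
stem_config <- function(max_step = 3, n_models = 50, alpha = 0.01,
                        pseudocount = 1, max_exact_t = 5, n_perm = 2000) {
  stopifnot(max_step >= 1, n_models >= 2, alpha > 0, alpha <= 1,
            pseudocount >= 0, n_perm >= 1)
  structure(list(max_step = max_step, n_models = n_models, alpha = alpha,
                 pseudocount = pseudocount, max_exact_t = max_exact_t,
                 n_perm = n_perm),
            class = "stem_config")
}

#' Enumerate candidate model profiles
#'
#' All integer series of length `t_points` that start at 0 and change by at
#' most `max_step` units between consecutive points: `(2*max_step+1)^(t_points-1)`
#' candidates, in lexicographic row order, including the flat profile.
#'
#' @param t_points Series length (at least 2).
#' @param max_step Maximum absolute unit change per step (at least 1).
#' @return Integer matrix, one candidate profile per row.
#' @export
enumerate_profiles <- function(t_points, max_step) {
  stopifnot(t_points >= 2, max_step >= 1)
  steps <- seq.int(-max_step, max_step)
  grid <- as.matrix(expand.grid(rep(list(steps), t_points - 1L)))
  cs <- grid
  for (j in seq_len(ncol(grid))[-1]) cs[, j] <- cs[, j - 1] + grid[, j]
  out <- cbind(0L, cs)
  out <- out[do.call(order, as.data.frame(out)), , drop = FALSE]
  dimnames(out) <- NULL
  storage.mode(out) <- "integer"
  out
}

#' Profile distance
#'
#' One minus the Pearson correlation of two series. The flat (zero
#' variance) series has no defined correlation, so the metric is completed
#' by convention: distance 0 between two flat series, 1 between a flat and
#' a non-flat series.
#'
#' @param p,q Numeric vectors of equal length.
#' @return Distance in \[0, 2\].
#' @export
profile_distance <- function(p, q) {
  if (length(p) != length(q)) abort("profiles must have equal length")
  sp <- sd(p); sq <- sd(q)
  if (sp == 0 && sq == 0) return(0)
  if (sp == 0 || sq == 0) return(1)
  1 - cor(p, q)
}

# all-pairs profile distance matrix between rows of A and rows of B,
# computed as 1 - row-standardized cross product, with the flat convention
.profile_dist_matrix <- function(A, B) {
  stdz <- function(M) {
    mu <- rowMeans(M)
    s <- sqrt(rowSums((M - mu)^2))
    list(X = (M - mu) / ifelse(s == 0, 1, s), flat = s == 0)
  }
  a <- stdz(A); b <- stdz(B)
  C <- a$X %*% t(b$X)
  C[a$flat, ] <- 0
  C[, b$flat] <- 0
  if (any(a$flat) && any(b$flat)) C[a$flat, b$flat] <- 1
  D <- 1 - C
  # clamp tiny negative rounding
  D[D < 0] <- 0
  D
}

#' Select model profiles by greedy max-min distance
#'
#' Starting from the flat profile, repeatedly adds the candidate whose
#' minimum distance ([profile_distance()]) to the already-retained set is
#' largest, until `m` profiles are retained (or all candidates, if fewer).
#' Ties are broken in favour of a candidate whose sign-flipped profile is
#' already retained (keeping the retained set mirror-symmetric, so rising
#' and falling patterns are equally represented), then lexicographically.
#' Retained profiles are returned in lexicographic order; their profile ids
#' are the 0-based row positions in that order.
#'
#' @param candidates Integer matrix of candidate profiles (rows).
#' @param m Number of profiles to retain.
#' @return Integer matrix of retained profiles in lexicographic row order.
#' @export
select_model_profiles <- function(candidates, m) {
  stopifnot(m >= 2)
  n <- nrow(candidates)
  if (m >= n) m <- n
  D <- .profile_dist_matrix(candidates, candidates)
  flat <- which(rowSums(abs(candidates)) == 0)
  if (length(flat) == 0) {
    # no flat candidate: seed from the lexicographically first profile
    flat <- 1L
  }
  sel <- flat[1]
  key <- apply(candidates, 1, paste, collapse = ",")
  neg_key <- apply(-candidates, 1, paste, collapse = ",")
  while (length(sel) < m) {
    mind <- apply(D[, sel, drop = FALSE], 1, min)
    mind[sel] <- -Inf
    best <- max(mind)
    tied <- which(mind >= best - 1e-9)
    if (length(tied) > 1) {
      mirror <- tied[neg_key[tied] %in% key[sel]]
      if (length(mirror) > 0) tied <- mirror
    }
    sel <- c(sel, tied[1])
  }
  out <- candidates[sort(sel), , drop = FALSE]
  dimnames(out) <- NULL
  out
}

#' Log2-ratio series relative to the first time point
#'
#' Each feature's series becomes `log2((value_t + pseudo) / (value_1 + pseudo))`,
#' anchoring the first entry at exactly 0, the scale on which model
#' profiles are defined.
#'
#' @param x Expression tibble (typically per-million values).
#' @param series_order Character vector of library ids defining the series.
#' @param pseudocount Added to both numerator and denominator.
#' @return Tibble: `feature_id` plus one column per series point.
#' @export
to_log_ratio_series <- function(x, series_order, pseudocount = 1) {
  x <- validate_expression(x)
  missing <- setdiff(series_order, library_ids(x))
  if (length(missing) > 0) abort(paste0("unknown column: ", missing[1]))
  m <- expr_values(x)[, series_order, drop = FALSE]
  lr <- log2((m + pseudocount) / (m[, 1] + pseudocount))
  expr_tibble(lr)
}

#' Assign features to model profiles
#'
#' Each feature goes to the model profile minimizing
#' `1 - Pearson(series, model)`; ties break toward the lowest profile id,
#' and zero-variance series go to the flat profile (if present in the
#' model set).
#'
#' @param series Log2-ratio series tibble ([to_log_ratio_series()]).
#' @param models Integer matrix of model profiles (rows, lexicographic
#'   order as from [select_model_profiles()]).
#' @return Tibble: `feature_id`, `profile_id` (0-based), `distance`.
#' @export
assign_profiles <- function(series, models) {
  if (is.null(dim(models)) || nrow(models) == 0) abort("models must be a non-empty matrix")
  m <- .series_values(series)
  if (ncol(m) != ncol(models)) abort("series and model profiles differ in length")
  D <- .profile_dist_matrix(m, models)
  idx <- apply(D, 1, which.min)
  tibble::tibble(
    feature_id = rownames(m),
    profile_id = as.integer(idx) - 1L,
    distance = D[cbind(seq_len(nrow(D)), idx)])
}

# log2-ratio series tables carry negative values, so they skip the
# non-negativity check of validate_expression()
.series_values <- function(series) {
  series <- tibble::as_tibble(series)
  if (anyNA(series[-1])) abort("missing values in series table")
  m <- as.matrix(series[-1])
  rownames(m) <- series[[1]]
  m
}

# all permutations of seq_len(n), in a deterministic order
.permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- .permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    rest <- seq_len(n)[-i]
    cbind(i, matrix(rest[sub], nrow(sub)))
  }))
}

#' Permutation-expected profile counts
#'
#' The null model permutes each feature's time points, re-anchors the
#' series at its first point, and re-assigns it to the nearest model
#' profile; the expected count of a profile is the mean assigned count over
#' permutations. All `T!` orderings are enumerated for series of up to
#' `max_exact_t` points, otherwise `n_perm` permutations are sampled under
#' `seed`.
#'
#' @inheritParams assign_profiles
#' @param permutations Optional integer matrix of permutations (rows); by
#'   default all of them for short series.
#' @param max_exact_t,n_perm,seed Control sampled permutations for long series.
#' @return Numeric vector of expected counts, one per model profile.
#' @export
expected_counts <- function(series, models, permutations = NULL,
                            max_exact_t = 5, n_perm = 2000, seed = 1L) {
  m <- .series_values(series)
  tp <- ncol(m)
  if (is.null(permutations)) {
    if (tp <= max_exact_t) {
      permutations <- .permutations(tp)
    } else {
      permutations <- withr::with_seed(seed, t(replicate(n_perm, sample.int(tp))))
    }
  }
  e <- numeric(nrow(models))
  for (i in seq_len(nrow(permutations))) {
    mp <- m[, permutations[i, ], drop = FALSE]
    # re-anchoring at the first point shifts each series by a constant,
    # which leaves the correlation distance unchanged
    D <- .profile_dist_matrix(mp, models)
    idx <- apply(D, 1, which.min)
    tab <- tabulate(idx, nbins = nrow(models))
    e <- e + tab
  }
  e / nrow(permutations)
}

#' Binomial significance of an assigned profile count
#'
#' Upper-tail probability that at least `a` of `n` features land on a
#' profile when each lands there independently with probability `e/n`
#' (the permutation-expected count over the clustered universe). Computed
#' by log-space summation of binomial terms, exact for `n` up to 10^4.
#'
#' @param a Assigned count(s), integers in \[0, n\].
#' @param e Expected count(s) under the permutation null.
#' @param n Number of clustered features.
#' @return Vector of upper-tail p-values in (0, 1\].
#' @export
profile_significance <- function(a, e, n) {
  k <- max(length(a), length(e))
  a <- rep_len(a, k); e <- rep_len(e, k)
  if (any(e > n)) abort("expected count cannot exceed the universe size")
  if (any(a < 0 | a > n)) abort("assigned count must lie in [0, n]")
  if (any(e < 0)) abort("expected count must be non-negative")
  vapply(seq_len(k), function(i) .binom_upper_tail(a[i], n, e[i] / n), numeric(1))
}

# log-space sum of dbinom terms from a to n via logsumexp
.binom_upper_tail <- function(a, n, p) {
  if (a <= 0) return(1)
  if (p <= 0) return(0)
  if (p >= 1) return(1)
  ks <- seq.int(a, n)
  lt <- lchoose(n, ks) + ks * log(p) + (n - ks) * log1p(-p)
  mx <- max(lt)
  min(1, exp(mx + log(sum(exp(lt - mx)))))
}

#' Cluster a short expression series into model profiles
#'
#' End-to-end profile clustering: per-million normalization (unless the
#' input is already normalized), log2-ratio series over `series_order`,
#' model-profile enumeration and greedy selection, nearest-profile
#' assignment, permutation-expected counts and binomial significance.
#'
#' @param x Expression tibble of counts or normalized values.
#' @param series_order Library ids in series (time) order.
#' @param config A [stem_config()].
#' @param features Optional feature subset to cluster (e.g. the DE union).
#' @param normalized Set `TRUE` if `x` is already depth-normalized.
#' @param seed Seed for sampled permutations (long series only).
#' @return An object of class `stem_fit`: list with `models` (tibble of
#'   profile id/vector), `assignments`, `stats` (assigned `n_assigned`,
#'   expected `n_expected`, `p_value`, `significant`), `n`, `alpha`,
#'   `series`.
#' @export
cluster_profiles <- function(x, series_order, config = stem_config(),
                             features = NULL, normalized = FALSE, seed = 1L) {
  x <- validate_expression(x)
  if (!normalized) x <- normalize_per_million(x)
  if (!is.null(features)) x <- x[x$feature_id %in% features, , drop = FALSE]
  if (nrow(x) == 0) abort("no features to cluster")
  series <- to_log_ratio_series(x, series_order, config$pseudocount)
  cand <- enumerate_profiles(length(series_order), config$max_step)
  models <- select_model_profiles(cand, config$n_models)
  assignments <- assign_profiles(series, models)
  a <- tabulate(assignments$profile_id + 1L, nbins = nrow(models))
  e <- expected_counts(series, models, max_exact_t = config$max_exact_t,
                       n_perm = config$n_perm, seed = seed)
  n <- nrow(series)
  p <- profile_significance(a, e, n)
  stats <- tibble::tibble(
    profile_id = seq_len(nrow(models)) - 1L,
    profile = apply(models, 1, paste, collapse = ","),
    n_assigned = a, n_expected = e, p_value = p,
    significant = p <= config$alpha)
  structure(list(models = models, assignments = assignments, stats = stats,
                 n = n, alpha = config$alpha, series = series,
                 series_order = series_order),
            class = "stem_fit")
}

#' @export
print.stem_fit <- function(x, ...) {
  cat("Model-profile clustering:", x$n, "features,",
      nrow(x$models), "model profiles,",
      sum(x$stats$significant), "significant at alpha =", x$alpha, "\n")
  print(dplyr::arrange(x$stats[x$stats$significant, ], .data$p_value))
  invisible(x)
}

#' Significant profiles and their member features
#'
#' @param fit A `stem_fit`.
#' @param alpha Significance threshold (defaults to the fit's).
#' @return Tibble of significant profiles with a `members` list-column.
#' @export
significant_profiles <- function(fit, alpha = NULL) {
  alpha <- alpha %||% fit$alpha
  keep <- fit$stats[fit$stats$p_value <= alpha, ]
  keep$members <- purrr::map(keep$profile_id, function(id) {
    fit$assignments$feature_id[fit$assignments$profile_id == id]
  })
  keep
}

#' Union of features in significant profiles
#'
#' The membership consumed by the integration stage.
#'
#' @inheritParams significant_profiles
#' @return Character vector of feature ids.
#' @export
profile_members <- function(fit, alpha = NULL) {
  sort(unique(unlist(significant_profiles(fit, alpha)$members)))
}
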