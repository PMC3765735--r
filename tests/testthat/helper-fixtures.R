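# shared fixtures, generated once per test run

.fixture_env <- new.env(parent = emptyenv())

# small synthetic study reused across tests (deterministic)
small_study <- function(dispersion = 0.1, seed = 3) {
  key <- paste0("study_", dispersion, "_", seed)
  if (is.null(.fixture_env[[key]])) {
    .fixture_env[[key]] <- simulate_study(sim_config(
      n_genes = 400, n_mirnas = 20, n_proteins = 30,
      dispersion = dispersion, seed = seed))
  }
  .fixture_env[[key]]
}

# tiny count table built by hand
tiny_counts <- function() {
  tibble::tibble(
    feature_id = paste0("g", 1:4),
    L1 = c(10L, 0L, 25L, 65L),
    L2 = c(20L, 5L, 25L, 50L))
}

# random log2-ratio series table anchored at 0
random_series <- function(n, t, seed = 1) {
  withr::with_seed(seed, {
    m <- matrix(rnorm(n * t), n, t)
    m <- m - m[, 1]
    colnames(m) <- paste0("T", seq_len(t))
    tibble::tibble(feature_id = paste0("f", seq_len(n))) |>
      dplyr::bind_cols(tibble::as_tibble(as.data.frame(m)))
  })
}

# independent brute-force p-value for the exact tag test: full enumeration
# of the conditional distribution with lgamma-based log probabilities
oracle_tag_p <- function(x, y, n1, n2) {
  t <- x + y
  if (t == 0) return(1)
  pr <- n2 / (n1 + n2)
  ys <- 0:t
  lp <- lgamma(t + 1) - lgamma(ys + 1) - lgamma(t - ys + 1) +
    ys * log(pr) + (t - ys) * log1p(-pr)
  keep <- lp <= lp[ys == y] + log1p(1e-7)
  # sum smallest terms first for accuracy
  sum(sort(exp(lp[keep])))
}
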