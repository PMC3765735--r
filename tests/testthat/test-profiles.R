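test_that("profile enumeration is exhaustive and bounded", {
  p21 <- enumerate_profiles(2, 1)
  expect_equal(nrow(p21), 3)
  expect_equal(p21, rbind(c(0L, -1L), c(0L, 0L), c(0L, 1L)))

  p43 <- enumerate_profiles(4, 3)
  expect_equal(nrow(p43), 343)  # (2c+1)^(T-1)
  expect_true(all(p43[, 1] == 0))
  expect_true(all(abs(p43[, -1] - p43[, -4]) <= 3))
  key4 <- apply(p43, 1, paste, collapse = ",")
  # observed cluster shapes appear among the candidates
  expect_true(all(c("0,-1,-2,-3", "0,1,2,3") %in% key4))
  p33 <- enumerate_profiles(3, 3)
  expect_true("0,2,3" %in% apply(p33, 1, paste, collapse = ","))
})

test_that("profile distance completes the metric at the flat profile", {
  expect_equal(profile_distance(c(0, 0, 0), c(0, 0, 0)), 0)
  expect_equal(profile_distance(c(0, 0, 0), c(0, 1, 2)), 1)
  expect_equal(profile_distance(c(0, 1, 2), c(0, 2, 4)), 0)
  expect_equal(profile_distance(c(0, 1, 2), c(0, -1, -2)), 2)
})

test_that("greedy model selection reproduces a brute-force oracle", {
  cand <- enumerate_profiles(3, 1)
  got <- select_model_profiles(cand, 4)

  # independent step-by-step greedy with scalar distances
  d <- function(p, q) profile_distance(p, q)
  sel <- which(apply(cand, 1, function(v) all(v == 0)))
  while (length(sel) < 4) {
    mind <- sapply(seq_len(nrow(cand)), function(i) {
      if (i %in% sel) return(-Inf)
      min(sapply(sel, function(j) d(cand[i, ], cand[j, ])))
    })
    best <- max(mind)
    tied <- which(mind >= best - 1e-9)
    neg_in <- sapply(tied, function(i) {
      any(sapply(sel, function(j) all(cand[j, ] == -cand[i, ])))
    })
    if (any(neg_in)) tied <- tied[neg_in]
    sel <- c(sel, tied[1])
  }
  oracle <- cand[sort(sel), , drop = FALSE]
  dimnames(oracle) <- NULL
  expect_equal(got, oracle)

  # m >= candidate count returns everything
  expect_equal(nrow(select_model_profiles(cand, 100)), nrow(cand))

  # every retained pair respects the reported minimum separation
  models <- select_model_profiles(enumerate_profiles(4, 2), 10)
  dm <- outer(seq_len(nrow(models)), seq_len(nrow(models)),
              Vectorize(function(i, j) profile_distance(models[i, ], models[j, ])))
  expect_true(all(dm[upper.tri(dm)] > 0))
})

test_that("log2-ratio series anchor at zero and honour the pseudocount", {
  x <- tibble::tibble(feature_id = c("flat", "dbl", "zero"),
                      A = c(7, 10, 0), B = c(7, 20, 0),
                      C = c(7, 40, 0), D = c(7, 80, 0))
  s <- to_log_ratio_series(x, c("A", "B", "C", "D"), pseudocount = 0)
  expect_equal(unlist(s[s$feature_id == "flat", -1], use.names = FALSE), c(0, 0, 0, 0))
  expect_equal(unlist(s[s$feature_id == "dbl", -1], use.names = FALSE), c(0, 1, 2, 3))
  s1 <- to_log_ratio_series(x, c("A", "B", "C"), pseudocount = 1)
  expect_equal(unlist(s1[s1$feature_id == "zero", -1], use.names = FALSE), c(0, 0, 0))
  expect_error(to_log_ratio_series(x, c("A", "nope")), "unknown column")
})

test_that("assignment matches an exhaustive distance scan", {
  models <- select_model_profiles(enumerate_profiles(4, 2), 12)
  expect_error(assign_profiles(random_series(5, 3), models), "length")

  series <- random_series(200, 4, seed = 10)
  asg <- assign_profiles(series, models)
  m <- as.matrix(series[-1])
  for (i in seq_len(50)) {
    dists <- apply(models, 1, function(v) profile_distance(m[i, ], v))
    expect_equal(asg$profile_id[i], which.min(dists) - 1L)
    expect_equal(asg$distance[i], min(dists), tolerance = 1e-9)
  }

  # a series equal to a model vector lands there with distance 0
  exact <- tibble::tibble(feature_id = "e", A = 0, B = models[5, 2],
                          C = models[5, 3], D = models[5, 4])
  a1 <- assign_profiles(exact, models)
  expect_equal(a1$profile_id, 4L)
  expect_equal(a1$distance, 0, tolerance = 1e-12)

  # perfect anti-correlation has distance 2
  mm <- rbind(c(0L, 1L, 2L, 3L), c(0L, -1L, -2L, -3L))
  up <- tibble::tibble(feature_id = "u", A = 0, B = 1, C = 2, D = 3)
  a2 <- assign_profiles(up, mm)
  expect_equal(a2$profile_id, 0L)
  expect_equal(profile_distance(c(0, 1, 2, 3), mm[2, ]), 2)

  # zero-variance series go to the flat profile
  mflat <- rbind(c(0L, 0L, 0L, 0L), c(0L, 1L, 2L, 3L))
  fl <- tibble::tibble(feature_id = "f", A = 0, B = 0, C = 0, D = 0)
  expect_equal(assign_profiles(fl, mflat)$profile_id, 0L)
})

test_that("permutation nulls conserve counts and enumerate T! orderings", {
  expect_equal(nrow(culmnet:::.permutations(3)), 6)
  expect_equal(nrow(unique(culmnet:::.permutations(4))), 24)

  models <- select_model_profiles(enumerate_profiles(4, 2), 12)
  series <- random_series(150, 4, seed = 2)
  e <- expected_counts(series, models)
  expect_equal(sum(e), 150)

  # identity permutation only: expected equals assigned
  a <- tabulate(assign_profiles(series, models)$profile_id + 1L, nbins = nrow(models))
  e_id <- expected_counts(series, models, permutations = matrix(1:4, 1))
  expect_equal(e_id, as.numeric(a))
})

test_that("mirrored profiles receive equal expected counts on sign-symmetric data", {
  models <- rbind(c(0L, -1L, -2L, -3L), c(0L, -1L, 0L, 2L), c(0L, 0L, 0L, 0L),
                  c(0L, 1L, 0L, -2L), c(0L, 1L, 2L, 3L))
  half <- random_series(60, 4, seed = 8)
  mirrored <- half
  mirrored$feature_id <- paste0(half$feature_id, "_neg")
  mirrored[-1] <- -half[-1]
  sym <- dplyr::bind_rows(half, mirrored)
  e <- expected_counts(sym, models)
  expect_equal(e[1], e[5])
  expect_equal(e[2], e[4])
  expect_equal(sum(e), 120)
})

test_that("profile significance is an exact binomial upper tail", {
  expect_equal(profile_significance(0, 10, 100), 1)
  # monotone non-increasing in the assigned count
  p_seq <- profile_significance(0:50, 10, 100)
  expect_true(all(diff(p_seq) <= 0))
  # matches the distribution-function oracle, including the published-scale
  # case (5,837 clustered genes, 85.7 expected, 177 assigned)
  cases <- list(c(177, 85.7, 5837), c(12, 3.2, 400), c(40, 39.9, 100),
                c(5, 0.01, 5000))
  for (cs in cases) {
    got <- profile_significance(cs[1], cs[2], cs[3])
    ora <- pbinom(cs[1] - 1, cs[3], cs[2] / cs[3], lower.tail = FALSE)
    expect_equal(log10(got), log10(ora), tolerance = 1e-6)
  }
  lp <- log10(profile_significance(177, 85.7, 5837))
  expect_gt(lp, -20); expect_lt(lp, -16)
  expect_error(profile_significance(10, 200, 100), "exceed")
})

test_that("significant profiles are recovered on a planted fixture", {
  # 30% of features on one non-flat retained shape, the rest random
  models <- select_model_profiles(enumerate_profiles(4, 3), 50)
  key <- apply(models, 1, paste, collapse = ",")
  target <- models[which(key != "0,0,0,0")[10], ]
  target_key <- paste(target, collapse = ",")
  withr::with_seed(21, {
    n <- 300
    m <- matrix(rnorm(n * 4, sd = 0.6), n, 4)
    planted <- seq_len(90)
    m[planted, ] <- m[planted, ] * 0.2 + rep(target, each = length(planted))
    m <- m - m[, 1]
  })
  series <- tibble::tibble(feature_id = paste0("f", 1:n)) |>
    dplyr::bind_cols(tibble::as_tibble(as.data.frame(m)))
  asg <- assign_profiles(series, models)
  a <- tabulate(asg$profile_id + 1L, nbins = nrow(models))
  e <- expected_counts(series, models)
  p <- profile_significance(a, e, n)
  target_id <- which(key == target_key)
  flat_id <- which(key == "0,0,0,0")
  expect_lte(p[target_id], 0.01)
  expect_gt(p[flat_id], 0.01)

  fit <- structure(list(models = models,
                        assignments = asg,
                        stats = tibble::tibble(
                          profile_id = seq_along(key) - 1L, profile = key,
                          n_assigned = a, n_expected = e, p_value = p,
                          significant = p <= 0.01),
                        n = n, alpha = 0.01, series = series),
                   class = "stem_fit")
  sp <- significant_profiles(fit)
  expect_true(target_key %in% sp$profile)
  expect_true(all(p[sp$profile_id + 1] <= 0.01))
  expect_equal(significant_profiles(fit, alpha = 1)$profile_id,
               fit$stats$profile_id)
  # the recovered profile's membership is dominated by the planted features
  tgt_members <- unlist(sp$members[sp$profile == target_key])
  expect_gt(mean(tgt_members %in% series$feature_id[planted]), 0.8)
  expect_setequal(profile_members(fit, alpha = 1), series$feature_id)
})

test_that("profile recovery meets its calibrated floor on the reference run", {
  # full-size reference study (2,000 genes, mild overdispersion, seed 7);
  # exact per-gene recovery among the 50 crowded model profiles is
  # noise-limited -- the floor below was frozen from calibration runs
  s <- simulate_study(sim_config(seed = 7))
  de <- call_de(s$mrna)
  fit <- cluster_profiles(s$mrna, c("G1M", "G2M", "G3M", "G4M"),
                          features = de_union(de), seed = 7)
  asg <- fit$assignments
  asg$assigned <- fit$stats$profile[asg$profile_id + 1]
  m <- dplyr::inner_join(asg, s$truth$gene_profiles,
                         by = c(feature_id = "gene_id"))
  pl <- m[!is.na(m$profile), ]
  expect_gte(mean(pl$assigned == pl$profile), 0.35)
  # at the profile level, every planted shape is recovered as significant
  planted_shapes <- unique(pl$profile)
  expect_true(all(planted_shapes %in%
                    fit$stats$profile[fit$stats$significant]))
})

test_that("end-to-end clustering on a synthetic study finds planted shapes", {
  s <- small_study()
  de <- call_de(s$mrna)
  fit <- cluster_profiles(s$mrna, c("G1M", "G2M", "G3M", "G4M"),
                          features = de_union(de), seed = 1)
  expect_s3_class(fit, "stem_fit")
  expect_equal(sum(fit$stats$n_assigned), fit$n)
  expect_equal(sum(fit$stats$n_expected), fit$n, tolerance = 1e-8)
  planted <- unique(stats::na.omit(s$truth$gene_profiles$profile))
  sig <- fit$stats$profile[fit$stats$significant]
  # planted shapes (or their assignable neighbours) dominate the significant set
  expect_gte(length(intersect(planted, sig)), 3)
  g <- glance(fit)
  expect_equal(g$n_significant, sum(fit$stats$significant))
  expect_equal(nrow(tidy(fit)), nrow(fit$models))
})
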