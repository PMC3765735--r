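test_that("Pearson correlation and p-value match the direct formula", {
  expect_equal(pearson_with_p(1:5, 2 * (1:5) + 3)$r, 1)
  expect_equal(pearson_with_p(1:5, -(1:5))$r, -1)
  expect_equal(pearson_with_p(1:5, -(1:5))$p, 0)

  x <- c(1, 2, 3, 4, 5, 6); y <- c(2, 1, 4, 3, 6, 5)
  got <- pearson_with_p(x, y)
  # independent formula evaluation
  r_o <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  t_o <- r_o * sqrt(4) / sqrt(1 - r_o^2)
  p_o <- 2 * (1 - pt(abs(t_o), 4))
  expect_equal(got$r, r_o, tolerance = 1e-12)
  expect_equal(got$p, p_o, tolerance = 1e-12)
  ct <- cor.test(x, y)
  expect_equal(got$p, unname(ct$p.value), tolerance = 1e-12)

  expect_error(pearson_with_p(1:3, c(2, 2, 2)), "zero-variance")
  expect_error(pearson_with_p(1:2, 1:2), "at least 3")
})

test_that("the critical correlation at n = 6 rounds to the screen threshold", {
  expect_equal(round_half_up(critical_r(6, 0.05), 2), 0.81)
  expect_equal(critical_r(6, 0.05), 0.8114, tolerance = 1e-4)

  # bisection oracle against the t distribution at n = 3
  bisect <- function(n, alpha) {
    lo <- 1e-9; hi <- 1 - 1e-12
    for (i in 1:200) {
      mid <- (lo + hi) / 2
      p <- 2 * pt(mid * sqrt((n - 2) / (1 - mid^2)), n - 2, lower.tail = FALSE)
      if (p > alpha) lo <- mid else hi <- mid
    }
    (lo + hi) / 2
  }
  expect_equal(critical_r(3, 0.05), bisect(3, 0.05), tolerance = 1e-6)
  # p drops strictly below alpha just above the root
  r <- critical_r(6, 0.05)
  expect_lt(2 * pt((r + 1e-6) * sqrt(4 / (1 - (r + 1e-6)^2)), 4,
                   lower.tail = FALSE), 0.05)
  expect_lt(critical_r(6, 0.10), critical_r(6, 0.05))
  expect_error(critical_r(2, 0.05), "at least 3")
})

test_that("pair screens are strict at the threshold and find planted pairs", {
  s0 <- small_study(dispersion = 0)
  neg <- screen_pairs(s0$mirna, s0$mrna, s0$target_map, "negative")
  reg_key <- paste(s0$truth$regulated$mirna_id, s0$truth$regulated$gene_id)
  pass_key <- paste(neg$source_id, neg$target_id)[neg$passes_screen]
  # planted anti-regulated pairs all pass the negative screen at zero
  # overdispersion
  expect_equal(mean(reg_key %in% pass_key), 1)
  expect_true(all(neg$r[neg$passes_screen] < -0.81))
  expect_true(all(neg$p[neg$passes_screen] <= 0.05))

  # a pair at exactly r = -0.80 fails the strict screen
  fake <- tibble::tibble(source_id = "m", target_id = "g",
                         r = -0.80, p = 0.03, type = "negative",
                         passes_screen = -0.80 < -0.81 & 0.03 <= 0.05)
  expect_false(fake$passes_screen)

  # absent features are skipped with a warning
  bad_map <- tibble::tibble(mirna_id = "no-such", gene_id = s0$mrna$feature_id[1])
  expect_warning(out <- screen_pairs(s0$mirna, s0$mrna, bad_map, "negative"),
                 "absent")
  expect_equal(nrow(out), 0)
})

test_that("positive mRNA-protein screen recovers encoding relationships", {
  s0 <- small_study(dispersion = 0)
  pmap <- s0$truth$protein_map[, c("gene_id", "protein_id")]
  pos <- screen_pairs(s0$mrna, s0$protein, pmap, "positive")
  expect_true(all(pos$r[pos$passes_screen] > 0.81))
  # proteins of profiled genes correlate positively with their mRNA
  profiled <- s0$truth$gene_profiles$gene_id[!is.na(s0$truth$gene_profiles$profile)]
  hit <- pos[pos$source_id %in% profiled, ]
  expect_gt(mean(hit$passes_screen), 0.7)
  expect_gt(median(hit$r), 0.85)
})

test_that("Fisher enrichment equals the hypergeometric tail oracle", {
  # worked 2x2 table: 6/10 targets negative, 10/90 non-targets negative
  got <- culmnet:::.fisher_greater(6, 4, 10, 80)
  ora <- phyper(5, 10, 90, 16, lower.tail = FALSE)
  expect_equal(got, ora, tolerance = 1e-12)
  ft <- fisher.test(matrix(c(6, 4, 10, 80), 2, byrow = TRUE),
                    alternative = "greater")
  expect_equal(got, unname(ft$p.value), tolerance = 1e-12)

  # exhaustive sweep over small tables against both oracles
  for (m in 0:12) for (n2 in 0:12) for (a in 0:m) for (cc in 0:n2) {
    b <- m - a; d <- n2 - cc
    got <- culmnet:::.fisher_greater(a, b, cc, d)
    if (m == 0 || n2 == 0 || (a + cc) == 0 || (b + d) == 0) {
      expect_equal(got, 1)
    } else {
      expect_equal(got, phyper(a - 1, m, n2, a + cc, lower.tail = FALSE),
                   tolerance = 1e-12)
    }
  }
})

test_that("per-miRNA enrichment flags planted regulators", {
  s0 <- small_study(dispersion = 0)
  enr <- mirna_target_enrichment(s0$mirna, s0$mrna, s0$target_map)
  expect_true(all(enr$p_value > 0), all(enr$p_value <= 1))
  # planted regulators have 4 truly regulated targets each out of 10;
  # the background negative rate is inflated by genes sharing the
  # anti-profile, so the enrichment is present but not extreme
  expect_lt(median(enr$p_value), 0.05)
  # two-sided option is valid and never smaller than machine zero
  enr2 <- mirna_target_enrichment(s0$mirna, s0$mrna, s0$target_map,
                                  alternative = "two.sided")
  expect_true(all(enr2$p_value <= 1))
})

test_that("integration keeps screened pairs whose gene has a significant profile", {
  pairs <- tibble::tibble(
    source_id = c("m1", "m1", "m2", "gA"),
    target_id = c("gA", "gB", "gC", "p1"),
    r = c(-0.95, -0.9, -0.99, 0.97),
    p = c(0.01, 0.03, 0.001, 0.02),
    type = c("negative", "negative", "negative", "positive"),
    passes_screen = c(TRUE, TRUE, FALSE, TRUE))
  neg <- pairs[pairs$type == "negative", ]
  pos <- pairs[pairs$type == "positive", ]

  out <- integrate_pairs(neg, pos, mrna_members = c("gA", "gB"))
  expect_equal(nrow(out$pairs), 3)
  expect_setequal(out$genes, c("gA", "gB"))
  expect_equal(out$proteins, "p1")

  # a gene outside every significant profile is excluded
  out2 <- integrate_pairs(neg, pos, mrna_members = "gA")
  expect_false("gB" %in% out2$genes)

  # empty membership gives an empty set
  out0 <- integrate_pairs(neg, pos, mrna_members = character())
  expect_equal(nrow(out0$pairs), 0)
  expect_equal(glance(out0)$n_genes, 0)

  # monotone: enlarging the member set never removes a retained pair
  k2 <- paste(out2$pairs$source_id, out2$pairs$target_id)
  k1 <- paste(out$pairs$source_id, out$pairs$target_id)
  expect_true(all(k2 %in% k1))

  # miRNA membership gate applies only when supplied
  out3 <- integrate_pairs(neg, pos, mrna_members = c("gA", "gB"),
                          mirna_members = character())
  expect_equal(sum(out3$pairs$type == "negative"), 0)
  expect_equal(sum(out3$pairs$type == "positive"), 1)
})

test_that("integrated unique genes equal planted regulated genes at zero noise", {
  s0 <- small_study(dispersion = 0)
  de <- call_de(s0$mrna)
  fit_dev <- cluster_profiles(s0$mrna, c("G1M", "G2M", "G3M", "G4M"),
                              features = de_union(de), seed = 1)
  members <- profile_members(fit_dev)
  neg <- screen_pairs(s0$mirna, s0$mrna, s0$target_map, "negative")
  out <- integrate_pairs(neg, NULL, mrna_members = members)
  reg_genes <- unique(s0$truth$regulated$gene_id)
  # every planted regulated gene that was clustered into a significant
  # profile survives integration; nothing else joins from the mRNA side
  expect_true(all(out$genes %in% neg$target_id))
  expect_gte(length(intersect(out$genes, reg_genes)) / length(reg_genes), 0.85)
})
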