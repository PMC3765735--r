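#' Configuration of a synthetic six-library study
#'
#' Describes a complete synthetic study over the six-library culm design:
#' four developmental stages (positions 1-4 of `library_ids`) plus a top
#' internode sample behaving like the early group and a bottom internode
#' sample behaving like the late group (positions 5 and 6). A fraction of
#' genes carries a planted temporal profile on the log2 scale; every miRNA
#' carries one, and its truly regulated targets carry the sign-flipped
#' profile, which guarantees the anti-correlation the screens look for.
#' Protein intensities are log-normal noise around the encoding mRNA's
#' expected per-million profile.
#'
#' @param n_genes,n_mirnas,n_proteins Feature counts per layer.
#' @param library_ids Six unique library labels; positions 1-4 are the
#'   developmental series, 5 the top and 6 the bottom internode.
#' @param library_sizes Total tags per library (distinct depths by default).
#' @param profile_fraction Fraction of genes with an independently planted
#'   profile (truly regulated targets are planted in addition).
#' @param amplitude Log2 units per unit profile step.
#' @param dispersion Negative-binomial overdispersion (variance
#'   `mu + dispersion * mu^2`); 0 draws Poisson counts.
#' @param targets_per_mirna Predicted targets per miRNA.
#' @param regulated_fraction Fraction of each miRNA's predicted targets
#'   that are truly anti-regulated.
#' @param novel_fraction Fraction of miRNAs labelled as novel (id prefix
#'   `novel-`).
#' @param baseline_sdlog Log-normal spread of gene baseline abundances.
#' @param protein_sdlog Log-normal measurement noise of protein spots.
#' @param seed Integer seed; identical configurations give identical studies.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 2000, n_mirnas = 100, n_proteins = 100,
                       library_ids = CULM_LIBRARIES,
                       library_sizes = c(80000, 95000, 110000, 125000, 90000, 105000),
                       profile_fraction = 0.3, amplitude = 1, dispersion = 0.1,
                       targets_per_mirna = 10, regulated_fraction = 0.4,
                       novel_fraction = 0.3, baseline_sdlog = 1,
                       protein_sdlog = 0.25, seed = 1L) {
  if (n_genes < 1 || n_mirnas < 1 || n_proteins < 0) abort("layer sizes must be positive")
  if (length(library_ids) != 6 || anyDuplicated(library_ids)) abort("need 6 unique library ids")
  if (length(library_sizes) != 6 || any(library_sizes <= 0)) abort("need 6 positive library sizes")
  for (f in c(profile_fraction, regulated_fraction, novel_fraction)) {
    if (f < 0 || f > 1) abort("fractions must lie in [0, 1]")
  }
  if (amplitude < 0) abort("amplitude must be non-negative")
  if (dispersion < 0) abort("dispersion must be non-negative")
  if (targets_per_mirna < 1) abort("targets_per_mirna must be at least 1")
  structure(list(
    n_genes = n_genes, n_mirnas = n_mirnas, n_proteins = n_proteins,
    library_ids = library_ids, library_sizes = library_sizes,
    profile_fraction = profile_fraction, amplitude = amplitude,
    dispersion = dispersion, targets_per_mirna = targets_per_mirna,
    regulated_fraction = regulated_fraction, novel_fraction = novel_fraction,
    baseline_sdlog = baseline_sdlog, protein_sdlog = protein_sdlog,
    seed = as.integer(seed)), class = "sim_config")
}

#' Expected abundance series of a planted profile
#'
#' Maps an integer model profile (starting at 0) to an expected-abundance
#' series: `baseline * 2^(amplitude * v_t)`.
#'
#' @param profile Integer profile vector with first entry 0.
#' @param amplitude Log2 units per profile step.
#' @param baseline Positive baseline abundance.
#' @return Numeric series of the same length.
#' @export
plant_profile <- function(profile, amplitude, baseline) {
  if (profile[1] != 0) abort("profile must start at 0")
  if (baseline <= 0) abort("baseline must be positive")
  baseline * 2^(amplitude * profile)
}

#' Draw counts from a mean matrix
#'
#' Scales each column of `means` to the corresponding library size and
#' draws Poisson counts (`dispersion = 0`) or negative-binomial counts with
#' variance `mu + dispersion * mu^2`. Deterministic under `seed`.
#'
#' @param means Non-negative feature-by-library matrix of relative means.
#' @param library_sizes One positive total per column.
#' @param dispersion Non-negative overdispersion.
#' @param seed Integer seed.
#' @return Integer count matrix of the same dimensions.
#' @export
sample_counts <- function(means, library_sizes, dispersion = 0, seed = 1L) {
  means <- as.matrix(means)
  if (any(means < 0)) abort("means must be non-negative")
  if (length(library_sizes) != ncol(means)) abort("one library size per column")
  if (dispersion < 0) abort("dispersion must be non-negative")
  withr::with_seed(seed, {
    out <- means
    for (l in seq_len(ncol(means))) {
      tot <- sum(means[, l])
      mu <- if (tot > 0) means[, l] / tot * library_sizes[l] else means[, l]
      out[, l] <- if (dispersion == 0) {
        rpois(nrow(means), mu)
      } else {
        rnbinom(nrow(means), mu = mu, size = 1 / dispersion)
      }
    }
    storage.mode(out) <- "integer"
    out
  })
}

#' Predicted-target map with a planted regulated subset
#'
#' Gives every miRNA exactly `targets_per_mirna` predicted target genes and
#' marks `round(targets_per_mirna * regulated_fraction)` of them as truly
#' regulated. Regulated targets are globally disjoint (a gene is truly
#' regulated by at most one miRNA) so the planted anti-correlation signal
#' is unambiguous; predicted-only targets may be shared between miRNAs.
#'
#' @param mirna_ids Character vector of miRNA ids (or a count).
#' @param gene_ids Character vector of gene ids (or a count).
#' @param targets_per_mirna Predicted targets per miRNA (at least 1).
#' @param regulated_fraction Fraction of predicted targets truly regulated.
#' @param seed Integer seed.
#' @param regulated_from Optional subset of `gene_ids` from which the truly
#'   regulated targets are drawn.
#' @return List with `map` (tibble `mirna_id`, `gene_id`) and `regulated`
#'   (tibble subset of `map`).
#' @export
make_target_map <- function(mirna_ids, gene_ids, targets_per_mirna,
                            regulated_fraction, seed = 1L,
                            regulated_from = NULL) {
  if (length(mirna_ids) == 1 && is.numeric(mirna_ids)) {
    mirna_ids <- sprintf("miR-%03d", seq_len(mirna_ids))
  }
  if (length(gene_ids) == 1 && is.numeric(gene_ids)) {
    gene_ids <- sprintf("gene%04d", seq_len(gene_ids))
  }
  if (targets_per_mirna < 1) abort("targets_per_mirna must be at least 1")
  if (targets_per_mirna > length(gene_ids)) abort("more targets requested than genes")
  if (regulated_fraction < 0 || regulated_fraction > 1) abort("regulated_fraction must lie in [0, 1]")
  n_reg <- round(targets_per_mirna * regulated_fraction)
  regulated_from <- regulated_from %||% gene_ids
  if (n_reg * length(mirna_ids) > length(regulated_from)) {
    abort("not enough genes to host disjoint regulated targets")
  }
  withr::with_seed(seed, {
    reg_genes <- sample(regulated_from, n_reg * length(mirna_ids))
    reg <- if (n_reg > 0) {
      tibble::tibble(
        mirna_id = rep(mirna_ids, each = n_reg),
        gene_id = reg_genes)
    } else {
      tibble::tibble(mirna_id = character(), gene_id = character())
    }
    map <- purrr::map(seq_along(mirna_ids), function(i) {
      own <- reg$gene_id[reg$mirna_id == mirna_ids[i]]
      extra <- sample(setdiff(gene_ids, own), targets_per_mirna - length(own))
      tibble::tibble(mirna_id = mirna_ids[i], gene_id = c(own, extra))
    })
    list(map = dplyr::bind_rows(map), regulated = reg)
  })
}

# planted profile pools, derived from the default model-profile selection:
# gene profiles are a well-separated (greedy max-min) subset of the
# retained models whose per-point range stays within +/-3 log2 steps;
# miRNA profiles are additionally restricted to shapes whose sign flip is
# itself a retained model, so anti-regulated targets carry assignable shapes
.profile_pools <- function(max_step = 3, n_models = 50, pool_size = 12) {
  cand <- enumerate_profiles(4, max_step)
  models <- select_model_profiles(cand, n_models)
  # planted shapes mimic the temporal classes observed in culm development:
  # within +/-3 log2 steps, a gradual first step (at most one unit), at
  # least one unit of contrast between the early (stages 1-2) and late
  # (stages 3-4) means, and at least half of the shape's six-library
  # variance on the early/late contrast axis -- the last two conditions
  # make the latent two-group sample structure dominate ordination by
  # construction
  z6 <- t(apply(models, 1, .z6))
  cc <- z6 - rowMeans(z6)
  b <- c(-1, -1, 1, 1, -1, 1) / sqrt(6)
  align <- as.vector((cc %*% b)^2 / rowSums(cc^2))
  contrast <- abs(z6[, 6] - z6[, 5])
  keep <- apply(abs(models), 1, max) <= 3 & rowSums(abs(models)) > 0 &
    abs(models[, 2]) <= 1 & contrast >= 1 & align >= 0.5
  inrange <- models[keep, , drop = FALSE]
  if (nrow(inrange) > pool_size) {
    D <- .profile_dist_matrix(inrange, inrange)
    sel <- 1L
    while (length(sel) < pool_size) {
      mind <- apply(D[, sel, drop = FALSE], 1, min)
      mind[sel] <- -1
      sel <- c(sel, which.max(mind))
    }
    inrange <- inrange[sort(sel), , drop = FALSE]
  }
  gene_pool <- inrange
  model_key <- apply(models, 1, paste, collapse = ",")
  neg_ok <- apply(-gene_pool, 1, paste, collapse = ",") %in% model_key
  mirna_pool <- gene_pool[neg_ok, , drop = FALSE]
  if (nrow(mirna_pool) == 0) mirna_pool <- gene_pool
  list(models = models, gene_pool = gene_pool, mirna_pool = mirna_pool)
}

# six-library log2 offsets for a 4-point developmental profile: the top
# internode follows the early-stage mean, the bottom internode the
# late-stage mean, planting the two-group sample structure
.z6 <- function(v) c(v, mean(v[1:2]), mean(v[3:4]))

# per-profile baseline multipliers (geometric mean 1) equalizing expected
# column totals, so per-million ratios reflect planted profiles without a
# compositional offset
.balance_alphas <- function(P, unplanted_mass, bound = log(2)) {
  if (nrow(P) < 2) return(rep(1, nrow(P)))
  # multipliers centred (geometric mean 1) and bounded so no profile class
  # is starved of abundance; residual column-total imbalance stays a small
  # offset
  alphas <- function(th) {
    la <- bound * tanh(th / bound)
    exp(la - mean(la))
  }
  obj <- function(th) {
    m <- as.vector(t(P) %*% alphas(th)) + unplanted_mass
    lm <- log(m)
    sum((lm - mean(lm))^2)
  }
  opt <- optim(rep(0, nrow(P)), obj, method = "BFGS",
               control = list(maxit = 1000, reltol = 1e-14))
  alphas(opt$par)
}

# expected relative abundances for one layer: baselines, planted log2
# offsets, compositional balancing
.layer_means <- function(base, z, profile_of, amplitude) {
  mu <- base * 2^(amplitude * z)
  planted <- !is.na(profile_of)
  if (any(planted) && amplitude > 0) {
    keys <- unique(profile_of[planted])
    P <- do.call(rbind, lapply(keys, function(k) {
      colSums(mu[which(profile_of == k), , drop = FALSE])
    }))
    alpha <- .balance_alphas(P, sum(base[!planted]))
    for (i in seq_along(keys)) {
      g <- which(profile_of == keys[i])
      mu[g, ] <- mu[g, ] * alpha[i]
    }
  }
  mu
}

#' Simulate a complete six-library study
#'
#' Generates mRNA and miRNA count tables, a protein intensity table, a
#' predicted-target map and a ground-truth record from a [sim_config()].
#' See the configuration help for the planted structure. Identical
#' configurations (including seed) give byte-identical output.
#'
#' @param config A [sim_config()].
#' @return A list of class `sim_study` with elements `mrna`, `mirna`,
#'   `protein` (expression tibbles), `target_map` (tibble), `truth` (list:
#'   planted profiles per layer, regulated pairs, protein-gene map, latent
#'   group labels, expected per-million matrices) and `config`.
#' @export
simulate_study <- function(config = sim_config()) {
  if (!inherits(config, "sim_config")) abort("config must come from sim_config()")
  cf <- config
  pools <- .profile_pools()
  genes <- sprintf("gene%04d", seq_len(cf$n_genes))
  n_novel <- round(cf$novel_fraction * cf$n_mirnas)
  mirnas <- c(sprintf("miR-%03d", seq_len(cf$n_mirnas - n_novel)),
              sprintf("novel-miR-%03d", seq_len(n_novel)))
  proteins <- sprintf("prot%03d", seq_len(cf$n_proteins))

  withr::with_seed(cf$seed, {
    # planted gene profiles from the pool
    n_prof <- round(cf$profile_fraction * cf$n_genes)
    pool_genes <- sample(genes, n_prof)
    pool_idx <- sample(nrow(pools$gene_pool), n_prof, replace = TRUE)

    base_g <- setNames(exp(rnorm(cf$n_genes, 0, cf$baseline_sdlog)), genes)

    # predicted targets; truly regulated targets hosted outside the pool
    # set and on expressed genes (upper half of baseline abundance), since
    # regulation planted on undetectable genes cannot be screened
    hosts <- setdiff(genes[base_g >= median(base_g)], pool_genes)
    n_reg_total <- round(cf$targets_per_mirna * cf$regulated_fraction) * length(mirnas)
    if (length(hosts) < n_reg_total) hosts <- setdiff(genes, pool_genes)
    tm <- make_target_map(mirnas, genes, cf$targets_per_mirna,
                          cf$regulated_fraction,
                          seed = sample.int(.Machine$integer.max, 1),
                          regulated_from = hosts)

    # miRNA profiles: all miRNAs carry one, drawn from the sign-closed pool
    mir_idx <- sample(nrow(pools$mirna_pool), cf$n_mirnas, replace = TRUE)
    mir_profiles <- pools$mirna_pool[mir_idx, , drop = FALSE]

    # gene-level planted log2 offsets over the six libraries
    zg <- matrix(0, cf$n_genes, 6, dimnames = list(genes, cf$library_ids))
    profile_of <- rep(NA_character_, cf$n_genes)
    names(profile_of) <- genes
    for (i in seq_along(pool_genes)) {
      v <- pools$gene_pool[pool_idx[i], ]
      zg[pool_genes[i], ] <- .z6(v)
      profile_of[pool_genes[i]] <- paste(v, collapse = ",")
    }
    reg <- tm$regulated
    for (i in seq_len(nrow(reg))) {
      v <- -mir_profiles[match(reg$mirna_id[i], mirnas), ]
      zg[reg$gene_id[i], ] <- .z6(v)
      profile_of[reg$gene_id[i]] <- paste(v, collapse = ",")
    }

    mu_g <- .layer_means(unname(base_g), zg, profile_of, cf$amplitude)

    zm <- matrix(0, cf$n_mirnas, 6, dimnames = list(mirnas, cf$library_ids))
    for (i in seq_len(cf$n_mirnas)) zm[i, ] <- .z6(mir_profiles[i, ])
    mir_profile_of <- apply(mir_profiles, 1, paste, collapse = ",")
    base_m <- exp(rnorm(cf$n_mirnas, 0, cf$baseline_sdlog))
    mu_m <- .layer_means(base_m, zm, mir_profile_of, cf$amplitude)

    counts_g <- sample_counts(mu_g, cf$library_sizes, cf$dispersion,
                              seed = sample.int(.Machine$integer.max, 1))
    counts_m <- sample_counts(mu_m, cf$library_sizes, cf$dispersion,
                              seed = sample.int(.Machine$integer.max, 1))

    mean_pm_g <- sweep(mu_g, 2, colSums(mu_g), "/") * 1e6
    mean_pm_m <- sweep(mu_m, 2, colSums(mu_m), "/") * 1e6

    # proteins: log-normal noise around the encoding mRNA's expected
    # per-million profile
    prot_genes <- sample(genes, cf$n_proteins)
    intens <- mean_pm_g[prot_genes, , drop = FALSE] *
      exp(matrix(rnorm(cf$n_proteins * 6, 0, cf$protein_sdlog), cf$n_proteins, 6))
    rownames(intens) <- proteins

    truth <- list(
      gene_profiles = tibble::tibble(
        gene_id = genes, profile = unname(profile_of),
        source = dplyr::case_when(
          genes %in% reg$gene_id ~ "target",
          genes %in% pool_genes ~ "pool",
          .default = NA_character_)),
      mirna_profiles = tibble::tibble(mirna_id = mirnas,
                                      profile = unname(mir_profile_of)),
      regulated = reg,
      protein_map = tibble::tibble(protein_id = proteins, gene_id = prot_genes),
      # positions 1,2 early, 3,4 late, 5 top (early-like), 6 bottom (late-like)
      groups = tibble::tibble(
        library_id = cf$library_ids,
        group = c(1L, 1L, 2L, 2L, 1L, 2L)),
      mean_pm_mrna = expr_tibble(mean_pm_g),
      mean_pm_mirna = expr_tibble(mean_pm_m))

    structure(list(
      mrna = expr_tibble(counts_g),
      mirna = expr_tibble(counts_m),
      protein = expr_tibble(intens),
      target_map = tm$map,
      truth = truth,
      config = cf), class = "sim_study")
  })
}

#' @export
print.sim_study <- function(x, ...) {
  cf <- x$config
  cat("Synthetic six-library study:", cf$n_genes, "genes,", cf$n_mirnas,
      "miRNAs,", cf$n_proteins, "proteins; seed", cf$seed, "\n")
  invisible(x)
}
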