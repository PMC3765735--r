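#' Pipeline configuration
#'
#' Collects file paths, series orders, thresholds and the seed for a full
#' pipeline run. Either provide input paths (`mrna`, and optionally
#' `mirna`, `protein`, `target_map`, `protein_map`, `interactions`) or a
#' [sim_config()] in `simulate`, in which case the study is generated and
#' its tables written under the output directory. Configurations round-trip
#' through YAML with [write_pipeline_config()] / [read_pipeline_config()].
#'
#' @param mrna,mirna,protein,target_map,protein_map,interactions Input file
#'   paths (TSV), or `NULL`.
#' @param simulate Optional [sim_config()] replacing the input paths.
#' @param development,internode Library ids in series order.
#' @param de,stem,screen Threshold objects ([de_thresholds()],
#'   [stem_config()], [screen_thresholds()]).
#' @param require_mirna_profile Should integration also require the miRNA
#'   to sit in a significant miRNA profile?
#' @param seed Integer seed for every stochastic stage.
#' @param out_dir Output directory.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(mrna = NULL, mirna = NULL, protein = NULL,
                            target_map = NULL, protein_map = NULL,
                            interactions = NULL, simulate = NULL,
                            development = DEV_ORDER,
                            internode = INTERNODE_ORDER,
                            de = de_thresholds(), stem = stem_config(),
                            screen = screen_thresholds(),
                            require_mirna_profile = FALSE,
                            seed = 1L, out_dir = "culmnet-out") {
  if (is.null(mrna) && is.null(simulate)) {
    abort("either an mRNA count table or a simulation config is required")
  }
  structure(list(
    mrna = mrna, mirna = mirna, protein = protein, target_map = target_map,
    protein_map = protein_map, interactions = interactions,
    simulate = simulate, development = development, internode = internode,
    de = de, stem = stem, screen = screen,
    require_mirna_profile = require_mirna_profile,
    seed = as.integer(seed), out_dir = out_dir), class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param config A `pipeline_config`.
#' @param path YAML file path.
#' @export
write_pipeline_config <- function(config, path) {
  x <- unclass(config)
  x$de <- unclass(x$de)
  x$stem <- unclass(x$stem)
  x$screen <- unclass(x$screen)
  if (!is.null(x$simulate)) x$simulate <- unclass(x$simulate)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_pipeline_config <- function(path) {
  x <- yaml::read_yaml(path)
  sim <- if (!is.null(x$simulate)) do.call(sim_config, x$simulate)
  pipeline_config(
    mrna = x$mrna, mirna = x$mirna, protein = x$protein,
    target_map = x$target_map, protein_map = x$protein_map,
    interactions = x$interactions, simulate = sim,
    development = x$development, internode = x$internode,
    de = do.call(de_thresholds, x$de), stem = do.call(stem_config, x$stem),
    screen = do.call(screen_thresholds, x$screen),
    require_mirna_profile = isTRUE(x$require_mirna_profile),
    seed = x$seed, out_dir = x$out_dir)
}

#' Read a two-column pair table
#'
#' @param path TSV with two id columns (e.g. miRNA, target gene).
#' @return Tibble with the file's two columns.
#' @export
read_pair_table <- function(path) {
  x <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                       progress = FALSE)
  if (ncol(x) < 2) abort("pair table needs two columns")
  x
}

#' Run the full pipeline
#'
#' Executes the stages in order: `simulate` (optional), `dge`, `profiles`
#' (development and internode series, mRNA and miRNA layers), `correlate`,
#' `enrich`, `integrate`, `network`, `ordinate`. Per-stage outputs are
#' written as TSV under the output directory together with a YAML manifest
#' recording the seed, package version, stage statuses, per-stage feature
#' counts and md5 hashes of every written file. Stages whose inputs are
#' missing (e.g. no target map) are skipped with a notice; any stage error
#' halts the run with a stage-named message.
#'
#' @param config A [pipeline_config()] (or path to its YAML).
#' @return Invisibly, a list with all stage results and the manifest.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  cf <- config
  dir.create(cf$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(seed = cf$seed,
                   version = as.character(utils::packageVersion("culmnet")),
                   stages = list())
  outputs <- character()
  res <- list()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(paste0("stage ", name, " failed: ", conditionMessage(e)))
    })
  }
  note <- function(name, status, counts = NULL) {
    manifest$stages[[name]] <<- list(status = status, counts = counts)
  }
  emit <- function(x, file) {
    path <- file.path(cf$out_dir, file)
    readr::write_tsv(x, path, progress = FALSE)
    outputs <<- c(outputs, path)
    path
  }

  # -- simulate ------------------------------------------------------------
  if (!is.null(cf$simulate)) {
    study <- stage("simulate", {
      sc <- cf$simulate
      sc$seed <- cf$seed
      simulate_study(sc)
    })
    cf$mrna <- emit(study$mrna, "input_mrna.tsv")
    cf$mirna <- emit(study$mirna, "input_mirna.tsv")
    cf$protein <- emit(study$protein, "input_protein.tsv")
    cf$target_map <- emit(study$target_map, "input_target_map.tsv")
    cf$protein_map <- emit(study$truth$protein_map, "input_protein_map.tsv")
    res$study <- study
    note("simulate", "completed", list(genes = nrow(study$mrna)))
  } else {
    note("simulate", "skipped (inputs supplied)")
  }

  mrna <- stage("dge", read_expression_matrix(cf$mrna, integer = TRUE))
  mirna <- if (!is.null(cf$mirna)) stage("dge", read_expression_matrix(cf$mirna, integer = TRUE))
  protein <- if (!is.null(cf$protein)) stage("dge", read_expression_matrix(cf$protein))

  # -- dge -----------------------------------------------------------------
  de <- stage("dge", call_de(mrna, cf$de))
  union <- de_union(de)
  emit(de, "de_mrna.tsv"); emit(de_summary(de), "de_mrna_summary.tsv")
  de_mirna <- NULL
  if (!is.null(mirna)) {
    de_mirna <- stage("dge", call_de(mirna, cf$de))
    emit(de_mirna, "de_mirna.tsv")
  }
  res$de <- de; res$de_mirna <- de_mirna; res$de_union <- union
  note("dge", "completed", list(n_union = length(union)))

  # -- profiles ------------------------------------------------------------
  fits <- stage("profiles", {
    feats <- if (length(union) >= 2) union  # fall back to all features
    f <- list(
      mrna_dev = cluster_profiles(mrna, cf$development, cf$stem,
                                  features = feats, seed = cf$seed),
      mrna_int = cluster_profiles(mrna, cf$internode, cf$stem,
                                  features = feats, seed = cf$seed))
    if (!is.null(mirna) && !is.null(de_mirna)) {
      mu <- de_union(de_mirna)
      if (length(mu) >= 2) {
        f$mirna_dev <- cluster_profiles(mirna, cf$development, cf$stem,
                                        features = mu, seed = cf$seed)
        f$mirna_int <- cluster_profiles(mirna, cf$internode, cf$stem,
                                        features = mu, seed = cf$seed)
      }
    }
    f
  })
  for (nm in names(fits)) emit(fits[[nm]]$stats, paste0("profiles_", nm, ".tsv"))
  mrna_members <- sort(unique(c(profile_members(fits$mrna_dev),
                                profile_members(fits$mrna_int))))
  mirna_members <- if (!is.null(fits$mirna_dev)) {
    sort(unique(c(profile_members(fits$mirna_dev),
                  profile_members(fits$mirna_int))))
  }
  res$profiles <- fits
  note("profiles", "completed",
       list(n_mrna_members = length(mrna_members),
            n_mirna_members = length(mirna_members)))

  # -- correlate -----------------------------------------------------------
  negative <- positive <- NULL
  if (!is.null(mirna) && !is.null(cf$target_map)) {
    tm <- read_pair_table(cf$target_map)
    negative <- stage("correlate",
                      screen_pairs(mirna, mrna, tm, "negative", cf$screen))
    emit(negative, "pairs_negative.tsv")
  }
  if (!is.null(protein) && !is.null(cf$protein_map)) {
    pmap <- read_pair_table(cf$protein_map)
    # source is the encoding gene, target the protein spot
    positive <- stage("correlate",
                      screen_pairs(mrna, protein, pmap[, c(2, 1)], "positive",
                                   cf$screen))
    emit(positive, "pairs_positive.tsv")
  }
  res$negative <- negative; res$positive <- positive
  if (is.null(negative) && is.null(positive)) {
    note("correlate", "skipped (no target or protein map)")
  } else {
    note("correlate", "completed",
         list(n_negative_pass = sum(negative$passes_screen %||% 0),
              n_positive_pass = sum(positive$passes_screen %||% 0)))
  }

  # -- enrich --------------------------------------------------------------
  if (!is.null(mirna) && !is.null(cf$target_map)) {
    enrich <- stage("enrich", {
      tm <- read_pair_table(cf$target_map)
      mirna_target_enrichment(mirna, mrna, tm, alpha = cf$screen$alpha,
                              min_present = cf$screen$min_present)
    })
    emit(enrich, "enrichment.tsv")
    res$enrichment <- enrich
    note("enrich", "completed", list(n_mirnas = nrow(enrich)))
  } else {
    note("enrich", "skipped (no target map)")
  }

  # -- integrate -----------------------------------------------------------
  if (!is.null(negative) || !is.null(positive)) {
    integrated <- stage("integrate", integrate_pairs(
      negative, positive, mrna_members,
      mirna_members = if (cf$require_mirna_profile) mirna_members,
      alpha = cf$screen$alpha))
    emit(integrated$pairs, "integrated_pairs.tsv")
    res$integrated <- integrated
    note("integrate", "completed", list(
      n_pairs = nrow(integrated$pairs), n_genes = length(integrated$genes)))
  } else {
    note("integrate", "skipped (no screened pairs)")
  }

  # -- network -------------------------------------------------------------
  if (!is.null(res$integrated)) {
    network <- stage("network", {
      inter <- if (!is.null(cf$interactions)) read_pair_table(cf$interactions)
      build_network(res$integrated, inter)
    })
    export_network(network, file.path(cf$out_dir, "network.sif"), "sif")
    export_network(network, file.path(cf$out_dir, "network.graphml"), "graphml")
    export_network(network, file.path(cf$out_dir, "network.tsv"), "tsv")
    outputs <- c(outputs, file.path(cf$out_dir, c("network.sif", "network.graphml",
                                                  "network.tsv", "network.tsv.nodes.tsv")))
    res$network <- network
    note("network", "completed", list(n_nodes = nrow(network$nodes),
                                      n_edges = nrow(network$edges)))
  } else {
    note("network", "skipped (no integrated set)")
  }

  # -- ordinate ------------------------------------------------------------
  ord <- stage("ordinate",
               ordinate(mrna, features = if (length(union) >= 2) union))
  emit(ord$scores, "ordination_mrna.tsv")
  res$ordination <- ord
  note("ordinate", "completed",
       list(partition = paste(ord$scores$cluster, collapse = "")))

  manifest$outputs <- as.list(unname(tools::md5sum(outputs)))
  names(manifest$outputs) <- basename(outputs)
  yaml::write_yaml(manifest, file.path(cf$out_dir, "manifest.yaml"))
  res$manifest <- manifest
  invisible(res)
}
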