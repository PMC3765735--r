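#' Build the typed integration network
#'
#' One node per unique gene, miRNA and protein of an integrated set; one
#' edge per retained pair (`represses`: miRNA to gene, weighted by `|r|`;
#' `encodes`: gene to protein, weighted by `|r|`), plus optional
#' `interacts` edges (weight 1) from a gene-gene interaction table,
#' added only between genes already in the network. Self-loops and
#' malformed interaction rows are skipped with a warning. Nodes and edges
#' are deterministically ordered (by type, then id).
#'
#' @param integrated An [integrate_pairs()] result.
#' @param interactions Optional two-column table of gene-gene interactions.
#' @param node_attributes Optional table whose first column is a node id;
#'   remaining columns (e.g. pre-computed functional annotations) are
#'   joined onto the node table.
#' @return Object of class `culm_network`: list with `nodes` (tibble `id`,
#'   `type`, `core_gene`, `cor_significant`, plus any joined attributes)
#'   and `edges` (tibble `from`, `to`, `type`, `weight`).
#' @export
build_network <- function(integrated, interactions = NULL,
                          node_attributes = NULL) {
  if (!inherits(integrated, "integrated_set")) abort("need an integrated_set")
  p <- integrated$pairs
  mirnas <- c(integrated$mirnas_known, integrated$mirnas_novel)
  sig_ids <- unique(c(p$source_id[p$cor_significant], p$target_id[p$cor_significant]))
  nodes <- tibble::tibble(
    id = c(integrated$genes, mirnas, integrated$proteins),
    type = rep(c("gene", "miRNA", "protein"),
               c(length(integrated$genes), length(mirnas),
                 length(integrated$proteins))))
  nodes$core_gene <- nodes$type == "gene"
  nodes$cor_significant <- nodes$id %in% sig_ids
  edges <- tibble::tibble(
    from = p$source_id, to = p$target_id,
    type = ifelse(p$type == "negative", "represses", "encodes"),
    weight = abs(p$r))
  if (!is.null(interactions) && nrow(interactions) > 0) {
    it <- tibble::as_tibble(interactions)
    a <- as.character(it[[1]]); b <- as.character(it[[2]])
    bad <- is.na(a) | is.na(b) | a == "" | b == "" | a == b
    if (any(bad)) warn(paste0(sum(bad), " malformed interaction row(s) skipped"))
    a <- a[!bad]; b <- b[!bad]
    genes <- nodes$id[nodes$type == "gene"]
    keep <- a %in% genes & b %in% genes
    if (any(keep)) {
      edges <- dplyr::bind_rows(edges, tibble::tibble(
        from = a[keep], to = b[keep], type = "interacts", weight = 1))
    }
  }
  edges <- dplyr::distinct(edges)
  if (!is.null(node_attributes)) {
    na_ <- tibble::as_tibble(node_attributes)
    names(na_)[1] <- "id"
    nodes <- dplyr::left_join(nodes, na_, by = "id")
  }
  nodes <- dplyr::arrange(nodes, .data$type, .data$id)
  edges <- dplyr::arrange(edges, .data$type, .data$from, .data$to)
  structure(list(nodes = nodes, edges = edges), class = "culm_network")
}

#' @export
print.culm_network <- function(x, ...) {
  cat("Integration network:", nrow(x$nodes), "nodes,", nrow(x$edges), "edges\n")
  print(table(x$nodes$type))
  invisible(x)
}

.as_igraph <- function(network) {
  igraph::graph_from_data_frame(network$edges, directed = TRUE,
                                vertices = network$nodes)
}

#' Export and re-import a network
#'
#' Writers are deterministic: the same network gives byte-identical files.
#' `sif` uses the edge type as the relation name, `tsv` writes the edge
#' list with attributes (plus a `<path>.nodes.tsv` node table), `graphml`
#' goes through igraph and round-trips all node and edge attributes.
#'
#' @param network A `culm_network`.
#' @param path Output file path.
#' @param format `"sif"`, `"graphml"` or `"tsv"`.
#' @return `path`, invisibly.
#' @export
export_network <- function(network, path, format = c("sif", "graphml", "tsv")) {
  if (!format[1] %in% c("sif", "graphml", "tsv")) abort(paste0("unknown format: ", format[1]))
  format <- match.arg(format)
  if (format == "sif") {
    lines <- paste(network$edges$from, network$edges$type, network$edges$to,
                   sep = "\t")
    writeLines(lines, path)
  } else if (format == "tsv") {
    readr::write_tsv(network$edges, path, progress = FALSE)
    readr::write_tsv(network$nodes, paste0(path, ".nodes.tsv"), progress = FALSE)
  } else {
    g <- .as_igraph(network)
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(path)
}

#' @rdname export_network
#' @export
read_network <- function(path, format = c("sif", "graphml", "tsv")) {
  if (!format[1] %in% c("sif", "graphml", "tsv")) abort(paste0("unknown format: ", format[1]))
  format <- match.arg(format)
  if (format == "sif") {
    parts <- strsplit(readLines(path), "\t")
    edges <- tibble::tibble(
      from = vapply(parts, `[`, "", 1),
      to = vapply(parts, `[`, "", 3),
      type = vapply(parts, `[`, "", 2))
    nodes <- tibble::tibble(id = sort(unique(c(edges$from, edges$to))))
    out <- list(nodes = nodes, edges = dplyr::arrange(edges, .data$type, .data$from, .data$to))
  } else if (format == "tsv") {
    edges <- readr::read_tsv(path, col_types = readr::cols(), progress = FALSE)
    nodes <- readr::read_tsv(paste0(path, ".nodes.tsv"), col_types = readr::cols(),
                             progress = FALSE)
    out <- list(nodes = tibble::as_tibble(nodes), edges = tibble::as_tibble(edges))
  } else {
    g <- igraph::read_graph(path, format = "graphml")
    nodes <- tibble::as_tibble(igraph::as_data_frame(g, "vertices"))
    nodes <- nodes[, names(nodes) != "id"]  # graphml's internal node id
    names(nodes)[names(nodes) == "name"] <- "id"
    edges <- tibble::as_tibble(igraph::as_data_frame(g, "edges"))
    nodes <- dplyr::arrange(nodes, .data$type, .data$id)
    edges <- dplyr::arrange(edges, .data$type, .data$from, .data$to)
    out <- list(nodes = nodes, edges = edges)
  }
  structure(out, class = "culm_network")
}
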