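#' Tidy profile-clustering results
#'
#' `tidy()` returns the per-profile statistics table; `glance()` a one-row
#' summary.
#'
#' @param x A `stem_fit`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.stem_fit <- function(x, ...) x$stats

#' @rdname tidy.stem_fit
#' @export
glance.stem_fit <- function(x, ...) {
  tibble::tibble(n_features = x$n, n_models = nrow(x$models),
                 n_significant = sum(x$stats$significant), alpha = x$alpha)
}

#' Tidy ordination results
#'
#' `tidy()` returns the sample scores with cluster labels; `glance()` the
#' variance explained by the leading axes.
#'
#' @param x A `culm_ordination`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.culm_ordination <- function(x, ...) x$scores

#' @rdname tidy.culm_ordination
#' @export
glance.culm_ordination <- function(x, ...) {
  tibble::tibble(method = x$method,
                 var_axis_1 = x$var_explained[1],
                 var_axis_2 = x$var_explained[2])
}

#' Tidy an integrated pair set
#'
#' `tidy()` returns the retained pairs; `glance()` the cardinalities the
#' integration reports (pairs, unique genes, known/novel miRNAs, proteins,
#' significantly correlated pairs).
#'
#' @param x An `integrated_set`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.integrated_set <- function(x, ...) x$pairs

#' @rdname tidy.integrated_set
#' @export
glance.integrated_set <- function(x, ...) {
  tibble::tibble(
    n_pairs = nrow(x$pairs),
    n_genes = length(x$genes),
    n_mirnas = length(x$mirnas_known) + length(x$mirnas_novel),
    n_mirnas_known = length(x$mirnas_known),
    n_mirnas_novel = length(x$mirnas_novel),
    n_proteins = length(x$proteins),
    n_cor_significant = sum(x$pairs$cor_significant))
}

#' Tidy a network
#'
#' `tidy()` returns the typed edge list; `glance()` node and edge counts.
#'
#' @param x A `culm_network`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.culm_network <- function(x, ...) x$edges

#' @rdname tidy.culm_network
#' @export
glance.culm_network <- function(x, ...) {
  tibble::tibble(n_nodes = nrow(x$nodes), n_edges = nrow(x$edges),
                 n_genes = sum(x$nodes$type == "gene"),
                 n_mirnas = sum(x$nodes$type == "miRNA"),
                 n_proteins = sum(x$nodes$type == "protein"))
}
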