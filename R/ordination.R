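#' Ordination of the six libraries
#'
#' Principal component analysis (default) or classical principal
#' coordinates on Euclidean distances of the same matrix; for Euclidean
#' geometry the two give identical axes up to sign. Features (typically
#' restricted to the union of differentially expressed features) are
#' log2(per-million + 1) transformed and standardized across libraries
#' before ordination. Axis signs follow a deterministic convention: the
#' largest-magnitude sample coordinate on each axis is positive. The
#' two-group sample partition is the k = 2 cut of a hierarchical clustering
#' of the same standardized matrix.
#'
#' @param x Count expression tibble.
#' @param features Optional feature subset (e.g. [de_union()]).
#' @param method `"pca"` or `"pcoa"`.
#' @param normalized Set `TRUE` if `x` is already depth-normalized.
#' @param distance,linkage Passed to [hierarchical_cluster()] for the
#'   partition.
#' @return Object of class `culm_ordination`: `scores` tibble
#'   (`library_id`, `axis_1` ... `axis_k`, `cluster`), `var_explained`,
#'   `dendrogram` (an `hclust`), `method`.
#' @export
ordinate <- function(x, features = NULL, method = c("pca", "pcoa"),
                     normalized = FALSE, distance = "correlation",
                     linkage = "average") {
  method <- match.arg(method)
  s <- .ordination_matrix(x, features, normalized)  # libraries x features
  if (method == "pca") {
    pc <- prcomp(s, center = TRUE, scale. = FALSE)
    k <- min(nrow(s) - 1, ncol(pc$x))
    coords <- pc$x[, seq_len(k), drop = FALSE]
    ve <- pc$sdev[seq_len(k)]^2 / sum(pc$sdev^2)
  } else {
    cmd <- cmdscale(dist(s), k = nrow(s) - 1, eig = TRUE)
    coords <- cmd$points
    ve <- cmd$eig[seq_len(ncol(coords))] / sum(pmax(cmd$eig, 0))
  }
  # deterministic sign: largest-magnitude coordinate positive per axis
  for (j in seq_len(ncol(coords))) {
    i <- which.max(abs(coords[, j]))
    if (coords[i, j] < 0) coords[, j] <- -coords[, j]
  }
  colnames(coords) <- paste0("axis_", seq_len(ncol(coords)))
  hc <- hierarchical_cluster(x, features = features, distance = distance,
                             linkage = linkage, k = 2, normalized = normalized)
  scores <- tibble::as_tibble(as.data.frame(coords))
  scores <- tibble::add_column(scores, library_id = rownames(s), .before = 1)
  scores$cluster <- hc$partition$cluster[match(scores$library_id,
                                               hc$partition$library_id)]
  structure(list(scores = scores, var_explained = as.numeric(ve),
                 dendrogram = hc$dendrogram, method = method),
            class = "culm_ordination")
}

# shared preprocessing: log2(per-million + 1), drop degenerate features,
# standardize each feature across libraries, return libraries x features
.ordination_matrix <- function(x, features, normalized) {
  x <- validate_expression(x)
  if (!normalized) x <- normalize_per_million(x)
  if (!is.null(features)) x <- x[x$feature_id %in% features, , drop = FALSE]
  m <- t(log2(expr_values(x) + 1))   # libraries x features
  sds <- apply(m, 2, sd)
  m <- m[, sds > 0, drop = FALSE]
  if (ncol(m) < 2) abort("fewer than 2 non-degenerate features")
  scale(m, center = TRUE, scale = TRUE)
}

#' Hierarchical clustering of the libraries
#'
#' Average-linkage (default) clustering of the standardized
#' log2(per-million + 1) feature matrix under correlation or Euclidean
#' distance, cut at `k` clusters.
#'
#' @inheritParams ordinate
#' @param distance `"correlation"` (1 - Pearson between library profiles)
#'   or `"euclidean"`.
#' @param linkage `"average"` or `"complete"`.
#' @param k Number of clusters for the cut.
#' @return List with `dendrogram` (`hclust`) and `partition` (tibble
#'   `library_id`, `cluster`).
#' @export
hierarchical_cluster <- function(x, features = NULL,
                                 distance = c("correlation", "euclidean"),
                                 linkage = c("average", "complete"),
                                 k = 2, normalized = FALSE) {
  distance <- match.arg(distance)
  linkage <- match.arg(linkage)
  m <- .ordination_matrix(x, features, normalized)
  if (k < 1 || k > nrow(m)) abort("invalid number of clusters")
  d <- if (distance == "correlation") as.dist(1 - cor(t(m))) else dist(m)
  hc <- hclust(d, method = linkage)
  part <- cutree(hc, k = k)
  list(dendrogram = hc,
       partition = tibble::tibble(library_id = rownames(m),
                                  cluster = unname(part)))
}

#' Do two sample partitions agree up to label swapping?
#'
#' @param partition Tibble with `library_id` and `cluster`.
#' @param reference Tibble with `library_id` and `group`.
#' @return `TRUE` when the partitions induce the same split.
#' @export
partition_agrees <- function(partition, reference) {
  m <- dplyr::inner_join(partition, reference, by = "library_id")
  if (nrow(m) != nrow(partition)) return(FALSE)
  tab <- table(m$cluster, m[[3]])
  sum(diag(tab)) == nrow(m) || sum(diag(tab[, rev(seq_len(ncol(tab)))])) == nrow(m)
}
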