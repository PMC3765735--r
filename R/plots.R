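#' Up/down regulated features per library pair
#'
#' Paired bar chart of up- and down-regulated feature counts for each
#' library comparison.
#'
#' @param de A [call_de()] result.
#' @return A ggplot object.
#' @export
plot_de_counts <- function(de) {
  s <- de_summary(de) |>
    tidyr::pivot_longer(c("n_up", "n_down"), names_to = "direction",
                        values_to = "n") |>
    dplyr::mutate(pair = paste(.data$lib_a, "vs", .data$lib_b),
                  direction = ifelse(.data$direction == "n_up", "up", "down"))
  ggplot2::ggplot(s, ggplot2::aes(x = .data$pair, y = .data$n,
                                  fill = .data$direction)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::scale_fill_manual(values = c(up = "black", down = "grey70")) +
    ggplot2::labs(x = NULL, y = "differentially expressed features") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Profile-clustering panel
#'
#' Mean log2-ratio series per model profile, faceted, with significant
#' profiles highlighted, ordered by p-value.
#'
#' @param object A `stem_fit`.
#' @param top Number of profiles shown (most significant first).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.stem_fit <- function(object, top = 12, ...) {
  st <- dplyr::arrange(object$stats, .data$p_value)
  st <- head(st, top)
  series <- expr_values(object$series)
  long <- purrr::map(seq_len(nrow(st)), function(i) {
    id <- st$profile_id[i]
    members <- object$assignments$feature_id[object$assignments$profile_id == id]
    if (length(members) == 0) return(NULL)
    m <- series[members, , drop = FALSE]
    tibble::tibble(
      profile = sprintf("profile %d (%s)\nA=%d E=%.1f", id, st$profile[i],
                        st$n_assigned[i], st$n_expected[i]),
      significant = st$significant[i],
      t = seq_len(ncol(m)), mean = colMeans(m))
  }) |> dplyr::bind_rows()
  long$profile <- factor(long$profile, unique(long$profile))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$t, y = .data$mean,
                                     colour = .data$significant)) +
    ggplot2::geom_line(linewidth = 1) +
    ggplot2::geom_hline(yintercept = 0, linetype = 3) +
    ggplot2::facet_wrap(~profile, scales = "free_y") +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "firebrick",
                                            `FALSE` = "grey50")) +
    ggplot2::scale_x_continuous(breaks = seq_len(max(long$t)),
                                labels = object$series_order) +
    ggplot2::labs(x = NULL, y = "mean log2 ratio") +
    ggplot2::theme_minimal()
}

#' Ordination scatter of the six libraries
#'
#' @param object A `culm_ordination`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.culm_ordination <- function(object, ...) {
  sc <- object$scores
  ve <- round(100 * object$var_explained[1:2], 1)
  ggplot2::ggplot(sc, ggplot2::aes(x = .data$axis_1, y = .data$axis_2,
                                   colour = factor(.data$cluster),
                                   label = .data$library_id)) +
    ggplot2::geom_point(size = 3) +
    ggplot2::geom_text(vjust = -1, show.legend = FALSE) +
    ggplot2::labs(x = paste0("axis 1 (", ve[1], "%)"),
                  y = paste0("axis 2 (", ve[2], "%)"),
                  colour = "cluster") +
    ggplot2::theme_minimal()
}

#' Saturation curve plot
#'
#' @param curve A [saturation_curve()] result.
#' @return A ggplot object.
#' @export
plot_saturation <- function(curve) {
  ggplot2::ggplot(curve, ggplot2::aes(x = .data$depth, y = .data$n_detected)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "subsampled tags", y = "detected features") +
    ggplot2::theme_minimal()
}
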