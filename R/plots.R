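#' @importFrom ggplot2 ggplot aes geom_col geom_tile geom_line geom_rug
#'   geom_segment geom_point facet_wrap labs scale_fill_manual
#'   scale_fill_gradient theme_minimal theme element_text
NULL

BASE_COLS <- c(A = "#66c2a5", T = "#fc8d62", G = "#8da0cb", C = "#e78ac3")

#' Plot a base-composition table
#'
#' Stacked base-percentage bars per species, faceted by position class.
#'
#' @param object a `composition_table` from [base_composition()].
#' @param ... ignored.
#' @return a ggplot object.
#' @method autoplot composition_table
#' @export
autoplot.composition_table <- function(object, ...) {
  long <- tidyr::pivot_longer(object, cols = c("A_pct", "T_pct", "G_pct",
                                               "C_pct"),
                              names_to = "base", values_to = "pct")
  long$base <- sub("_pct", "", long$base)
  ggplot(long, aes(x = .data$species, y = .data$pct, fill = .data$base)) +
    geom_col() +
    facet_wrap(~position, nrow = 1) +
    scale_fill_manual(values = BASE_COLS) +
    labs(x = NULL, y = "% of counted bases", fill = "base") +
    theme_minimal() +
    theme(axis.text.x = element_text(angle = 45, hjust = 1))
}

#' Plot a p-distance matrix
#'
#' @param object a `p_distance` from [p_distance_matrix()].
#' @param ... ignored.
#' @return a ggplot object (heatmap of pairwise p).
#' @method autoplot p_distance
#' @export
autoplot.p_distance <- function(object, ...) {
  full <- bind_rows(as_tibble(object),
                    object |> filter(.data$a != .data$b) |>
                      rename(a = "b", b = "a"))
  ggplot(full, aes(x = .data$a, y = .data$b, fill = .data$p)) +
    geom_tile() +
    ggplot2::geom_text(aes(label = sprintf("%.3f", .data$p)), size = 3) +
    scale_fill_gradient(low = "#f7fbff", high = "#2171b5") +
    labs(x = NULL, y = NULL, fill = "p-distance") +
    theme_minimal()
}

#' Plot per-column polymorphism density and diagnostic sites
#'
#' Polymorphic-column density in fixed bins along the alignment, with a rug
#' of species-diagnostic columns.
#'
#' @param object a `site_profile` from [site_profile()].
#' @param bin bin width in columns.
#' @param ... ignored.
#' @return a ggplot object.
#' @method autoplot site_profile
#' @export
autoplot.site_profile <- function(object, bin = 50L, ...) {
  object$bin <- (object$column - 1L) %/% bin
  dens <- object |>
    group_by(.data$bin) |>
    summarise(mid = mean(.data$column),
              density = mean(.data$is_polymorphic), .groups = "drop")
  diag_cols <- object[!is.na(object$diagnostic_for), ]
  p <- ggplot(dens, aes(x = .data$mid, y = .data$density)) +
    geom_line(color = "#2171b5") +
    labs(x = "alignment column", y = "polymorphic-site density") +
    theme_minimal()
  if (nrow(diag_cols)) {
    p <- p + geom_rug(data = diag_cols,
                      aes(x = .data$column, color = .data$diagnostic_for),
                      inherit.aes = FALSE, sides = "b") +
      labs(color = "diagnostic for")
  }
  p
}

#' Plot hypervariable windows
#'
#' @param object a `window_score` from [hypervariable_windows()].
#' @param ... ignored.
#' @return a ggplot object (one segment per merged window).
#' @method autoplot window_score
#' @export
autoplot.window_score <- function(object, ...) {
  object$label <- sprintf("%d-%d", object$start, object$end)
  ggplot(object, aes(y = stats::reorder(.data$label, .data$density))) +
    geom_segment(aes(x = .data$start, xend = .data$end,
                     yend = stats::reorder(.data$label, .data$density),
                     linewidth = .data$density), color = "#2171b5") +
    labs(x = "alignment column", y = NULL, linewidth = "density") +
    theme_minimal()
}

#' Plot a specificity matrix
#'
#' Tile plot of predicted amplification (positive / negative) for each
#' primer pair against each single-species template and mixture.
#'
#' @param object a `specificity_matrix` from [specificity_matrix()].
#' @param ... ignored.
#' @return a ggplot object.
#' @method autoplot specificity_matrix
#' @export
autoplot.specificity_matrix <- function(object, ...) {
  object$pair <- sprintf("%s (r%d)", object$target_species, object$pair_rank)
  ggplot(object, aes(x = .data$template_set, y = .data$pair,
                     fill = .data$positive)) +
    geom_tile(color = "white") +
    scale_fill_manual(values = c(`TRUE` = "#2171b5", `FALSE` = "grey85"),
                      labels = c(`TRUE` = "amplicon", `FALSE` = "none")) +
    labs(x = "template set", y = "primer pair", fill = NULL) +
    theme_minimal() +
    theme(axis.text.x = element_text(angle = 45, hjust = 1))
}
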