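#' Plot a root mask, optionally with its skeleton overlaid
#'
#' @param mask Logical root mask.
#' @param skeleton Optional `root_skeleton` to overlay.
#' @return A ggplot object.
#' @export
plot_mask <- function(mask, skeleton = NULL) {
  coords <- which(mask, arr.ind = TRUE)
  df <- tibble(row = coords[, 1L], col = coords[, 2L], layer = "root")
  if (!is.null(skeleton)) {
    sc <- which(skeleton$pixels, arr.ind = TRUE)
    df <- bind_rows(df, tibble(row = sc[, 1L], col = sc[, 2L],
                               layer = "skeleton"))
  }
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   colour = .data$layer)) +
    ggplot2::geom_point(shape = ".", show.legend = !is.null(skeleton)) +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_colour_manual(values = c(root = "grey40",
                                            skeleton = "red")) +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "column (px)", y = "row (px)", colour = NULL) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.kw_scan <- function(object, ...) {
  df <- tidy(object) %>% filter(.data$scanned)
  df$index <- seq_len(nrow(df))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$index, y = -log10(.data$p),
                                   colour = .data$linkage_group)) +
    ggplot2::geom_point() +
    ggplot2::geom_point(data = df[df$marker %in% object$focal$marker, ],
                        shape = 1, size = 3, colour = "black") +
    ggplot2::labs(x = "marker index",
                  y = expression(-log[10](p)),
                  colour = "linkage group",
                  title = paste("Kruskal-Wallis scan:", object$trait)) +
    ggplot2::theme_minimal()
}

#' Plot trait time-series with fitted exponential curves
#'
#' @param traits Long trait table (`plant_id`, `time_point`, trait columns).
#' @param trait Trait column to display.
#' @param rates Optional output of [growth_rates()] to annotate fitted `k`.
#' @return A ggplot object.
#' @export
plot_growth <- function(traits, trait = "total_length", rates = NULL) {
  p <- ggplot2::ggplot(traits,
                       ggplot2::aes(x = .data$time_point,
                                    y = .data[[trait]],
                                    group = .data$plant_id)) +
    ggplot2::geom_line(alpha = 0.5) +
    ggplot2::geom_point() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "imaging session", y = trait) +
    ggplot2::theme_minimal()
  if (!is.null(rates)) {
    lab <- rates %>% filter(.data$trait == .env$trait)
    p <- p + ggplot2::ggtitle(
      sprintf("%s: mean k = %.3f / session", trait, mean(lab$k, na.rm = TRUE)))
  }
  p
}
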