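#' Pairs-style summary plot of the four M-F indices
#'
#' A 4 x 4 panel matrix in the style of the figures that accompany the
#' indices: per-sex density curves of each index on the diagonal, two-color
#' scatterplots below the diagonal, and `r` / `r_p` (whole-sample and
#' sex-partialled correlations) printed above the diagonal. In panels that
#' pair sex-directionality with a typicality-family index, the quadrants of
#' sign disagreement are shaded and contain exactly the discordant-flagged
#' profiles.
#'
#' @param scores An `mf_scores` table (with its fitted model attached).
#' @param shade_discordant Shade the discordant quadrants in
#'   directionality-vs-typicality-family panels (default `TRUE`).
#' @param point_alpha,point_size Scatterplot point styling.
#' @return A `patchwork` object of 16 ggplot panels.
#' @export
summary_plot <- function(scores, shade_discordant = TRUE,
                         point_alpha = 0.4, point_size = 0.6) {
  idx <- c("mfd", "mft", "mfp", "mfc")
  labels <- c(mfd = "M-F(D)", mft = "M-F(T)", mfp = "M-F(P)", mfc = "M-F(C)")
  if (nrow(scores) == 0L) abort("Empty score table.")
  stopifnot(all(c(idx, "sex") %in% names(scores)))
  smry <- summarize_indices(scores)
  df <- tibble::as_tibble(scores)

  sex_scale <- ggplot2::scale_color_manual(
    values = c(female = "#C0392B", male = "#2C6FBB"), drop = FALSE)
  sex_fill <- ggplot2::scale_fill_manual(
    values = c(female = "#C0392B", male = "#2C6FBB"), drop = FALSE)
  theme_panel <- ggplot2::theme_minimal(base_size = 9) +
    ggplot2::theme(legend.position = "none",
                   panel.grid.minor = ggplot2::element_blank())

  # boundary value on each axis: indices cross sex at 0 except mfp at 0.5
  boundary <- c(mfd = 0, mft = 0, mfp = 0.5, mfc = 0)

  diag_panel <- function(v) {
    ggplot2::ggplot(df, ggplot2::aes(x = .data[[v]], fill = .data$sex,
                                     color = .data$sex)) +
      ggplot2::geom_density(alpha = 0.35) +
      sex_scale + sex_fill +
      ggplot2::labs(x = labels[[v]], y = NULL) +
      theme_panel
  }

  lower_panel <- function(xv, yv) {
    pair_has_mfd <- xor(xv == "mfd", yv == "mfd")
    g <- ggplot2::ggplot(df, ggplot2::aes(x = .data[[xv]], y = .data[[yv]]))
    if (shade_discordant && pair_has_mfd) {
      bx <- boundary[[xv]]; by <- boundary[[yv]]
      shade <- data.frame(
        xmin = c(-Inf, bx), xmax = c(bx, Inf),
        ymin = c(by, -Inf), ymax = c(Inf, by))
      g <- g + ggplot2::geom_rect(
        data = shade, inherit.aes = FALSE,
        ggplot2::aes(xmin = .data$xmin, xmax = .data$xmax,
                     ymin = .data$ymin, ymax = .data$ymax),
        fill = "grey80", alpha = 0.5)
    }
    g + ggplot2::geom_point(ggplot2::aes(color = .data$sex),
                            alpha = point_alpha, size = point_size) +
      sex_scale +
      ggplot2::labs(x = labels[[xv]], y = labels[[yv]]) +
      theme_panel
  }

  upper_panel <- function(xv, yv) {
    row <- dplyr::filter(smry$correlations,
                         (.data$index_x == xv & .data$index_y == yv) |
                           (.data$index_x == yv & .data$index_y == xv))
    lab <- sprintf("r = %.2f\nr_p = %.2f", row$r[1], row$r_p[1])
    ggplot2::ggplot() +
      ggplot2::annotate("text", x = 0, y = 0, label = lab, size = 3.2) +
      ggplot2::theme_void() +
      ggplot2::labs(x = NULL, y = NULL)
  }

  panels <- vector("list", 16L)
  k <- 0L
  for (i in seq_along(idx)) {      # row = y index
    for (j in seq_along(idx)) {    # col = x index
      k <- k + 1L
      panels[[k]] <- if (i == j) diag_panel(idx[i])
      else if (i > j) lower_panel(idx[j], idx[i])
      else upper_panel(idx[i], idx[j])
    }
  }
  patchwork::wrap_plots(panels, nrow = 4, ncol = 4)
}

#' @rdname summary_plot
#' @param object An `mf_scores` table.
#' @param ... Passed on to [summary_plot()].
#' @method autoplot mf_scores
#' @export
autoplot.mf_scores <- function(object, ...) summary_plot(object, ...)

#' Save a summary plot to file
#'
#' Thin wrapper over [summary_plot()] + [ggplot2::ggsave()]; the output
#' format (png/pdf/svg) follows the file extension.
#'
#' @inheritParams summary_plot
#' @param path Output file path.
#' @param width,height Figure size in inches.
#' @return `path`, invisibly.
#' @export
save_summary_plot <- function(scores, path, width = 9, height = 9, ...) {
  g <- summary_plot(scores, ...)
  ggplot2::ggsave(path, g, width = width, height = height)
  invisible(path)
}
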