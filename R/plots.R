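group_palette <- c(confirmed = "grey40", fkh_activated = "#d95f02",
                   fkh1_sensitive = "#7570b3", cen_proximal = "#1b9e77",
                   rdna = "#e7298a")

#' Chromosome signal profile with origin-group glyphs
#'
#' Line plot of a (multi-)strain profile along one chromosome, with
#' color-coded glyphs under the axis marking origins of each group —
#' the standard way replication profiles are displayed.
#'
#' @param profile A binned track tibble, optionally multi-strain.
#' @param chrom Chromosome to plot.
#' @param origins Optional origin set tibble for the glyph row.
#' @param groups Origin groups to mark.
#' @return A ggplot object.
#' @export
plot_profile <- function(profile, chrom, origins = NULL,
                         groups = c("fkh_activated", "cen_proximal")) {
  df <- dplyr::filter(profile, .data$chrom == !!chrom)
  if (nrow(df) == 0) abort(paste0("no bins on chromosome ", chrom))
  if (!"strain" %in% names(df)) df$strain <- "track"
  p <- ggplot2::ggplot(df, ggplot2::aes(x = (.data$start + .data$end) / 2,
                                        y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$strain)) +
    ggplot2::labs(x = paste0(chrom, " position (bp)"), y = "signal") +
    ggplot2::theme_minimal()
  if (!is.null(origins)) {
    long <- origin_group_long(origins, groups)
    marks <- dplyr::filter(
      dplyr::inner_join(long,
                        origins[, c("name", "chrom", "midpoint")], by = "name"),
      .data$chrom == !!chrom)
    if (nrow(marks)) {
      ymin <- -0.04 * max(df$value)
      p <- p + ggplot2::geom_point(
        data = marks,
        ggplot2::aes(x = .data$midpoint, y = ymin, color = .data$group),
        inherit.aes = FALSE, shape = 16, size = 1.6) +
        ggplot2::scale_color_manual(values = group_palette)
    }
  }
  p
}

#' Boxplots of window signal by origin group
#'
#' @param x A `group_comparison`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
#' @method autoplot group_comparison
autoplot.group_comparison <- function(x, ...) {
  long <- origin_group_long(x$origins, x$groups)
  present <- x$groups[x$groups %in% long$group]
  dropped <- setdiff(x$groups, present)
  if (length(dropped)) {
    warn(paste0("empty group omitted from plot: ", paste(dropped, collapse = ", ")))
  }
  df <- dplyr::inner_join(x$windows, long, by = "name",
                          relationship = "many-to-many")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$group, y = .data$signal,
                                   fill = .data$group)) +
    ggplot2::geom_boxplot(outlier.size = 0.5) +
    ggplot2::facet_grid(cols = ggplot2::vars(.data$strain)) +
    ggplot2::scale_fill_manual(values = group_palette, guide = "none") +
    ggplot2::labs(x = NULL, y = "window signal") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Scatter plot with per-group lines of best fit
#'
#' @param x A `scatter_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
#' @method autoplot scatter_fit
autoplot.scatter_fit <- function(x, ...) {
  d <- attr(x, "data")
  vars <- attr(x, "vars")
  fits <- tibble::as_tibble(unclass(x))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$x, y = .data$y,
                                  color = .data$group)) +
    ggplot2::geom_point(size = 0.8, alpha = 0.7) +
    ggplot2::geom_abline(data = fits,
                         ggplot2::aes(slope = .data$slope,
                                      intercept = .data$intercept,
                                      color = .data$group)) +
    ggplot2::labs(x = vars[["x"]], y = vars[["y"]]) +
    ggplot2::theme_minimal()
}

#' Heatmap of feature-centered signal
#'
#' @param x A `heatmap_matrix`.
#' @param ... Unused.
#' @return A ggplot object (tiles; rows in matrix order).
#' @export
#' @method autoplot heatmap_matrix
autoplot.heatmap_matrix <- function(x, ...) {
  df <- tidy.heatmap_matrix(x)
  df$name <- factor(df$name, levels = rev(rownames(x)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$offset, y = .data$name,
                                   fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(na.value = "grey90") +
    ggplot2::labs(x = "offset from feature midpoint (bp)", y = NULL,
                  fill = "signal") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank())
}
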