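# ggplot2 views of the genome scan: per-chromosome SNP-index tracks for the
# two pools and the delta track, with optional band and candidate-region
# shading.

#' Plot the sliding-window SNP-index tracks
#'
#' Three stacked tracks per chromosome -- Y-pool index, G-pool index, and
#' delta-SNP-index -- with optional null-band bounds on the delta track and
#' shaded candidate regions.
#'
#' @param windows A `bsa_windows` tibble.
#' @param band Optional `bsa_null_band`; its bounds at the median window
#'   depth are drawn on the delta track.
#' @param regions Optional `bsa_regions` to shade.
#' @param level Band level to draw.
#' @return A ggplot object.
#' @export
plot_snp_index <- function(windows, band = NULL, regions = NULL,
                           level = 0.95) {
  stopifnot(inherits(windows, "bsa_windows"))
  w <- windows[!windows$empty, ]
  long <- tidyr::pivot_longer(
    w, c("mean_index_y", "mean_index_g", "mean_delta"),
    names_to = "track", values_to = "value")
  long$track <- factor(long$track,
                       levels = c("mean_index_y", "mean_index_g", "mean_delta"),
                       labels = c("Y-pool SNP-index", "G-pool SNP-index",
                                  "Delta SNP-index"))
  long$mid <- (long$start + long$end) / 2
  p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$mid / 1e6,
                                          y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.3, colour = "grey30") +
    ggplot2::facet_grid(track ~ chrom, scales = "free") +
    ggplot2::labs(x = "Position (Mb)", y = NULL) +
    ggplot2::theme_bw()
  if (!is.null(regions) && nrow(regions) > 0) {
    shade <- as_tibble(regions)
    p <- p + ggplot2::geom_rect(
      data = shade,
      ggplot2::aes(xmin = .data$start / 1e6, xmax = .data$end / 1e6),
      ymin = -Inf, ymax = Inf, fill = "gold", alpha = 0.3,
      inherit.aes = FALSE)
  }
  if (!is.null(band)) {
    b <- band[abs(band$level - level) < 1e-9, ]
    d <- stats::median(w$mean_depth, na.rm = TRUE)
    bi <- b[which.min(abs(b$depth - d)), ]
    hl <- tibble(track = factor("Delta SNP-index",
                                levels = levels(long$track)),
                 lower = bi$lower, upper = bi$upper)
    p <- p +
      ggplot2::geom_hline(data = hl, ggplot2::aes(yintercept = .data$upper),
                          linetype = 2, colour = "red") +
      ggplot2::geom_hline(data = hl, ggplot2::aes(yintercept = .data$lower),
                          linetype = 2, colour = "red")
  }
  p
}

#' @rdname plot_snp_index
#' @param object A `bsa_windows` tibble.
#' @param ... Passed on to [plot_snp_index()].
#' @export
autoplot.bsa_windows <- function(object, ...) {
  plot_snp_index(object, ...)
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
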