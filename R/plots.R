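# ggplot2 views of the main result types.

#' Plot one subject's log2-ratio track with envelope and loss calls
#'
#' Raw ratios as points, the moving-average line, the reference panel's
#' center - 1 SD band edges, and called loss segments as red bars — the
#' standard aCGH profile view.
#'
#' @param tracks Wide log2-ratio tibble.
#' @param manifest Tiling probe manifest.
#' @param subject Subject column to plot.
#' @param envelope Optional envelope from [build_reference_envelope()].
#' @param segments Optional call tibble; the subject's loss segments are
#'   drawn as red bars.
#' @param window Moving-average window for the smoothed line.
#' @return A ggplot object, faceted by chromosome.
#' @export
plot_log2_track <- function(tracks, manifest, subject, envelope = NULL,
                            segments = NULL, window = 11) {
  df <- tibble::tibble(
    chrom = manifest$chrom,
    pos = (manifest$start + manifest$end) / 2,
    raw = tracks[[subject]],
    smoothed = moving_average(tracks, window, manifest)[[subject]])
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$pos)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$raw),
                        colour = "grey60", size = 0.5, na.rm = TRUE) +
    ggplot2::geom_line(ggplot2::aes(y = .data$smoothed), na.rm = TRUE) +
    ggplot2::facet_wrap(~chrom, scales = "free_x") +
    ggplot2::labs(x = "genome position (bp)", y = "log2 ratio",
                  title = paste("aCGH profile:", subject)) +
    ggplot2::theme_minimal()
  if (!is.null(envelope)) {
    env <- dplyr::bind_cols(df[c("chrom", "pos")],
                            envelope[c("center", "scale")])
    p <- p +
      ggplot2::geom_line(data = env, colour = "steelblue", alpha = 0.6,
                         ggplot2::aes(y = .data$center - .data$scale)) +
      ggplot2::geom_line(data = env, colour = "steelblue", alpha = 0.6,
                         ggplot2::aes(y = .data$center + .data$scale))
  }
  if (!is.null(segments)) {
    seg <- segments[segments$subject_id == subject &
                      segments$state == "loss", ]
    if (nrow(seg) > 0) {
      p <- p + ggplot2::geom_segment(
        data = seg, colour = "red", linewidth = 2,
        ggplot2::aes(x = .data$start, xend = .data$end,
                     y = -1.4, yend = -1.4))
    }
  }
  p
}

#' Heatmap of region loss status across subjects
#'
#' @param status Long status tibble (`subject_id`, `region`, `status`,
#'   optionally `group` for faceting).
#' @return A ggplot object.
#' @export
plot_region_status <- function(status) {
  p <- ggplot2::ggplot(status, ggplot2::aes(
    x = .data$region, y = .data$subject_id, fill = .data$status)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_manual(values = c(
      loss = "firebrick", unchanged = "grey85", gain = "goldenrod",
      missing = "white")) +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank())
  if ("group" %in% names(status)) {
    p <- p + ggplot2::facet_wrap(~group, scales = "free_y")
  }
  p
}

#' Forest plot of per-region odds ratios
#'
#' @param object A `cnv_association_report`.
#' @param ... Unused.
#' @return A ggplot object: OR point estimates with confidence bars on a
#'   log axis.
#' @export
autoplot.cnv_association_report <- function(object, ...) {
  pr <- object$per_region
  ggplot2::ggplot(pr, ggplot2::aes(x = .data$odds_ratio,
                                   y = .data$region)) +
    ggplot2::geom_vline(xintercept = 1, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$conf_low, xmax = .data$conf_high),
      height = 0.15) +
    ggplot2::geom_point(size = 2) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "odds ratio (log scale)", y = NULL,
                  title = "Copy-number loss: case-control odds ratios") +
    ggplot2::theme_minimal()
}
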