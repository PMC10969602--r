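#' Plot an axial slice of a field map
#'
#' @param field A [field_map()].
#' @param slice 1-based index along the third (B0) axis; default middle.
#' @param mask Optional [brain_mask()]; out-of-mask voxels are blanked.
#' @return A ggplot object.
#' @export
plot_field_slice <- function(field, slice = NULL, mask = NULL) {
  dims <- dim(field$data)
  if (is.null(slice)) slice <- ceiling(dims[3] / 2)
  sl <- field$data[, , slice]
  if (!is.null(mask)) sl[!mask$data[, , slice]] <- NA
  df <- tidyr::expand_grid(i = seq_len(dims[1]), j = seq_len(dims[2]))
  df$hz <- as.vector(sl)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$i, y = .data$j,
                                   fill = .data$hz)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient2(low = "#313695", mid = "white",
                                  high = "#a50026", na.value = "grey95") +
    ggplot2::coord_fixed(ratio = field$spacing[2] / field$spacing[1]) +
    ggplot2::labs(x = NULL, y = NULL, fill = "Hz",
                  title = sprintf("off-resonance, slice %d", slice)) +
    ggplot2::theme_minimal()
}

#' Box plot of a cohort metric by shim method
#'
#' @param object A `shim_study` from [run_study()].
#' @param metric `"sd_after_hz"` or `"coverage_pct"`.
#' @param resolution Resolution label to show for coverage metrics.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method
autoplot.shim_study <- function(object, metric = "coverage_pct",
                                resolution = NULL, ...) {
  df <- object$results
  if (is.null(resolution)) resolution <- df$resolution[1]
  df <- dplyr::filter(df, .data$resolution == !!resolution)
  order <- c("SH2", "IPRES32", "SH3", "SH4", "SH5", "UNIC51")
  df$method <- factor(df$method, levels = intersect(order,
                                                    unique(df$method)))
  lab <- if (metric == "sd_after_hz") "residual field SD (Hz)"
         else sprintf("brain coverage (%%) at %s", resolution)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$method,
                                   y = .data[[metric]])) +
    ggplot2::geom_boxplot(fill = "#74add1", alpha = 0.7) +
    ggplot2::labs(x = NULL, y = lab) +
    ggplot2::theme_minimal()
}

#' Linewidth map of a coverage result
#'
#' Tile plot of per-MRSI-voxel linewidth for one block slice, usable voxels
#' outlined.
#'
#' @param object A `coverage_result`.
#' @param bk Block-slice index along the third axis; default middle brain
#'   slice.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method
autoplot.coverage_result <- function(object, bk = NULL, ...) {
  df <- object$blocks
  if (is.null(bk)) {
    brain_bk <- df$bk[df$is_brain]
    bk <- round(stats::median(brain_bk))
  }
  df <- dplyr::filter(df, .data$bk == !!bk, .data$is_brain)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$bi, y = .data$bj,
                                   fill = .data$linewidth_hz,
                                   colour = .data$usable)) +
    ggplot2::geom_tile(linewidth = 0.6) +
    ggplot2::scale_fill_viridis_c(direction = -1) +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "black",
                                            `FALSE` = "transparent")) +
    ggplot2::labs(x = NULL, y = NULL, fill = "linewidth (Hz)",
                  colour = "usable",
                  title = sprintf("MRSI voxels, block slice %d", bk)) +
    ggplot2::theme_minimal()
}
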