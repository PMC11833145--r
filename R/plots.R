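#' Plot an axial slice of a volume or label map
#'
#' @param volume An [image_volume()] or label map.
#' @param slice Slice index along z (default: middle slice).
#' @param discrete Render as discrete labels (default for label maps).
#' @return A ggplot.
#' @export
plot_slice <- function(volume, slice = NULL,
                       discrete = inherits(volume, "label_map")) {
  vs <- voxel_size(volume)
  n <- dim(volume)
  slice <- slice %||% (floor(n[3] / 2) + 1L)
  d <- expand.grid(x = seq_len(n[1]), y = seq_len(n[2]))
  d$value <- as.numeric(volume[, , slice])
  d$x <- (d$x - (n[1] + 1) / 2) * vs[1]
  d$y <- (d$y - (n[2] + 1) / 2) * vs[2]
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$x, y = .data$y))
  if (discrete) {
    p <- p + ggplot2::geom_raster(ggplot2::aes(fill = factor(.data$value))) +
      ggplot2::labs(fill = "label")
  } else {
    p <- p + ggplot2::geom_raster(ggplot2::aes(fill = .data$value)) +
      ggplot2::scale_fill_viridis_c()
  }
  p + ggplot2::coord_fixed() +
    ggplot2::labs(x = "x (mm)", y = "y (mm)")
}
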