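#' Plot one axial slice of a volume with an optional mask overlay
#'
#' A quick-look raster of slice `z` (third axis) with mask voxels outlined
#' in colour — handy for inspecting phantoms, predictions and ground truth.
#'
#' @param vol A [volume_image()] or 3D array.
#' @param mask Optional [binary_mask()] (or array) on the same grid.
#' @param z Slice index; defaults to the middle slice.
#' @param mask_colour Overlay colour.
#' @return A ggplot object.
#' @export
plot_slice <- function(vol, mask = NULL, z = NULL, mask_colour = "yellow") {
  arr <- if (inherits(vol, "volume_image")) vol$voxels else vol
  if (is.null(z)) z <- ceiling(dim(arr)[3] / 2)
  sl <- arr[, , z]
  df <- tidyr::expand_grid(x = seq_len(nrow(sl)), y = seq_len(ncol(sl)))
  df$intensity <- as.vector(sl)
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$intensity)) +
    ggplot2::scale_fill_gradient(low = "black", high = "white") +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = sprintf("slice z = %d", z)) +
    ggplot2::theme_void()
  if (!is.null(mask)) {
    mar <- if (inherits(mask, "volume_image")) mask$voxels else mask
    msl <- mar[, , z]
    md <- df[as.vector(msl) > 0, , drop = FALSE]
    if (nrow(md)) {
      p <- p + ggplot2::geom_tile(data = md, fill = NA,
                                  colour = mask_colour, linewidth = 0.2)
    }
  }
  p
}
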