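#' Whole-cell mask from a reference image
#'
#' Otsu-thresholds the reference image (typically the sum of both channels),
#' keeps the largest connected component and fills its holes. When several
#' cells are present only the largest is analysed — a documented limitation
#' of the per-cell design.
#'
#' @param reference_frame Numeric 2D intensity matrix; must not be constant.
#' @return A logical matrix marking the cell footprint.
#' @export
cell_mask <- function(reference_frame) {
  if (!is.matrix(reference_frame))
    stop("reference_frame must be a 2D matrix", call. = FALSE)
  .segment_cell(reference_frame)
}

#' Pearson colocalization of two channels within a cell mask
#'
#' Product-moment correlation of the paired pixel intensities of the two
#' channels over the masked pixels. Values near 1 indicate reliable
#' colocalization; values near zero indicate uncorrelated distributions.
#' Scatter pairs are returned in row-major pixel order for plotting channel 1
#' on the x-axis against channel 2 on the y-axis.
#'
#' @param channel1,channel2 Numeric 2D matrices of identical shape.
#' @param mask Logical matrix selecting the analysed pixels; default uses
#'   [cell_mask()] on the channel sum.
#' @param background_offset Constant subtracted from both channels before
#'   correlating (default 0; the correlation itself is invariant to offsets,
#'   the option only affects the returned scatter).
#' @return An object of class `coloc_result`: list with `pearson_r`,
#'   `n_pixels` and `scatter` (two-column matrix of paired intensities).
#' @examples
#' a <- matrix(runif(400), 20); m <- matrix(TRUE, 20, 20)
#' pearson_coloc(a, a, m)$pearson_r  # 1
#' @export
pearson_coloc <- function(channel1, channel2, mask = NULL,
                          background_offset = 0) {
  if (!identical(dim(channel1), dim(channel2)))
    stop("channel shapes differ", call. = FALSE)
  if (is.null(mask)) mask <- cell_mask(channel1 + channel2)
  if (!identical(dim(mask), dim(channel1)))
    stop("mask shape differs from the channels", call. = FALSE)
  # row-major order to match scatterplot convention
  sel <- which(t(mask))
  x <- t(channel1)[sel] - background_offset
  y <- t(channel2)[sel] - background_offset
  if (length(x) < 2)
    stop("need at least 2 masked pixels", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("undefined correlation: a channel has zero variance in the mask",
         call. = FALSE)
  structure(
    list(pearson_r = stats::cor(x, y), n_pixels = length(x),
         scatter = cbind(channel1 = x, channel2 = y)),
    class = "coloc_result"
  )
}

#' @export
print.coloc_result <- function(x, ...) {
  cat(sprintf("coloc_result: Pearson R = %.3f over %d pixels\n",
              x$pearson_r, x$n_pixels))
  invisible(x)
}
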