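#' Euclidean distance map of a binary mask
#'
#' For every foreground pixel, the exact Euclidean distance (in pixels) to
#' the nearest background pixel; background pixels are 0. Pixels outside
#' the raster count as background, so an isolated foreground pixel and any
#' border foreground pixel have value 1. Computed with the exact
#' distance transform of \pkg{EBImage} on a background-padded copy.
#'
#' @param mask logical matrix, `TRUE` = foreground.
#' @param strict_imagej_edm if `TRUE`, emulate an 8-bit distance image:
#'   values are rounded to the nearest integer (half away from zero) and
#'   clipped at 255. The default keeps exact real distances; quantization
#'   is a storage artifact of the original tooling, not part of the
#'   method.
#' @return Numeric matrix of the same dimensions, non-negative, zero
#'   exactly on background.
#' @export
distance_map <- function(mask, strict_imagej_edm = FALSE) {
  stopifnot(is.logical(mask))
  h <- nrow(mask); w <- ncol(mask)
  if (!any(mask)) return(matrix(0, h, w))
  padded <- pad1(mask * 1, 0)
  dm <- as.matrix(EBImage::distmap(padded, metric = "euclidean"))
  dm <- dm[2:(h + 1L), 2:(w + 1L), drop = FALSE]
  if (strict_imagej_edm) dm <- pmin(round_half_away(dm), 255)
  dm
}
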