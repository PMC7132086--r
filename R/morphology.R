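#' Threshold a micrograph into a binary mask
#'
#' @param m single-channel [micrograph].
#' @param threshold integer intensity in 0..255.
#' @param polarity `"dark"`: foreground (candidate cell footprint) is every
#'   pixel with intensity `<= threshold`; `"bright"`: intensity
#'   `> threshold`.
#' @return Logical matrix of the same dimensions; `TRUE` = foreground.
#' @export
binarize <- function(m, threshold, polarity = c("dark", "bright")) {
  stopifnot(inherits(m, "micrograph"), m$channels == 1L)
  polarity <- match.arg(polarity)
  if (threshold < 0 || threshold > 255) {
    stop("`threshold` must be in 0..255", call. = FALSE)
  }
  if (polarity == "dark") m$pixels <= threshold else m$pixels > threshold
}

# Number of TRUE 8-neighbours of every pixel; pixels outside the raster
# count as FALSE. Vectorised via a zero-padded copy.
.neighbor_sum <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  p <- pad1(mask * 1L, 0L)
  r <- 2:(h + 1L); cc <- 2:(w + 1L)
  p[r - 1L, cc - 1L] + p[r - 1L, cc] + p[r - 1L, cc + 1L] +
  p[r,      cc - 1L] +                 p[r,      cc + 1L] +
  p[r + 1L, cc - 1L] + p[r + 1L, cc] + p[r + 1L, cc + 1L]
}

#' Iterated counted-neighbour binary erosion
#'
#' One iteration removes every foreground pixel with at least
#' `neighbor_count` background 8-neighbours; pixels outside the raster
#' count as background, so the mask also erodes inward from the border.
#' With `neighbor_count = 1` this is classical erosion by the 3x3 box.
#'
#' @param mask logical matrix, `TRUE` = foreground.
#' @param iterations number of erosion passes (>= 1).
#' @param neighbor_count 1..8, background-neighbour quota for removal.
#' @return Logical matrix of the same dimensions.
#' @export
binary_erode <- function(mask, iterations, neighbor_count = 1L) {
  stopifnot(is.logical(mask), iterations >= 1, neighbor_count %in% 1:8)
  for (i in seq_len(iterations)) {
    mask <- mask & (8L - .neighbor_sum(mask) < neighbor_count)
  }
  mask
}

#' Iterated counted-neighbour binary dilation
#'
#' Dual of [binary_erode()]: one iteration promotes every background pixel
#' with at least `neighbor_count` foreground 8-neighbours. Pixels outside
#' the raster count as background and never contribute.
#'
#' @inheritParams binary_erode
#' @return Logical matrix of the same dimensions.
#' @export
binary_dilate <- function(mask, iterations, neighbor_count = 1L) {
  stopifnot(is.logical(mask), iterations >= 1, neighbor_count %in% 1:8)
  for (i in seq_len(iterations)) {
    mask <- mask | (.neighbor_sum(mask) >= neighbor_count)
  }
  mask
}

#' Iterated binary opening
#'
#' `iterations` erosion passes followed by `iterations` dilation passes.
#' Removes protrusions and inter-footprint necks narrower than the
#' effective scale, so touching cell footprints separate into distinct
#' blobs, while blobs that survive keep (approximately) their size.
#'
#' @inheritParams binary_erode
#' @param iterations number of erosion passes and of dilation passes.
#' @return Logical matrix of the same dimensions; always a subset of the
#'   input foreground.
#' @export
binary_open <- function(mask, iterations, neighbor_count = 1L) {
  eroded <- binary_erode(mask, iterations, neighbor_count)
  if (!any(eroded)) return(eroded)
  binary_dilate(eroded, iterations, neighbor_count)
}
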