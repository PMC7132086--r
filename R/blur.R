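# Banded row-convolution operator for one image dimension: a sparse n x n
# matrix whose row i holds the Gaussian kernel centred at i, truncated at
# the raster edge and renormalised so every row sums to 1 (no padding
# bias; the image mean is preserved up to border redistribution).
.gauss_band <- function(n, sigma) {
  hw <- ceiling(3.5 * sigma)
  offs <- (-hw):hw
  wts <- stats::dnorm(offs, sd = sigma)
  i <- rep(seq_len(n), each = length(offs))
  j <- i + rep(offs, times = n)
  keep <- j >= 1L & j <= n
  K <- Matrix::sparseMatrix(i = i[keep], j = j[keep],
                            x = rep(wts, times = n)[keep], dims = c(n, n))
  Matrix::Diagonal(n, 1 / Matrix::rowSums(K)) %*% K
}

#' Gaussian smoothing of a single-channel micrograph
#'
#' Separable Gaussian convolution with standard deviation `sigma_px`
#' pixels and kernel half-width `ceiling(3.5 * sigma_px)`. At the raster
#' border the truncated kernel is renormalised, which keeps the image mean
#' within one intensity level of the input. The result is re-quantized to
#' 8-bit integers (round half away from zero).
#'
#' @param m single-channel [micrograph].
#' @param sigma_px positive Gaussian standard deviation in pixels.
#' @return A smoothed [micrograph] with 8-bit intensities.
#' @export
gaussian_blur <- function(m, sigma_px) {
  stopifnot(inherits(m, "micrograph"))
  if (m$channels != 1L) {
    stop("gaussian_blur requires a single-channel micrograph", call. = FALSE)
  }
  assert_scalar_positive(sigma_px, "sigma_px")
  h <- nrow(m$pixels); w <- ncol(m$pixels)
  out <- .gauss_band(h, sigma_px) %*% m$pixels %*% Matrix::t(.gauss_band(w, sigma_px))
  out <- pmin(pmax(round_half_away(as.matrix(out)), 0), 255)
  micrograph(out, m$pixel_size_um, m$source_id)
}
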