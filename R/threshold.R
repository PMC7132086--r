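#' 256-bin intensity histogram of a single-channel micrograph
#'
#' @param m a single-channel [micrograph] with 8-bit intensities.
#' @return Integer vector of length 256; element `i` counts pixels with
#'   intensity `i - 1`.
#' @export
intensity_histogram <- function(m) {
  stopifnot(inherits(m, "micrograph"))
  if (m$channels != 1L) {
    stop("intensity_histogram requires a single-channel micrograph",
         call. = FALSE)
  }
  tabulate(as.integer(m$pixels) + 1L, nbins = 256L)
}

# Strict interior local maxima of a length-256 vector: bins 2..255 whose
# two neighbours are both strictly lower. Edge bins never qualify.
.mode_count <- function(h) {
  n <- length(h)
  core <- 2:(n - 1)
  which(h[core] > h[core - 1] & h[core] > h[core + 1])  + 1L
}

#' Minimum-method histogram auto-threshold
#'
#' The histogram-minimum thresholding rule: a real-valued working copy of
#' the 256-bin histogram is repeatedly smoothed with a 3-bin moving average
#' (edges replicated) until exactly two strict local maxima remain; the
#' threshold is the first bin `t` strictly between the two peaks where the
#' smoothed histogram stops descending, i.e. `h[t-1] > h[t]` and
#' `h[t+1] >= h[t]`. Intended for bimodal intensity distributions such as
#' dark cell-contact footprints against a brighter inter-cell phase.
#'
#' @param histogram integer vector of 256 non-negative bin counts with a
#'   positive total, as from [intensity_histogram()].
#' @param source_id label used in the error message when no threshold is
#'   found.
#' @param max_iterations smoothing-iteration cap; histograms that never
#'   become bimodal (uniform, single-peaked) raise a "threshold not found"
#'   error when the cap is reached.
#' @return Integer threshold intensity in 0..255.
#' @export
minimum_autothreshold <- function(histogram, source_id = "image",
                                  max_iterations = 10000L) {
  if (length(histogram) != 256L || any(histogram < 0) || sum(histogram) <= 0) {
    stop("`histogram` must be 256 non-negative counts with a positive total",
         call. = FALSE)
  }
  h <- as.numeric(histogram)
  n <- 256L
  iter <- 0L
  repeat {
    peaks <- .mode_count(h)
    if (length(peaks) == 2L) break
    if (iter >= max_iterations) {
      stop(sprintf("threshold not found for '%s': histogram did not become bimodal within %d smoothing iterations",
                   source_id, max_iterations), call. = FALSE)
    }
    h <- (c(h[1], h[-n]) + h + c(h[-1], h[n])) / 3
    iter <- iter + 1L
  }
  for (t in (peaks[1] + 1L):(peaks[2] - 1L)) {
    if (h[t - 1L] > h[t] && h[t + 1L] >= h[t]) {
      return(t - 1L)  # bin index -> intensity
    }
  }
  stop(sprintf("threshold not found for '%s': no valley between the two modes",
               source_id), call. = FALSE)
}
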