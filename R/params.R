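#' Pipeline parameter set
#'
#' The five operator parameters of the counting pipeline, plus the two
#' behaviour flags. Usually produced by [derive_params()]; construct
#' directly only to override individual values.
#'
#' @param sigma_px Gaussian smoothing standard deviation in pixels.
#' @param erode_iterations iterations of counted-neighbour binary erosion.
#' @param open_iterations iterations of binary opening (erosion passes
#'   followed by the same number of dilation passes).
#' @param noise_tolerance maxima-detection prominence tolerance, in
#'   distance-map units (pixels of Euclidean distance).
#' @param neighbor_count 1..8: a pixel flips when at least this many of its
#'   8 neighbours belong to the other phase. The default 1 gives classical
#'   3x3 erosion/dilation.
#' @param polarity which side of the threshold is cell contact footprint:
#'   `"dark"` (intensity <= threshold, the default) or `"bright"`.
#' @param exclude_edge_maxima drop maxima whose tolerance region touches
#'   the raster border. Default `FALSE`: border-cut cells are counted.
#' @param strict_imagej_edm quantize the distance map to 8-bit integers
#'   (round half away, clip at 255) before maxima detection, emulating
#'   tools that store the distance map as an 8-bit image.
#' @return An object of class `pipeline_params`.
#' @seealso [derive_params()], [count_cells()]
#' @export
pipeline_params <- function(sigma_px, erode_iterations, open_iterations,
                            noise_tolerance, neighbor_count = 1L,
                            polarity = c("dark", "bright"),
                            exclude_edge_maxima = FALSE,
                            strict_imagej_edm = FALSE) {
  polarity <- match.arg(polarity)
  ints <- c(sigma_px = sigma_px, erode_iterations = erode_iterations,
            open_iterations = open_iterations,
            noise_tolerance = noise_tolerance,
            neighbor_count = neighbor_count)
  if (any(ints < 1) || any(ints != round(ints))) {
    stop("all pipeline parameters must be integers >= 1", call. = FALSE)
  }
  if (neighbor_count > 8) {
    stop("`neighbor_count` must be in 1..8", call. = FALSE)
  }
  structure(
    list(sigma_px = as.integer(sigma_px),
         erode_iterations = as.integer(erode_iterations),
         open_iterations = as.integer(open_iterations),
         noise_tolerance = as.integer(noise_tolerance),
         neighbor_count = as.integer(neighbor_count),
         polarity = polarity,
         exclude_edge_maxima = isTRUE(exclude_edge_maxima),
         strict_imagej_edm = isTRUE(strict_imagej_edm)),
    class = "pipeline_params"
  )
}

#' @export
print.pipeline_params <- function(x, ...) {
  cat(sprintf(paste0(
    "<pipeline_params> sigma=%d px, erode=%d it, open=%d it, noise=%d, ",
    "count=%d, polarity=%s%s%s\n"),
    x$sigma_px, x$erode_iterations, x$open_iterations, x$noise_tolerance,
    x$neighbor_count, x$polarity,
    if (x$exclude_edge_maxima) ", exclude-edge-maxima" else "",
    if (x$strict_imagej_edm) ", strict-8bit-EDM" else ""))
  invisible(x)
}

# Scaling coefficients (micrometres): each operator parameter is the
# nearest integer of coefficient / pixel_size_um, so every parameter
# corresponds to a fixed physical length regardless of magnification.
.scaling_um <- c(sigma = 1, erode = 1.25, open = 2.5,
                 noise_round = 1.75, noise_bottleneck = 4.75)

#' Derive pipeline parameters from pixel size and cell-footprint shape
#'
#' All five operator parameters scale with the image resolution so that
#' they correspond to fixed physical lengths on the leaf surface: the
#' Gaussian sigma is `1/x` pixels, erosion and opening iterations are
#' `1.25/x` and `2.5/x`, and the maxima noise tolerance is `1.75/x` for
#' round cell footprints or `4.75/x` for waisted ("bottleneck") footprints
#' of large lobed cells, where `x` is the pixel size in micrometres. Each
#' value is rounded to the nearest integer (ties away from zero); values
#' that would round to zero — pixel sizes coarser than ~2 um/px — are
#' clamped to 1 with a warning, since every operator needs a positive
#' parameter.
#'
#' @param pixel_size_um pixel size `x` in micrometres (> 0).
#' @param shape `"round"` or `"bottleneck"` cell contact footprint class.
#'   Bottleneck footprints need the larger merging tolerance so that the
#'   two distance-map peaks of one waisted footprint count as one cell.
#' @return A [pipeline_params] with default flags (`neighbor_count = 1`,
#'   `polarity = "dark"`, edge maxima kept, exact distance map).
#' @examples
#' derive_params(0.117, "round")    # sigma 9, erode 11, open 21, noise 15
#' derive_params(0.130, "bottleneck")
#' @export
derive_params <- function(pixel_size_um, shape = c("round", "bottleneck")) {
  assert_scalar_positive(pixel_size_um, "pixel_size_um")
  shape <- match.arg(shape)
  noise_um <- if (shape == "round") .scaling_um[["noise_round"]]
              else .scaling_um[["noise_bottleneck"]]
  raw <- c(sigma = .scaling_um[["sigma"]],
           erode = .scaling_um[["erode"]],
           open = .scaling_um[["open"]],
           noise = noise_um) / pixel_size_um
  vals <- round_half_away(raw)
  if (any(vals < 1)) {
    warning(sprintf(
      "pixel size %g um/px is coarser than the scaling rules anticipate; %s clamped to 1",
      pixel_size_um, paste(names(vals)[vals < 1], collapse = ", ")),
      call. = FALSE)
    vals[vals < 1] <- 1
  }
  pipeline_params(sigma_px = vals[["sigma"]],
                  erode_iterations = vals[["erode"]],
                  open_iterations = vals[["open"]],
                  noise_tolerance = vals[["noise"]])
}
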