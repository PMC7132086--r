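#' Identify and count epidermal cells in a micrograph
#'
#' End-to-end counting pipeline: (1) red-channel extraction, (2) Gaussian
#' smoothing, (3) minimum-method auto-threshold of the smoothed 256-bin
#' histogram and binarization, (4) iterated binary erosion then opening,
#' (5) Euclidean distance map, (6) noise-tolerant maxima detection. One
#' accepted maximum marks one cell contact footprint. The pipeline is
#' fully deterministic: identical input and parameters give bit-identical
#' outputs.
#'
#' @param m a [micrograph] (RGB or single-channel).
#' @param params a [pipeline_params], typically from [derive_params()].
#' @return An object of class `cell_count_result`:
#'   \describe{
#'     \item{report}{one-row data frame from [count_report()]: count, FOV
#'       area (mm^2), cell density (cells/mm^2), mean cell size (um^2,
#'       `NA` at count 0).}
#'     \item{maxima}{the `maxima_result` (markers, count, tolerance mask).}
#'     \item{intermediates}{QC snapshots: the blurred image, the selected
#'       threshold, the mask after binarization / erosion / opening, and
#'       the distance map.}
#'   }
#' @examples
#' sc <- generate_scene(scene_spec(height_px = 256, width_px = 256,
#'                                 n_cells = 10, seed = 7))
#' res <- count_cells(sc$image, derive_params(sc$spec$pixel_size_um, "round"))
#' res$report$cell_count
#' @export
count_cells <- function(m, params) {
  stopifnot(inherits(m, "micrograph"), inherits(params, "pipeline_params"))
  red <- extract_red_channel(m)
  blurred <- gaussian_blur(red, params$sigma_px)
  thr <- minimum_autothreshold(intensity_histogram(blurred), m$source_id)
  mask_bin <- binarize(blurred, thr, params$polarity)
  mask_eroded <- binary_erode(mask_bin, params$erode_iterations,
                              params$neighbor_count)
  mask_opened <- binary_open(mask_eroded, params$open_iterations,
                             params$neighbor_count)
  dm <- distance_map(mask_opened, params$strict_imagej_edm)
  mx <- find_maxima(dm, params$noise_tolerance, params$exclude_edge_maxima)
  d <- dim(m$pixels)
  structure(list(
    report = count_report(m$source_id, mx$count, d[1], d[2], m$pixel_size_um),
    maxima = mx,
    intermediates = list(blurred = blurred, threshold = thr,
                         mask_binarized = mask_bin,
                         mask_eroded = mask_eroded,
                         mask_opened = mask_opened,
                         distance_map = dm)),
    class = "cell_count_result")
}

#' @export
print.cell_count_result <- function(x, ...) {
  r <- x$report
  cat(sprintf("<cell_count_result> %s: %d cells | FOV %.4g mm^2 | %.1f cells/mm^2 | mean size %s um^2\n",
              r$source_id, r$cell_count, r$fov_area_mm2,
              r$cell_density_per_mm2,
              if (is.na(r$mean_cell_size_um2)) "NA"
              else sprintf("%.1f", r$mean_cell_size_um2)))
  invisible(x)
}
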