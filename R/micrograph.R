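#' Micrograph container
#'
#' A `micrograph` is a 2-D intensity raster (one channel) or an RGB stack
#' (three channels) together with the physical pixel size in micrometres.
#' Intensities are 8-bit integers in 0..255 stored as numerics. The raster
#' convention is row-major with 1-based `(row, col)` coordinates and the
#' origin at the top-left pixel, matching R matrix indexing: `pixels[r, c]`
#' for single-channel images, `pixels[r, c, ch]` for RGB.
#'
#' @param pixels numeric matrix (height x width) or array (height x width x
#'   channels) of intensities in 0..255.
#' @param pixel_size_um physical side length of one pixel in micrometres
#'   (must be positive). All scale-dependent pipeline parameters derive
#'   from this value.
#' @param source_id free-text provenance label used in reports and error
#'   messages.
#' @return An object of class `micrograph` with fields `pixels`, `channels`,
#'   `pixel_size_um`, `source_id`.
#' @seealso [load_micrograph()], [count_cells()]
#' @export
micrograph <- function(pixels, pixel_size_um, source_id = "<in-memory>") {
  assert_scalar_positive(pixel_size_um, "pixel_size_um")
  d <- dim(pixels)
  if (is.null(d) || !(length(d) %in% c(2L, 3L))) {
    stop("`pixels` must be a 2-D matrix or a 3-D array", call. = FALSE)
  }
  if (d[1] < 1L || d[2] < 1L) {
    stop("micrograph must have height >= 1 and width >= 1", call. = FALSE)
  }
  channels <- if (length(d) == 3L) d[3] else 1L
  structure(
    list(pixels = pixels, channels = as.integer(channels),
         pixel_size_um = as.numeric(pixel_size_um),
         source_id = as.character(source_id)),
    class = "micrograph"
  )
}

#' @export
print.micrograph <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<micrograph> %s: %d x %d px, %d channel(s), %.4g um/px\n",
              x$source_id, d[1], d[2], x$channels, x$pixel_size_um))
  invisible(x)
}

#' @export
dim.micrograph <- function(x) dim(x$pixels)

# Convert intensities on the decoder's [0, 1] scale to 8-bit 0..255.
# 8-bit sources (all values exact multiples of 1/255) are mapped back to
# their original integer codes; deeper sources (16-bit TIFF/PNG) are
# min-max rescaled to the full 8-bit range. A constant deep image maps to 0.
to_8bit <- function(values01) {
  v255 <- values01 * 255
  if (max(abs(v255 - round(v255))) < 1e-6) {
    return(round(v255))
  }
  rng <- range(values01)
  if (rng[2] > rng[1]) {
    round_half_away((values01 - rng[1]) / (rng[2] - rng[1]) * 255)
  } else {
    values01 * 0
  }
}

#' Load a micrograph from a TIFF, PNG, or JPEG file
#'
#' Decodes the image, converts it to 8-bit (16-bit inputs are linearly
#' min-max rescaled to 0..255), and attaches the user-supplied pixel size.
#' The pixel size is always taken from the caller, never from embedded
#' image metadata: the acquisition scale is set at the microscope and must
#' be stated explicitly for the parameter-scaling rules to be meaningful.
#'
#' @param path path to a TIFF, PNG, or JPEG image.
#' @param pixel_size_um pixel size in micrometres (> 0).
#' @param source_id provenance label; defaults to the file name.
#' @return A [micrograph] with the original channel count preserved.
#' @export
load_micrograph <- function(path, pixel_size_um, source_id = basename(path)) {
  assert_scalar_positive(pixel_size_um, "pixel_size_um")
  if (!file.exists(path)) {
    stop(sprintf("cannot read image '%s': file does not exist", path),
         call. = FALSE)
  }
  img <- tryCatch(
    EBImage::readImage(path),
    error = function(e) {
      stop(sprintf("cannot read image '%s': %s", path, conditionMessage(e)),
           call. = FALSE)
    }
  )
  dat <- EBImage::imageData(img)
  # EBImage stores (x = column, y = row); transpose to (row, col).
  if (length(dim(dat)) == 2L) {
    px <- to_8bit(t(dat))
  } else {
    px <- aperm(dat, c(2L, 1L, 3L))
    px <- array(to_8bit(px), dim = dim(px))
  }
  micrograph(px, pixel_size_um, source_id)
}

#' Write a micrograph to a PNG or TIFF file
#'
#' @param m a [micrograph] with 8-bit intensities.
#' @param path output path; format follows the file extension (.png / .tif).
#' @return `path`, invisibly.
#' @export
write_micrograph <- function(m, path) {
  stopifnot(inherits(m, "micrograph"))
  if (m$channels == 1L) {
    img <- EBImage::Image(t(m$pixels) / 255)
  } else {
    img <- EBImage::Image(aperm(m$pixels, c(2L, 1L, 3L)) / 255,
                          colormode = "Color")
  }
  EBImage::writeImage(img, path)
  invisible(path)
}

#' Extract the red channel of an RGB micrograph
#'
#' First pipeline stage. RGB micrographs are reduced to their red plane;
#' a single-channel micrograph is passed through unchanged with a message,
#' as a convenience for pre-converted grayscale imagery.
#'
#' @param m a [micrograph] with 1 or 3 channels.
#' @return A single-channel [micrograph].
#' @export
extract_red_channel <- function(m) {
  stopifnot(inherits(m, "micrograph"))
  if (m$channels == 1L) {
    message(sprintf("%s: already single-channel, red-channel extraction skipped",
                    m$source_id))
    return(m)
  }
  if (m$channels != 3L) {
    stop(sprintf("%s: expected 1 or 3 channels, got %d (alpha/extra channels unsupported)",
                 m$source_id, m$channels), call. = FALSE)
  }
  micrograph(m$pixels[, , 1L], m$pixel_size_um, m$source_id)
}

#' Overlay detected cell markers on a micrograph
#'
#' Quality-control rendering: marker positions (or the whole
#' within-tolerance region) are burned into a copy of the image at
#' saturating intensity (255), so automatic markers can be checked against
#' the original by eye. In `points` mode each marker is drawn as a small
#' cross (2-pixel arms, clipped at the border).
#'
#' @param m a [micrograph].
#' @param markers a `maxima_result` from [find_maxima()], or a 2-column
#'   `(row, col)` matrix of marker coordinates.
#' @param mode `"points"` (crosses at markers) or `"within_tolerance"`
#'   (saturate the whole tolerance mask; requires a `maxima_result`).
#' @return A new [micrograph]; the input is not modified.
#' @export
overlay_markers <- function(m, markers, mode = c("points", "within_tolerance")) {
  stopifnot(inherits(m, "micrograph"))
  mode <- match.arg(mode)
  h <- dim(m$pixels)[1]; w <- dim(m$pixels)[2]
  coords <- if (inherits(markers, "maxima_result")) markers$markers else markers
  if (is.null(coords)) coords <- matrix(integer(), 0L, 2L)
  coords <- matrix(as.numeric(coords), ncol = 2L)
  if (nrow(coords) > 0 &&
      (any(coords[, 1] < 1) || any(coords[, 1] > h) ||
       any(coords[, 2] < 1) || any(coords[, 2] > w))) {
    stop("marker coordinates fall outside the image", call. = FALSE)
  }
  sat <- function(px, rows, cols) {
    if (length(dim(px)) == 2L) px[cbind(rows, cols)] <- 255
    else for (ch in seq_len(dim(px)[3])) px[cbind(rows, cols, ch)] <- 255
    px
  }
  px <- m$pixels
  if (mode == "within_tolerance") {
    if (!inherits(markers, "maxima_result")) {
      stop("mode 'within_tolerance' requires a maxima_result", call. = FALSE)
    }
    idx <- which(markers$tolerance_mask, arr.ind = TRUE)
    if (nrow(idx) > 0) px <- sat(px, idx[, 1], idx[, 2])
  } else if (nrow(coords) > 0) {
    for (k in seq_len(nrow(coords))) {
      r <- coords[k, 1]; c <- coords[k, 2]
      rr <- pmax(1, pmin(h, (r - 2):(r + 2)))
      cc <- pmax(1, pmin(w, (c - 2):(c + 2)))
      px <- sat(px, rr, rep(c, 5))
      px <- sat(px, rep(r, 5), cc)
    }
  }
  micrograph(px, m$pixel_size_um, m$source_id)
}

#' Build a per-image count report row
#'
#' Derived quantities follow from the raster geometry: the field-of-view
#' area is `height * width * pixel_size_um^2 * 1e-6` mm^2, cell density is
#' cells per mm^2, and mean cell size is the FOV area per counted cell in
#' um^2 (reported as `NA` when the count is zero).
#'
#' @param source_id provenance label.
#' @param cell_count non-negative integer cell count.
#' @param height_px,width_px raster dimensions in pixels.
#' @param pixel_size_um pixel size in micrometres.
#' @return A one-row data frame with columns `source_id`, `cell_count`,
#'   `fov_area_mm2`, `cell_density_per_mm2`, `mean_cell_size_um2`.
#' @export
count_report <- function(source_id, cell_count, height_px, width_px,
                         pixel_size_um) {
  stopifnot(cell_count >= 0)
  area_um2 <- height_px * width_px * pixel_size_um^2
  area_mm2 <- area_um2 * 1e-6
  data.frame(
    source_id = as.character(source_id),
    cell_count = as.integer(cell_count),
    fov_area_mm2 = area_mm2,
    cell_density_per_mm2 = cell_count / area_mm2,
    mean_cell_size_um2 = if (cell_count > 0) area_um2 / cell_count else NA_real_,
    stringsAsFactors = FALSE
  )
}

#' Write count reports to CSV
#'
#' @param reports a data frame of [count_report()] rows, or a list of them.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_count_report <- function(reports, path) {
  cols <- c("source_id", "cell_count", "fov_area_mm2",
            "cell_density_per_mm2", "mean_cell_size_um2")
  if (is.data.frame(reports)) {
    df <- reports
  } else if (length(reports) == 0L) {
    df <- stats::setNames(
      data.frame(character(), integer(), numeric(), numeric(), numeric(),
                 stringsAsFactors = FALSE), cols)
  } else {
    df <- do.call(rbind, reports)
  }
  stopifnot(all(cols %in% names(df)))
  ok <- tryCatch({
    utils::write.csv(df[, cols], path, row.names = FALSE)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) {
    stop(sprintf("cannot write report '%s': %s", path, conditionMessage(ok)),
         call. = FALSE)
  }
  invisible(path)
}
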