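#' Match automatic markers against reference markers
#'
#' Greedy one-to-one nearest-pair matching under a distance cap: candidate
#' pairs are considered in ascending Euclidean distance (ties broken by
#' automatic then reference index), each marker is used at most once, and
#' only pairs closer than `radius_px` match. Formalizes the visual
#' automatic-vs-manual marker comparison as precision/recall.
#'
#' @param auto,ref 2-column `(row, col)` matrices of marker coordinates
#'   (automatic and reference/ground-truth); `NULL` or 0-row for empty.
#' @param radius_px positive matching radius in pixels. A scale-aware
#'   choice is the mean footprint radius (synthetic scenes) or
#'   `0.5 * sqrt(mean_cell_size_px2)` for real images.
#' @return A `match_result` list: `n_auto`, `n_ref`, `n_matched`,
#'   `precision` (`n_matched / n_auto`, 1 when `n_auto = 0`), `recall`
#'   (`n_matched / n_ref`, 1 when `n_ref = 0`), `count_error_abs`,
#'   `count_error_rel` (`NA` when `n_ref = 0`), and `pairs` (matched index
#'   pairs with distances).
#' @export
match_markers <- function(auto, ref, radius_px) {
  assert_scalar_positive(radius_px, "radius_px")
  as_mat <- function(z) {
    if (is.null(z) || length(z) == 0L) matrix(numeric(), 0L, 2L)
    else matrix(as.numeric(as.matrix(z)), ncol = 2L)
  }
  auto <- as_mat(auto); ref <- as_mat(ref)
  na <- nrow(auto); nr <- nrow(ref)
  pairs <- matrix(numeric(), 0L, 3L,
                  dimnames = list(NULL, c("auto", "ref", "dist")))
  if (na > 0 && nr > 0) {
    d <- sqrt(outer(auto[, 1], ref[, 1], "-")^2 +
              outer(auto[, 2], ref[, 2], "-")^2)
    idx <- which(d <= radius_px, arr.ind = TRUE)
    if (nrow(idx) > 0) {
      ord <- order(d[idx], idx[, 1], idx[, 2])
      used_a <- logical(na); used_r <- logical(nr)
      for (k in ord) {
        ia <- idx[k, 1]; ir <- idx[k, 2]
        if (used_a[ia] || used_r[ir]) next
        used_a[ia] <- TRUE; used_r[ir] <- TRUE
        pairs <- rbind(pairs, c(ia, ir, d[ia, ir]))
      }
    }
  }
  nm <- nrow(pairs)
  structure(list(
    n_auto = na, n_ref = nr, n_matched = nm,
    precision = if (na > 0) nm / na else 1,
    recall = if (nr > 0) nm / nr else 1,
    count_error_abs = abs(na - nr),
    count_error_rel = if (nr > 0) abs(na - nr) / nr else NA_real_,
    pairs = pairs), class = "match_result")
}

#' @export
print.match_result <- function(x, ...) {
  cat(sprintf("<match_result> auto %d vs ref %d: %d matched | precision %.3f | recall %.3f | |dcount| %d\n",
              x$n_auto, x$n_ref, x$n_matched, x$precision, x$recall,
              x$count_error_abs))
  invisible(x)
}

#' Cell density and mean cell size from a count and a micrograph
#'
#' Density is the count per FOV area in cells/mm^2; mean cell size is the
#' FOV area divided by the count in um^2 (so `density * mean_size = 1e6`
#' exactly for positive counts). A zero count gives density 0 and `NA`
#' size.
#'
#' @param count non-negative integer cell count.
#' @param m the counted [micrograph] (supplies raster size and pixel size).
#' @return List with `cell_density_per_mm2` and `mean_cell_size_um2`.
#' @export
density_and_size <- function(count, m) {
  stopifnot(inherits(m, "micrograph"), count >= 0)
  d <- dim(m$pixels)
  area_um2 <- d[1] * d[2] * m$pixel_size_um^2
  list(cell_density_per_mm2 = count / (area_um2 * 1e-6),
       mean_cell_size_um2 = if (count > 0) area_um2 / count else NA_real_)
}
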