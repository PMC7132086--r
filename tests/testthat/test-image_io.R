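make_rgb <- function(h = 8, w = 10, red = 200) {
  px <- array(0, dim = c(h, w, 3))
  px[, , 1] <- red
  micrograph(px, 0.117, "rgb-fixture")
}

test_that("8-bit images survive a save/load round trip pixel-exactly", {
  set.seed(11)
  px <- matrix(sample(0:255, 12 * 16, TRUE), 12, 16)
  m <- micrograph(px, 0.117, "roundtrip")
  f <- tempfile(fileext = ".png")
  write_micrograph(m, f)
  m2 <- load_micrograph(f, 0.117)
  expect_identical(dim(m2$pixels), c(12L, 16L))
  expect_equal(m2$pixels, px, ignore_attr = TRUE)
  # idempotence: a second round trip is bit-identical
  f2 <- tempfile(fileext = ".png")
  write_micrograph(m2, f2)
  expect_equal(load_micrograph(f2, 0.117)$pixels, m2$pixels)
})

test_that("16-bit TIFF input is min-max rescaled to the full 8-bit range", {
  skip_if_not_installed("tiff")
  v <- matrix(seq(1000, 21000, length.out = 300), 15, 20) / 65535
  f <- tempfile(fileext = ".tif")
  tiff::writeTIFF(v, f, bits.per.sample = 16L)
  m <- load_micrograph(f, 0.5)
  expect_equal(min(m$pixels), 0)
  expect_equal(max(m$pixels), 255)
  expect_true(all(m$pixels == floor(m$pixels)))
  # monotone in the source values
  expect_true(all(diff(m$pixels[, 1]) >= 0))
})

test_that("unreadable input and invalid pixel size raise informative errors", {
  junk <- tempfile(fileext = ".png")
  writeLines("this is not an image", junk)
  expect_error(load_micrograph(junk, 0.117), basename(junk), fixed = TRUE)
  expect_error(load_micrograph(tempfile(fileext = ".png"), 0.117), "exist")
  f <- tempfile(fileext = ".png")
  write_micrograph(micrograph(matrix(0, 4, 4), 1), f)
  expect_error(load_micrograph(f, -0.1), "positive")
})

test_that("red-channel extraction isolates the red plane", {
  m <- make_rgb(red = 200)
  r <- extract_red_channel(m)
  expect_identical(r$channels, 1L)
  expect_true(all(r$pixels == 200))
  expect_identical(dim(r$pixels), dim(m$pixels)[1:2])
  # colour files round-trip with their channel count preserved
  f <- tempfile(fileext = ".png")
  write_micrograph(m, f)
  back <- load_micrograph(f, 0.117)
  expect_identical(back$channels, 3L)
  expect_true(all(back$pixels[, , 1] == 200))
  expect_true(all(back$pixels[, , 2] == 0))
})

test_that("red-channel extraction is the identity on grayscale input", {
  m <- micrograph(matrix(7, 5, 5), 0.117, "gray")
  expect_message(r <- extract_red_channel(m), "single-channel")
  expect_identical(r$pixels, m$pixels)
})

test_that("extra channels are rejected", {
  px <- array(0, dim = c(4, 4, 4))
  m <- micrograph(px, 0.117, "rgba")
  expect_error(extract_red_channel(m), "channels")
})

test_that("marker overlays are local, bounded, and non-destructive", {
  set.seed(3)
  px <- matrix(sample(0:200, 400, TRUE), 20, 20)
  m <- micrograph(px, 0.5)
  # empty marker set: identity
  o0 <- overlay_markers(m, matrix(integer(), 0, 2))
  expect_identical(o0$pixels, px)
  # one marker: only its cross footprint changes
  o1 <- overlay_markers(m, matrix(c(10, 12), 1))
  expect_identical(dim(o1$pixels), dim(px))
  changed <- which(o1$pixels != px, arr.ind = TRUE)
  expect_true(all(changed[, 1] %in% 8:12 & changed[, 2] %in% 10:14))
  expect_true(all(o1$pixels[changed] == 255))
  expect_identical(m$pixels, px)  # input untouched
  # out-of-bounds marker rejected
  expect_error(overlay_markers(m, matrix(c(0, 5), 1)), "outside")
  expect_error(overlay_markers(m, matrix(c(5, 21), 1)), "outside")
})

test_that("within-tolerance overlay saturates exactly the mask", {
  m <- micrograph(matrix(100, 9, 9), 0.5)
  dm <- distance_map(local({x <- matrix(FALSE, 9, 9); x[3:7, 3:7] <- TRUE; x}))
  mx <- find_maxima(dm, 1)
  ov <- overlay_markers(m, mx, "within_tolerance")
  expect_true(all(ov$pixels[mx$tolerance_mask] == 255))
  expect_true(all(ov$pixels[!mx$tolerance_mask] == 100))
})

test_that("count reports round-trip through CSV in order", {
  r1 <- count_report("a", 125, 1000, 600, 0.5)
  r2 <- count_report("b", 0, 100, 100, 1)
  f <- tempfile(fileext = ".csv")
  write_count_report(list(r1, r2), f)
  back <- read.csv(f)
  expect_identical(nrow(back), 2L)
  expect_identical(back$source_id, c("a", "b"))
  expect_equal(back$cell_count, c(125L, 0L))
  expect_equal(back$fov_area_mm2[1], r1$fov_area_mm2)
  expect_true(is.na(back$mean_cell_size_um2[2]))
  # density and mean size are reciprocal through 1e6 um^2/mm^2
  expect_equal(back$cell_density_per_mm2[1] * back$mean_cell_size_um2[1], 1e6)
  # empty report: header only
  f0 <- tempfile(fileext = ".csv")
  write_count_report(list(), f0)
  empty <- read.csv(f0)
  expect_identical(nrow(empty), 0L)
  expect_identical(names(empty)[1:2], c("source_id", "cell_count"))
})
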