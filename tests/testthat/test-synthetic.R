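test_that("identical spec and seed give bit-identical scenes and leave the RNG alone", {
  spec <- scene_spec(height_px = 320, width_px = 320, n_cells = 12, seed = 4)
  set.seed(999); before <- runif(3)
  set.seed(999)
  s1 <- generate_scene(spec)
  after <- runif(3)
  s2 <- generate_scene(spec)
  expect_identical(s1$image$pixels, s2$image$pixels)
  expect_identical(s1$truth_centers, s2$truth_centers)
  expect_identical(before, after)  # caller RNG stream undisturbed
})

test_that("zero cells gives pure noise over background", {
  sc <- generate_scene(scene_spec(height_px = 64, width_px = 64, n_cells = 0,
                                  noise_sd = 5, seed = 2))
  expect_identical(sc$truth_count, 0L)
  expect_identical(nrow(sc$truth_centers), 0L)
  expect_lt(abs(mean(sc$image$pixels) - 160), 3)
  expect_true(all(sc$image$pixels >= 0 & sc$image$pixels <= 255))
})

test_that("footprint supports respect the minimum gap", {
  sc <- generate_scene(scene_spec(seed = 3))
  ctr <- sc$truth_centers
  rb <- sc$bounding_radius_px
  gap_px <- sc$spec$min_gap_um / sc$spec$pixel_size_um
  n <- nrow(ctr)
  for (i in seq_len(n - 1)) {
    d <- sqrt((ctr[(i + 1):n, 1] - ctr[i, 1])^2 +
              (ctr[(i + 1):n, 2] - ctr[i, 2])^2)
    expect_true(all(d >= rb[i] + rb[(i + 1):n] + gap_px - 1e-9))
  }
  expect_true(all(ctr[, 1] >= 1 & ctr[, 1] <= 800 &
                  ctr[, 2] >= 1 & ctr[, 2] <= 800))
})

test_that("impossible packing saturates with a warning", {
  expect_warning(
    sc <- generate_scene(scene_spec(height_px = 128, width_px = 128,
                                    n_cells = 500, seed = 5)),
    "saturated")
  expect_true(sc$saturated)
  expect_lt(sc$truth_count, 500L)
})

test_that("noiseless well-separated scenes are counted exactly", {
  sc <- generate_scene(scene_spec(height_px = 480, width_px = 480, n_cells = 30,
                                  noise_sd = 0, seed = 6))
  r <- suppressMessages(count_cells(sc$image, derive_params(0.5, "round")))
  expect_identical(r$report$cell_count, sc$truth_count)
})

test_that("bottleneck footprints need the bottleneck tolerance to count as single cells", {
  sc <- generate_scene(scene_spec(height_px = 480, width_px = 480, n_cells = 15,
                                  shape = "bottleneck", seed = 7))
  pb <- derive_params(0.5, "bottleneck")
  pr <- derive_params(0.5, "round")
  nb <- suppressMessages(count_cells(sc$image, pb))$report$cell_count
  nr <- suppressMessages(count_cells(sc$image, pr))$report$cell_count
  expect_lte(abs(nb - sc$truth_count), 1)
  # the round-class tolerance resolves the two lobes of most footprints
  expect_gt(nr, nb)
})

test_that("bright-footprint scenes count with bright polarity", {
  sc <- generate_scene(scene_spec(height_px = 320, width_px = 320, n_cells = 10,
                                  foreground_level = 190,
                                  background_level = 70, seed = 8))
  p <- derive_params(0.5, "round")
  pbright <- pipeline_params(p$sigma_px, p$erode_iterations, p$open_iterations,
                             p$noise_tolerance, polarity = "bright")
  r <- suppressMessages(count_cells(sc$image, pbright))
  expect_lte(abs(r$report$cell_count - sc$truth_count), 1)
})
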