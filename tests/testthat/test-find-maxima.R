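test_that("background-only maps yield no maxima", {
  res <- find_maxima(matrix(0, 10, 10), 5)
  expect_identical(res$count, 0L)
  expect_identical(nrow(res$markers), 0L)
  expect_false(any(res$tolerance_mask))
})

test_that("a single cone yields one marker at its apex", {
  rr <- matrix(seq_len(20), 20, 20); cc <- t(rr)
  cone <- pmax(10 - sqrt((rr - 10)^2 + (cc - 10)^2), 0)
  res <- find_maxima(cone, 3)
  expect_identical(res$count, 1L)
  expect_equal(unname(res$markers[1, ]), c(10, 10))
})

test_that("peak merging follows the saddle-prominence rule", {
  # saddle 50 is deeper than tolerance 15: two cells; saddle 95 is not: one
  tp_deep <- two_peak_map(100, 100, 50)
  tp_shallow <- two_peak_map(100, 100, 95)
  expect_identical(find_maxima(tp_deep$map, 15)$count, 2L)
  expect_identical(find_maxima(tp_shallow$map, 15)$count, 1L)
  # across constructed saddles, heights and tolerances, agree with the
  # pairwise saddle oracle
  for (h2 in c(100, 88)) {
    for (saddle in c(40, 65, 80)) {
      tp <- two_peak_map(100, h2, saddle)
      for (tol in c(3, 10, 20, 35, 55)) {
        expect_identical(find_maxima(tp$map, tol)$count,
                         oracle_two_peak_count(tp, tol),
                         info = sprintf("h2=%d saddle=%d tol=%d", h2, saddle, tol))
      }
    }
  }
})

test_that("maxima count is non-increasing in the noise tolerance", {
  tp <- two_peak_map(100, 90, 60)
  counts <- vapply(c(1, 5, 10, 20, 31, 45, 70, 101), function(tol) {
    find_maxima(tp$map, tol)$count
  }, integer(1))
  expect_true(all(diff(counts) <= 0))
  # scene-derived distance map: same property
  sc <- small_scene(5)
  res <- suppressMessages(count_cells(sc$image, derive_params(0.5, "round")))
  dm <- res$intermediates$distance_map
  counts2 <- vapply(c(1, 2, 4, 8, 16), function(tol) find_maxima(dm, tol)$count,
                    integer(1))
  expect_true(all(diff(counts2) <= 0))
})

test_that("an equal-valued plateau yields one marker at the pixel nearest its centroid", {
  v <- matrix(0, 10, 10)
  v[4:7, 4:7] <- 3
  res <- find_maxima(v, 1)
  expect_identical(res$count, 1L)
  # centroid (5.5, 5.5); four pixels tie at distance^2 = 0.5; smallest
  # row then column wins
  expect_equal(unname(res$markers[1, ]), c(5, 5))
})

test_that("markers are distinct, in-bounds, and inside the tolerance region", {
  sc <- small_scene(6)
  res <- suppressMessages(count_cells(sc$image, derive_params(0.5, "round")))
  mk <- res$maxima$markers
  expect_identical(nrow(mk), res$maxima$count)
  expect_identical(nrow(unique(mk)), nrow(mk))
  expect_true(all(mk[, "row"] >= 1 & mk[, "row"] <= 320 &
                  mk[, "col"] >= 1 & mk[, "col"] <= 320))
  expect_true(all(res$maxima$tolerance_mask[mk]))
})

test_that("edge exclusion drops only maxima whose region touches the border", {
  m <- matrix(FALSE, 21, 40)
  m[9:13, 18:22] <- TRUE         # interior blob
  m[1:5, 5:9] <- TRUE            # blob touching the top border
  d <- distance_map(m)
  # tolerance 3 makes each flood region cover its whole blob, so the
  # border blob's region reaches row 1
  both <- find_maxima(d, 3)
  expect_identical(both$count, 2L)
  inner <- find_maxima(d, 3, exclude_edge_maxima = TRUE)
  expect_identical(inner$count, 1L)
  expect_true(all(inner$markers[, "col"] >= 18))
  expect_false(any(inner$tolerance_mask[, 1:10]))
})
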