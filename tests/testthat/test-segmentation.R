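test_that("ISEF smoothing preserves constants and contracts variance", {
  const <- matrix(5, 30, 40)
  expect_equal(smooth_edges(const, 0.8), const, tolerance = 1e-12)
  set.seed(1)
  noisy <- matrix(rnorm(30 * 40), 30, 40)
  expect_lt(var(as.vector(smooth_edges(noisy, 0.8))), var(as.vector(noisy)))
  expect_error(smooth_edges(noisy, 0), "positive")
})

test_that("ISEF smoothing keeps a step edge in place", {
  step <- matrix(0, 40, 60)
  step[, 31:60] <- 1
  sm <- smooth_edges(step, 0.8)
  # half-max crossing stays between the original columns 30 and 31
  prof <- sm[20, ]
  cross <- which(prof >= 0.5)[1]
  expect_true(cross %in% c(30, 31, 32))
  # intensity range preserved
  expect_gte(min(sm), 0)
  expect_lte(max(sm), 1 + 1e-9)
})

test_that("ridge filter highlights a line and is rotation-equivariant", {
  img <- matrix(0, 41, 41)
  img[21, ] <- 1
  r <- ridge_enhance(img, 1)
  expect_equal(which.max(apply(r, 1, max)), 21)
  # response decays to ~0 beyond 3 sigma from the line
  expect_lt(max(r[c(1:17, 25:41), ]), 0.01 * max(r))
  # constant image: all-zero response
  expect_equal(ridge_enhance(matrix(2, 20, 20), 1), matrix(0, 20, 20))
  # 90-degree rotation commutes with the filter
  img2 <- t(img)
  expect_equal(ridge_enhance(img2, 1), t(r), tolerance = 1e-12)
  expect_error(ridge_enhance(img, 0.2), ">= 0.5")
})

test_that("watershed separates basins and merges small ones", {
  ridge <- matrix(0, 30, 50)
  ridge[, 25] <- 1
  lab <- watershed_cells(ridge, min_cell_area_px = 10, h = 0.01)
  expect_identical(length(setdiff(unique(as.vector(lab)), 0L)), 2L)
  # min area above every basin size collapses to a single label
  lab2 <- watershed_cells(ridge, min_cell_area_px = 1e6, h = 0.01)
  expect_identical(length(setdiff(unique(as.vector(lab2)), 0L)), 1L)
  expect_error(watershed_cells(ridge - 2), "non-negative")
})

test_that("label regions partition the raster", {
  fx <- rendered_fixture()
  lab <- segment(fx$render$image)
  pos <- lab[lab > 0]
  # regions disjoint by construction; with membrane pixels they tile the image
  expect_identical(length(pos) + sum(lab == 0), length(lab))
  # blank image: no crash, at most one region
  blank <- matrix(0.3, 60, 60)
  lb <- segment(blank)
  expect_lte(length(setdiff(unique(as.vector(lb)), 0L)), 1L)
})

test_that("noiseless rendered tissue is segmented cell-for-cell", {
  fx <- rendered_fixture()
  lab <- segment(fx$render$image)
  ev <- match_labels(lab, fx$render$labels, iou_threshold = 0.9)
  expect_identical(ev$n_truth, 100L)
  expect_gte(ev$matched_fraction, 0.99)
})
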