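test_that("natural strain series from tissue shapes", {
  shp <- data.frame(l = c(10, 10, 10), h = c(5, 5, 5))
  ns <- natural_strain_series(shp)
  expect_equal(ns$LmH, c(0, 0, 0))
  # l doubles while h halves: L - H = log 4
  ns2 <- natural_strain_series(data.frame(l = c(10, 20), h = c(5, 2.5)))
  expect_equal(ns2$LmH[2], log(4))
  # additivity under composed shears
  l <- 10 * exp(c(0, 0.1, 0.25)); h <- 5 * exp(-c(0, 0.1, 0.25))
  ns3 <- natural_strain_series(data.frame(l = l, h = h))
  expect_equal(ns3$LmH, 2 * c(0, 0.1, 0.25))
  expect_error(natural_strain_series(data.frame(l = 1, h = 1)), ">= 2")
  expect_error(natural_strain_series(data.frame(l = c(1, -1), h = c(1, 1))), "positive")
})

test_that("shear rate differentiates exactly on polynomials", {
  tt <- seq(0, 2, by = 0.1)
  # linear: slope 0.2 -> vxx = 0.1 everywhere, ends included
  expect_equal(shear_rate(0.2 * tt, tt), rep(0.1, length(tt)))
  expect_equal(shear_rate(rep(3, length(tt)), tt), rep(0, length(tt)))
  # quadratic is differentiated exactly by second-order stencils
  expect_equal(shear_rate(tt^2, tt), tt, tolerance = 1e-10)
  # cubic: interior error is O(dt^2); Richardson halving the step
  f <- function(t) t^3
  t1 <- seq(0, 2, by = 0.2); t2 <- seq(0, 2, by = 0.1)
  e1 <- max(abs(2 * shear_rate(f(t1), t1) - 3 * t1^2)[2:(length(t1) - 1)])
  e2 <- max(abs(2 * shear_rate(f(t2), t2) - 3 * t2^2)[2:(length(t2) - 1)])
  expect_gt(e1 / e2, 3.5)
})

test_that("the discrete shear decomposition identity holds exactly", {
  set.seed(3)
  es <- elongation_series(seq(4, 7, 0.25), cumsum(rnorm(13, 0, 0.01)),
                          c(0, cumsum(rnorm(12, 0.05, 0.02))))
  dec <- rearrangement_shear(es)
  expect_equal(dec$vxx - dec$dQxx_dt - dec$Rxx, rep(0, 13))
  expect_error(rearrangement_shear(es[1:2, ]), ">= 3")
})

test_that("elongation series validates its invariants", {
  expect_error(elongation_series(c(1, 1, 2), 1:3, 1:3), "increasing")
  expect_error(elongation_series(1:3, 1:2, 1:3), "equal length")
})

test_that("single planted events are detected with the right kind", {
  t1 <- simulate_event_series(n_cells = 100, n_frames = 4, n_t1 = 1,
                              n_t2 = 0, n_rosette = 0, seed = 2)
  d1 <- detect_events(t1)
  expect_identical(c(d1$n_T1, d1$n_T2, d1$n_rosette), c(1L, 0L, 0L))
  t2 <- simulate_event_series(n_cells = 100, n_frames = 5, n_t1 = 0,
                              n_t2 = 1, n_rosette = 0, seed = 3)
  d2 <- detect_events(t2)
  expect_identical(c(d2$n_T1, d2$n_T2, d2$n_rosette), c(0L, 1L, 0L))
  rs <- simulate_event_series(n_cells = 100, n_frames = 4, n_t1 = 0,
                              n_t2 = 0, n_rosette = 1, seed = 4)
  d3 <- detect_events(rs)
  expect_identical(c(d3$n_T1, d3$n_T2, d3$n_rosette), c(0L, 0L, 1L))
  expect_error(detect_events(list()), "mesh_series")
})

test_that("detected events carry the planted cells and times", {
  ser <- simulate_event_series(n_cells = 150, n_frames = 8, n_t1 = 3,
                               n_t2 = 1, n_rosette = 1, seed = 5)
  det <- detect_events(ser)
  gt <- ser$ground_truth$events
  key <- function(df) sort(paste(df$time, df$kind, df$cells))
  expect_identical(key(det$events), key(gt))
  expect_lte(det$cells_involved, det$total_cells)
})
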