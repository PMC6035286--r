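test_that("triangulation builds one triangle per tricellular vertex", {
  m <- lattice_mesh()
  tri <- triangulate(m)
  deg <- lengths(m$vertex_cells)
  expect_identical(nrow(tri), sum(deg == 3L))
  # triangle cell triples are mutually adjacent
  keys <- wingmorph:::adjacency_keys(m)
  for (r in sample(nrow(tri), 25)) {
    trip <- sort(c(tri$a[r], tri$b[r], tri$c[r]))
    for (pair in list(trip[1:2], trip[2:3], trip[c(1, 3)])) {
      expect_true(paste(pair[1], pair[2], sep = ":") %in% keys)
    }
  }
  expect_true(all(tri$area > 0))
})

test_that("fourfold vertices are fanned into two triangles", {
  m <- fourfold_mesh()
  tri <- triangulate(m)
  expect_identical(nrow(tri), 2L)
  expect_identical(sort(unique(c(tri$a, tri$b, tri$c))), c(1L, 2L, 3L, 4L))
})

test_that("empty triangulation warns", {
  # three cells in a row share no tricellular vertex
  v <- as.matrix(expand.grid(x = 0:3, y = 0:1))
  id <- function(x, y) x + 1 + 4 * y
  cells <- list("1" = c(id(0, 0), id(1, 0), id(1, 1), id(0, 1)),
                "2" = c(id(1, 0), id(2, 0), id(2, 1), id(1, 1)),
                "3" = c(id(2, 0), id(3, 0), id(3, 1), id(2, 1)))
  m <- new_cell_mesh(v, cells)
  expect_warning(tri <- triangulate(m), "no interior")
  expect_identical(nrow(tri), 0L)
  expect_error(mean_elongation(tri), "empty")
})

test_that("elongation tensor is exact on known shapes", {
  s <- 2 / 3^0.25
  eq <- rbind(c(0, 0), c(s, 0), c(s / 2, s * sqrt(3) / 2))
  # equilateral at any scale/rotation/vertex order gives (0, 0)
  for (th in c(0, 0.3, 1.2)) {
    R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
    P <- 3.7 * eq %*% t(R)
    expect_lt(max(abs(triangle_elongation(P))), 1e-12)
    expect_lt(max(abs(triangle_elongation(P[c(2, 3, 1), ]))), 1e-12)
  }
  # pure shear of the equilateral gives exactly (s, 0)
  D <- diag(c(exp(0.3), exp(-0.3)))
  q <- triangle_elongation(eq %*% D)
  expect_equal(unname(q), c(0.3, 0), tolerance = 1e-10)
  # degenerate triangle refused
  expect_error(triangle_elongation(rbind(c(0, 0), c(1, 1), c(2, 2))), "degenerate")
})

test_that("elongation agrees with an eigendecomposition oracle on random triangles", {
  set.seed(42)
  worst <- 0
  for (i in 1:1000) {
    P <- random_triangle()
    q <- triangle_elongation(P)
    o <- oracle_triangle_q(P)
    worst <- max(worst, max(abs(q - o)))
  }
  expect_lt(worst, 1e-10)
})

test_that("rotation of the tissue rotates Q by twice the angle", {
  m <- apply_pure_shear(disordered_mesh(), 0.2)
  q0 <- mean_elongation(triangulate(m))
  for (th in c(pi / 6, pi / 4, pi / 2)) {
    q1 <- mean_elongation(triangulate(rotate_mesh(m, th)))
    R2 <- matrix(c(cos(2 * th), sin(2 * th), -sin(2 * th), cos(2 * th)), 2)
    expect_equal(unname(q1), as.vector(R2 %*% q0), tolerance = 1e-8)
  }
})

test_that("mean elongation responds exactly to shear on the isotropic lattice", {
  m <- lattice_mesh()
  q0 <- mean_elongation(triangulate(m))
  ms <- apply_pure_shear(m, 0.3)
  for (w in c("uniform", "area")) {
    q <- mean_elongation(triangulate(ms), w)
    expect_equal(unname(q - q0), c(0.3, 0), tolerance = 1e-6)
  }
  # on a disordered mesh additivity holds approximately (matrix logs of
  # non-commuting maps); the error is O(s |Q|^2) per triangle
  d <- disordered_mesh()
  qd <- mean_elongation(triangulate(d))
  qs <- mean_elongation(triangulate(apply_pure_shear(d, 0.3)))
  expect_equal(unname(qs - qd), c(0.3, 0), tolerance = 5e-3)
})

test_that("mean anisotropy bounds the mean tensor magnitude", {
  for (mesh in list(lattice_mesh(), disordered_mesh(),
                    apply_pure_shear(disordered_mesh(), 0.25))) {
    tri <- triangulate(mesh)
    q <- mean_elongation(tri)
    expect_gte(mean_anisotropy(tri) + 1e-12, sqrt(sum(q^2)))
  }
  # sheared lattice: all triangles share the same Q, so the two agree
  tri <- triangulate(apply_pure_shear(lattice_mesh(), 0.3))
  expect_equal(mean_anisotropy(tri), 0.3, tolerance = 1e-6)
})

test_that("tissue shape and natural strains", {
  m <- lattice_mesh()
  ref <- tissue_shape(m)
  expect_equal(tissue_shape(m, ref)$LmH, 0)
  ms <- apply_pure_shear(m, 0.15)
  shp <- tissue_shape(ms, ref)
  expect_equal(shp$L, 0.15, tolerance = 1e-12)
  expect_equal(shp$H, -0.15, tolerance = 1e-12)
  expect_equal(shp$LmH, 0.3, tolerance = 1e-12)
  # doubling l alone gives L = log 2
  m2 <- transform_mesh(m, diag(c(2, 1)))
  expect_equal(tissue_shape(m2, ref)$L, log(2), tolerance = 1e-12)
})

test_that("junction polarity ratio recovers planted polarity", {
  m <- disordered_mesh()
  jn <- mesh_junctions(m)
  # uniform intensities give 1
  expect_equal(junction_polarity_ratio(m, rep(3.3, nrow(jn))), 1)
  # doubling the AP-oriented class gives exactly 2
  I <- synth_junction_intensities(m, 2, noise_sd = 0, seed = 1)
  expect_equal(junction_polarity_ratio(m, I), 2, tolerance = 1e-12)
  expect_error(junction_polarity_ratio(m, I[-1]), "align")
  expect_error(junction_polarity_ratio(m, I, angle_threshold_deg = 1e-9), "empty")
})

test_that("apico-basal profile normalization", {
  lines <- list(rep(2, 50), rep(7, 50))
  expect_equal(apicobasal_profile(lines), rep(1, 50))
  # scaling one line leaves the result unchanged
  x <- sin(seq(0, pi, length.out = 50)) + 2
  y <- cos(seq(0, pi, length.out = 50)) + 2
  p1 <- apicobasal_profile(list(x, y))
  p2 <- apicobasal_profile(list(10 * x, y))
  expect_equal(p1, p2)
  expect_equal(mean(p1), 1)
  # a two-peak profile keeps its peak positions
  z <- rep(1, 100); z[c(25, 75)] <- 10
  p <- apicobasal_profile(list(z, 2 * z))
  expect_identical(sort(order(p, decreasing = TRUE)[1:2]), c(25L, 75L))
  expect_error(apicobasal_profile(list(1:5, 1:6)), "equal")
})

test_that("surface coverage with fixed and Otsu thresholds", {
  expect_equal(ecm_coverage(rep(10, 100), 1), 100)
  expect_equal(ecm_coverage(rep(0.1, 100), 1), 0)
  p <- synth_surface_profile(0.3, 1000, contrast = 10, seed = 2)
  expect_equal(ecm_coverage(p, "otsu"), 30, tolerance = 2 / 30)
  expect_error(ecm_coverage(numeric(0)), "empty")
})

test_that("mesh recovered from labels matches the generator ground truth", {
  fx <- rendered_fixture()
  rec <- mesh_from_labels(fx$render$labels, pixel_size = 1 / 45)
  expect_identical(length(rec$cell_ids), n_cells(fx$mesh))
  expect_setequal(wingmorph:::adjacency_keys(rec),
                  wingmorph:::adjacency_keys(fx$mesh))
  # centroids within 1 px of the polygon centroids (after origin shift)
  bb <- apply(fx$mesh$vertices, 2, range)
  pad <- 2 / 45
  shift <- cbind(rec$centroids[, 1] + bb[1, 1] - pad,
                 rec$centroids[, 2] + bb[1, 2] - pad)
  truth <- fx$mesh$centroids[match(as.integer(rownames(rec$centroids)),
                                   fx$mesh$cell_ids), ]
  expect_lt(max(sqrt(rowSums((shift - truth)^2))) * 45, 1)
  # too few labels is an error
  expect_error(mesh_from_labels(matrix(c(0, 1, 1, 0), 2)), ">= 3")
})
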