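test_that("mesh topology is derived correctly and invariants hold", {
  m <- disordered_mesh()
  expect_s3_class(m, "cell_mesh")
  expect_true(validate_cell_mesh(m))
  # adjacency unordered pairs, irreflexive
  expect_true(all(m$adjacency[, 1] < m$adjacency[, 2]))
  # every adjacent pair shares at least two vertices (an edge)
  for (r in sample(nrow(m$adjacency), 20)) {
    a <- m$cells[[match(m$adjacency[r, 1], m$cell_ids)]]
    b <- m$cells[[match(m$adjacency[r, 2], m$cell_ids)]]
    expect_gte(length(intersect(a, b)), 2)
  }
  # polygons positively oriented
  expect_true(all(m$areas > 0))
  # cells tile the tessellated region: no overlap beyond bbox
  bb <- apply(m$vertices, 2, range)
  expect_lte(sum(m$areas), prod(bb[2, ] - bb[1, ]) * (1 + 1e-9))
})

test_that("pure shear preserves area exactly and maps coordinates as (e^s, e^-s)", {
  m <- disordered_mesh()
  for (s in c(-0.4, 0.123, 0.3)) {
    ms <- apply_pure_shear(m, s)
    expect_lt(abs(sum(ms$areas) - sum(m$areas)) / sum(m$areas), 1e-9)
    expect_equal(ms$vertices[, 1], m$vertices[, 1] * exp(s))
    expect_equal(ms$vertices[, 2], m$vertices[, 2] * exp(-s))
  }
  # s = 0 is the identity
  expect_equal(apply_pure_shear(m, 0)$vertices, m$vertices)
})

test_that("junction table is consistent with adjacency", {
  m <- lattice_mesh()
  jn <- mesh_junctions(m)
  k1 <- sort(paste(jn$cell_a, jn$cell_b, sep = ":"))
  k2 <- sort(paste(m$adjacency[, 1], m$adjacency[, 2], sep = ":"))
  expect_identical(k1, k2)
  # regular lattice: all junctions have the same length
  expect_lt(diff(range(jn$length)), 1e-5)
})

test_that("degenerate transforms are refused", {
  m <- lattice_mesh()
  expect_error(transform_mesh(m, matrix(c(1, 0, 0, -1), 2)), "determinant")
  expect_error(new_cell_mesh(matrix(1:9, 3), list()), "n x 2")
})

test_that("jitter is seeded and topology-preserving", {
  m <- lattice_mesh()
  j1 <- jitter_mesh(m, 0.02, 5)
  j2 <- jitter_mesh(m, 0.02, 5)
  expect_identical(j1$vertices, j2$vertices)
  expect_false(identical(j1$vertices, m$vertices))
  expect_identical(j1$cells, m$cells)
  expect_identical(j1$adjacency, m$adjacency)
})
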