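test_that("mesh generation is deterministic and has the requested size", {
  a <- make_cell_mesh(100, 0.3, 7)
  b <- make_cell_mesh(100, 0.3, 7)
  expect_identical(a, b)
  expect_identical(n_cells(a), 100L)
  c <- make_cell_mesh(100, 0.3, 8)
  expect_false(identical(a$vertices, c$vertices))
})

test_that("disorder 0 gives congruent regular hexagons in the interior", {
  m <- lattice_mesh()
  deg <- lengths(m$cells)
  interior <- setdiff(m$cell_ids, wingmorph:::boundary_cells(m))
  expect_true(all(deg[match(interior, m$cell_ids)] == 6L))
  # all interior cells congruent: equal areas, equal edge lengths
  ar <- m$areas[match(interior, m$cell_ids)]
  expect_lt(diff(range(ar)), 1e-5)
  # downstream isotropy: per-triangle elongation vanishes
  q <- triangle_elongations(triangulate(m))
  expect_lt(max(abs(q)), 1e-6)
})

test_that("cell areas are consistent with the tessellated area", {
  m <- make_cell_mesh(200, 0.3, 7)
  # mean area x n within 5% of the tessellated lattice area (n sites, each
  # owning sqrt(3)/2 square units of the unit-spacing hexagonal lattice)
  expected <- 200 * sqrt(3) / 2
  expect_lt(abs(mean(m$areas) * 200 - expected) / expected, 0.05)
})

test_that("generator argument validation", {
  expect_error(make_cell_mesh(3), ">= 4")
  expect_error(make_cell_mesh(10, disorder = 1.2), "disorder")
})
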