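test_that("a T1 exchanges exactly the expected adjacency pair", {
  m <- disordered_mesh()
  cand <- wingmorph:::t1_candidate_edges(m)
  expect_gt(nrow(cand), 50)
  r <- 5
  out <- plant_t1(m, cand$v1[r], cand$v2[r])
  expect_true(validate_cell_mesh(out))
  lost <- setdiff(wingmorph:::adjacency_keys(m), wingmorph:::adjacency_keys(out))
  gained <- setdiff(wingmorph:::adjacency_keys(out), wingmorph:::adjacency_keys(m))
  expect_identical(lost, paste(min(cand$cell_a[r], cand$cell_b[r]),
                               max(cand$cell_a[r], cand$cell_b[r]), sep = ":"))
  expect_identical(gained, paste(min(cand$cell_c[r], cand$cell_d[r]),
                                 max(cand$cell_c[r], cand$cell_d[r]), sep = ":"))
  # the new junction has the pre-collapse edge length
  jn <- mesh_junctions(out)
  new_j <- jn[jn$cell_a == min(cand$cell_c[r], cand$cell_d[r]) &
              jn$cell_b == max(cand$cell_c[r], cand$cell_d[r]), ]
  expect_equal(new_j$length, cand$length[r], tolerance = 1e-9)
  # total cell count unchanged
  expect_identical(n_cells(out), n_cells(m))
})

test_that("T2 removes the cell and leaves neighbors intact", {
  m <- disordered_mesh()
  vic <- setdiff(m$cell_ids, wingmorph:::boundary_cells(m))[1]
  out <- plant_t2(m, vic)
  expect_false(vic %in% out$cell_ids)
  expect_identical(n_cells(out), n_cells(m) - 1L)
  keep <- setdiff(m$cell_ids, vic)
  expect_equal(out$areas[match(keep, out$cell_ids)],
               m$areas[match(keep, m$cell_ids)])
  expect_error(plant_t2(m, 99999), "unknown")
})

test_that("shrinking a cell reduces its area and grows its neighbors", {
  m <- disordered_mesh()
  vic <- setdiff(m$cell_ids, wingmorph:::boundary_cells(m))[2]
  out <- shrink_cell(m, vic, 0.5)
  a0 <- m$areas[match(vic, m$cell_ids)]
  a1 <- out$areas[match(vic, out$cell_ids)]
  expect_lt(a1, 0.5 * a0)
  expect_true(validate_cell_mesh(out))
  # neighbors take up the vacated space
  nb <- unique(c(m$adjacency[m$adjacency[, 1] == vic, 2],
                 m$adjacency[m$adjacency[, 2] == vic, 1]))
  gain <- sum(out$areas[match(nb, out$cell_ids)]) -
    sum(m$areas[match(nb, m$cell_ids)])
  expect_gt(gain, 0)
  expect_error(shrink_cell(m, vic, 1.5), "factor")
})

test_that("rosette formation produces a high-order vertex", {
  m <- disordered_mesh()
  deg <- lengths(m$vertex_cells)
  bc <- wingmorph:::boundary_cells(m)
  v <- which(deg == 3L &
             vapply(m$vertex_cells, function(cc)
               length(cc) == 3L && !any(cc %in% bc), logical(1)))[5]
  out <- plant_rosette(m, v)
  expect_gte(max(lengths(out$vertex_cells)), 5L)
  expect_true(length(attr(out, "rosette_cells")) >= 5L)
})
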