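test_that("rendering is seeded and byte-identical", {
  m <- make_cell_mesh(25, 0.3, 2)
  a <- render_membrane_image(m, 30, 2, snr = 5, seed = 9)
  b <- render_membrane_image(m, 30, 2, snr = 5, seed = 9)
  expect_identical(a$image, b$image)
  expect_identical(a$labels, b$labels)
  c <- render_membrane_image(m, 30, 2, snr = 5, seed = 10)
  expect_false(identical(a$image, c$image))
})

test_that("label raster has one positive value per cell and 0 on membrane", {
  fx <- rendered_fixture()
  ids <- setdiff(unique(as.vector(fx$render$labels)), 0L)
  expect_identical(length(ids), n_cells(fx$mesh))
  expect_setequal(ids, fx$mesh$cell_ids)
  expect_gt(sum(fx$render$labels == 0), 0)
})

test_that("renderer refuses oversized rasters and bad arguments", {
  m <- make_cell_mesh(25, 0.3, 2)
  expect_error(render_membrane_image(m, 1000, 2, max_pixels = 1e5), "max_pixels")
  expect_error(render_membrane_image(m, -1, 2), "px_per_unit")
  expect_error(render_membrane_image(m, 30, 0.5), "membrane_width_px")
})
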