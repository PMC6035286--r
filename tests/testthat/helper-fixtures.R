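# Shared fixtures, built once per test run and cached.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

lattice_mesh <- function() fixture("lattice", function() make_cell_mesh(100, 0, 1))
disordered_mesh <- function() fixture("disordered", function() make_cell_mesh(200, 0.3, 7))

rendered_fixture <- function() fixture("rendered", function() {
  m <- make_cell_mesh(100, 0.3, 4)
  list(mesh = m, render = render_membrane_image(m, px_per_unit = 45,
                                                membrane_width_px = 2,
                                                snr = Inf, seed = 1))
})

# random non-degenerate triangle (3 x 2), counter-clockwise
random_triangle <- function() {
  repeat {
    P <- matrix(stats::rnorm(6), 3, 2)
    a2 <- (P[2, 1] - P[1, 1]) * (P[3, 2] - P[1, 2]) -
          (P[2, 2] - P[1, 2]) * (P[3, 1] - P[1, 1])
    if (abs(a2) > 0.1) break
  }
  if (a2 < 0) P <- P[c(1, 3, 2), ]
  P
}

# independent oracle: Q = 1/2 log(M M^T / det M) via explicit symmetric
# eigendecomposition (base eigen), fully separate from the package's
# hyperbolic closed form.
oracle_triangle_q <- function(P) {
  s <- 2 / 3^0.25
  R <- rbind(c(s, 0), c(s / 2, s * sqrt(3) / 2))
  M <- t(P[2:3, ] - rep(1, 2) %o% P[1, ]) %*% solve(t(R))
  A <- M %*% t(M) / det(M)
  e <- eigen((A + t(A)) / 2, symmetric = TRUE)
  L <- e$vectors %*% diag(log(e$values)) %*% t(e$vectors) / 2
  c(qxx = L[1, 1], qxy = L[1, 2])
}

# tiny 2x2 block of quads sharing a central fourfold vertex
fourfold_mesh <- function() {
  v <- as.matrix(expand.grid(x = 0:2, y = 0:2))
  id <- function(x, y) x + 1 + 3 * y
  cells <- list(
    "1" = c(id(0, 0), id(1, 0), id(1, 1), id(0, 1)),
    "2" = c(id(1, 0), id(2, 0), id(2, 1), id(1, 1)),
    "3" = c(id(1, 1), id(2, 1), id(2, 2), id(1, 2)),
    "4" = c(id(0, 1), id(1, 1), id(1, 2), id(0, 2))
  )
  new_cell_mesh(v, cells)
}
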