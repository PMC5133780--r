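# Quadrature grids, Wigner-Seitz ownership, region overlaps.

test_that("grid has the expected point count and hard-cell weights", {
  m <- water_geometry()
  g <- build_partitioned_grid(m, 75L, 302L)
  expect_equal(length(g$w_base), 3L * 75L * 302L)
  # hard cells: effective weight is the base weight or exactly zero
  expect_true(all(g$w_eff == g$w_base | g$w_eff == 0))
  expect_true(all(tabulate(g$owner[g$w_eff > 0], 3L) >= 1L))
  expect_error(build_partitioned_grid(m, 75L, 123L), "supported orders")
  expect_error(build_partitioned_grid(m, 5L, 110L), "n_radial")
})

test_that("Lebedev point sets integrate spherical harmonics exactly", {
  for (ord in c(6L, 50L, 302L)) {
    tab <- lebedev_points(ord)
    expect_equal(sum(tab[, 4]), 4 * pi, tolerance = 1e-10)
    # degree-2 exactness: int x^2 dOmega = 4 pi / 3
    expect_equal(sum(tab[, 1]^2 * tab[, 4]), 4 * pi / 3,
                 tolerance = 1e-10)
  }
})

test_that("ownership follows the nearest-atom rule with low-index tie-break", {
  m <- molecule(c("H", "H"), rbind(c(0, 0, 0), c(0, 0, 2)), unit = "bohr")
  mid <- matrix(c(0.3, -0.1, 1), 1, 3)   # equidistant plane point
  expect_equal(nearest_atom(mid, m$coords), 1L)
  off <- matrix(c(0, 0, 1.2), 1, 3)
  expect_equal(nearest_atom(off, m$coords), 2L)
})

test_that("ownership is invariant under rigid translation", {
  m <- water_geometry()
  g <- build_partitioned_grid(m, 35L, 110L)
  shift <- c(1.3, -0.7, 2.1)
  m2 <- molecule(m$symbols, sweep(m$coords, 2, shift, "+"),
                 unit = "bohr")
  g2 <- build_partitioned_grid(m2, 35L, 110L)
  expect_equal(g2$owner, g$owner)
  expect_equal(g2$w_eff, g$w_eff, tolerance = 1e-12)
})

test_that("partition integrates normalized Gaussians to unity", {
  m <- water_geometry()
  g <- build_partitioned_grid(m, 75L, 302L)
  sel <- g$w_eff > 0
  pts <- g$points[sel, ]
  w <- g$w_eff[sel]
  for (a in 1:3) {
    alpha <- 1.0
    d2 <- rowSums(sweep(pts, 2, m$coords[a, ])^2)
    f <- (2 * alpha / pi)^1.5 * exp(-2 * alpha * d2)  # normalized square
    expect_equal(sum(w * f), 1, tolerance = 1e-3)
  }
})

test_that("region overlaps close to orthonormality and improve on refinement", {
  w <- water_sto3g()
  res <- vapply(list(c(35L, 110L), c(50L, 194L), c(75L, 302L)),
                function(gs) {
                  g <- build_partitioned_grid(w$mol, gs[1], gs[2])
                  overlap_residual(region_overlaps(w, g))
                }, numeric(1))
  expect_lt(res[3], 2e-2)
  # non-increasing within 10% over three standard refinement steps
  expect_true(all(diff(res) < 0.1 * res[-3]))
})

test_that("homonuclear symmetry relates the two atomic regions of H2", {
  w <- make_h2_minimal(0.5)
  g <- build_partitioned_grid(w$mol, 50L, 194L)
  ro <- region_overlaps(w, g)
  # |G| equal between atoms; bonding diagonal symmetric, od antisymmetric
  expect_equal(abs(ro$G[1, , ]), abs(ro$G[2, , ]), tolerance = 1e-6)
  expect_equal(ro$G[1, 1, 1], ro$G[2, 1, 1], tolerance = 1e-6)
  expect_equal(ro$G[1, 1, 2], -ro$G[2, 1, 2], tolerance = 1e-6)
})

test_that("own-cell and union-binned estimates agree within quadrature error", {
  w <- water_sto3g()
  g <- build_partitioned_grid(w$mol, 75L, 302L)
  own <- region_overlaps(w, g)
  uni <- region_overlaps(w, g, mode = "union")
  tol <- 3 * max(overlap_residual(own), overlap_residual(uni))
  expect_lt(max(abs(own$G - uni$G)), tol)
})
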