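# Plane detection, reflection-parity classification, channel splitting.

test_that("plane detection: planar, non-planar, and linear cases", {
  pl <- detect_molecular_plane(water_geometry())
  expect_false(is.null(pl))
  expect_false(pl$degenerate)
  expect_lt(pl$rms, 1e-6)
  # all three atoms lie in the detected plane
  d <- sweep(water_geometry()$coords, 2, pl$point) %*% pl$normal
  expect_lt(max(abs(d)), 1e-6)

  hex <- load_xyz(shipped_xyz("hexan-1-ol"))
  expect_null(detect_molecular_plane(hex))

  h2 <- molecule(c("H", "H"), rbind(c(0, 0, 0), c(0, 0, 1.4)),
                 unit = "bohr")
  pl2 <- detect_molecular_plane(h2)
  expect_true(pl2$degenerate)
})

test_that("ethylene-like model yields exactly one occupied pi MO", {
  w <- make_ethylene_like()
  plane <- list(point = c(0, 0, 0), normal = c(0, 1, 0))
  lab <- classify_orbitals(w, plane)
  expect_equal(sum(lab$label[w$occ > 0] == "pi"), 1L)
  expect_equal(sum(lab$label == "mixed"), 0L)
  expect_length(lab$label, w$nmo)   # every MO gets exactly one label
})

test_that("parity scores match brute-force numerical reflection", {
  w <- make_ethylene_like()
  plane <- list(point = c(0, 0, 0), normal = c(0, 1, 0))
  lab <- classify_orbitals(w, plane)
  # numerical <psi|sigma psi> on a dense cube
  sp <- seq(-4.2, 4.2, length.out = 29)
  pts <- as.matrix(expand.grid(sp, sp, sp))
  h3 <- diff(sp)[1]^3
  psi <- eval_mos(w, pts)
  refl <- pts; refl[, 2] <- -refl[, 2]
  psir <- eval_mos(w, refl)
  num <- colSums(psi * psir) * h3
  nrm <- colSums(psi * psi) * h3
  expect_equal(lab$score, num / nrm, tolerance = 5e-3)
})

test_that("water has exactly one occupied pi orbital (out-of-plane lone pair)", {
  w <- cached_wfn("h2o-b3lyp-6311gss")
  pl <- detect_molecular_plane(w$mol)
  lab <- classify_orbitals(w, pl)
  expect_equal(sum(lab$label[w$occ > 0] == "pi"), 1L)
})

test_that("channel decomposition is exactly additive with vanishing cross term", {
  w <- make_ethylene_like()
  plane <- list(point = c(0, 0, 0), normal = c(0, 1, 0))
  lab <- classify_orbitals(w, plane)
  g <- build_partitioned_grid(w$mol, 50L, 194L)
  ro <- region_overlaps(w, g)
  pb <- build_pair_basis(w)
  dm <- density_matrix(w)
  pw <- pair_bond_weights(w, dm, pb)
  dec <- decompose_response(lab, pb, ro, weights = pw, type = "bond")
  expect_equal(dec$sigma$values + dec$pi$values + dec$cross$values,
               dec$total$values, tolerance = 1e-12)
  decd <- decompose_response(lab, pb, ro, type = "density")
  expect_equal(decd$sigma$values + decd$pi$values + decd$cross$values,
               decd$total$values, tolerance = 1e-12)
  # mirror-symmetric cells: sigma-pi cross channel integrates to ~0
  expect_lt(max(abs(decd$cross$values)), 1e-3)
  expect_equal(dec$contamination, 0)
})
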