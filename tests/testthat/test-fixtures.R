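# Model-wavefunction generators.

test_that("minimal H2 model satisfies every wavefunction invariant exactly", {
  w <- make_h2_minimal(0.5)
  expect_equal(crossprod(w$C, w$S %*% w$C), diag(2), tolerance = 1e-12)
  # analytic overlap equals the engine's overlap for the chosen geometry
  expect_equal(overlap_matrix(w$basis), w$S, tolerance = 1e-12)
  expect_error(make_h2_minimal(0), "0, 1")
  expect_error(make_h2_minimal(1.2), "0, 1")
})

test_that("random models are reproducible and pass validation", {
  a <- make_random_model(9, 4, seed = 123)
  b <- make_random_model(9, 4, seed = 123)
  expect_identical(a$C, b$C)
  expect_identical(a$eps, b$eps)
  expect_false(identical(a$C, make_random_model(9, 4, seed = 124)$C))
  expect_lt(max(abs(crossprod(a$C, a$S %*% a$C) - diag(9))), 1e-10)
  expect_true(all(diff(a$eps) >= 0.05 - 1e-12))
  expect_error(make_random_model(13, 2, seed = 1), "n_ao")
  expect_error(make_random_model(6, 6, seed = 1), "n_occ")
})

test_that("SCF engine reproduces standard closed-form reference energies", {
  # H2/STO-3G at R = 1.4 bohr and water/STO-3G: textbook RHF values
  h2 <- run_scf(molecule(c("H", "H"), rbind(c(0, 0, 0), c(0, 0, 1.4)),
                         unit = "bohr"),
                scf_method(functional = "hf", basis = "sto-3g"))
  expect_equal(h2$method$energy, -1.11671, tolerance = 2e-5)
  w <- water_sto3g()
  expect_equal(w$method$energy, -74.96293, tolerance = 2e-4)
})

test_that("s-type electron repulsion integrals match the closed form", {
  # (ss|ss) over normalized single Gaussians has an erf/Boys closed form
  m <- molecule(c("H", "H"), rbind(c(0, 0, 0), c(0, 0, 1.7)),
                unit = "bohr")
  a <- 0.9; b <- 1.3
  bas <- lrfbo:::.make_aobasis(m, list(
    list(l = 0L, atom = 1L, exp = a, coef = 1),
    list(l = 0L, atom = 2L, exp = b, coef = 1)), "cartesian", "test")
  G <- eri_tensor(bas)
  na <- (2 * a / pi)^0.75; nb <- (2 * b / pi)^0.75
  # (aa|bb): two centres, closed form with F0(T) = erf(sqrt(T))*sqrt(pi/(4T))
  p <- 2 * a; q <- 2 * b; R2 <- 1.7^2
  T <- p * q / (p + q) * R2
  erf <- function(x) 2 * pnorm(x * sqrt(2)) - 1
  F0 <- 0.5 * sqrt(pi / T) * erf(sqrt(T))
  ref <- 2 * pi^2.5 / (p * q * sqrt(p + q)) * F0 * na^2 * nb^2
  expect_equal(G[1, 1, 2, 2], ref, tolerance = 1e-10)
})

test_that("ethylene-like fixture drives the sigma/pi machinery end to end", {
  w <- make_ethylene_like()
  expect_equal(sum(w$occ), 4)
  expect_lt(max(abs(crossprod(w$C, w$S %*% w$C) - diag(4))), 1e-10)
  # serialises to Molden and returns intact
  f <- withr::local_tempfile(fileext = ".molden")
  write_molden(w, f)
  w2 <- read_molden(f)
  expect_equal(abs(w2$C), abs(w$C), tolerance = 1e-8)
})
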