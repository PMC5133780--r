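# Density-matrix algebra: P, Q = PS, Mayer bond orders, Mulliken charges.

test_that("minimal H2 model has closed-form P, Q and exact unit bond order", {
  for (s in c(0.2, 0.5, 0.8)) {
    w <- make_h2_minimal(s)
    dm <- density_matrix(w)
    expect_equal(dm$P, matrix(1 / (1 + s), 2, 2), tolerance = 1e-12)
    expect_equal(dm$Q, matrix(1, 2, 2), tolerance = 1e-12)
    B <- mayer_bond_orders(wfn = w)
    expect_equal(B[1, 2], 1, tolerance = 1e-12)
  }
})

test_that("q_matrix is the plain product and validates dimensions", {
  expect_equal(q_matrix(diag(3), diag(3)), diag(3))
  expect_error(q_matrix(diag(3), diag(2)), "dimension")
  P <- matrix(rnorm(16), 4); P <- P + t(P)
  S <- diag(4)
  expect_equal(sum(diag(q_matrix(P, S))), sum(diag(P %*% S)))
})

test_that("bond-order table closes onto Tr(Q^2) and twice the electron count", {
  w <- water_sto3g()
  dm <- density_matrix(w)
  B <- mayer_bond_orders(wfn = w)
  expect_equal(sum(B), sum(diag(dm$Q %*% dm$Q)), tolerance = 1e-8)
  # idempotent closed-shell density: Tr(Q^2) = 2 N_elec
  expect_equal(sum(B), 2 * w$mol$nelec, tolerance = 1e-6)
  expect_equal(B, t(B), tolerance = 1e-12)
  expect_equal(B[1, 2], B[1, 3], tolerance = 1e-6) # C2v symmetry
})

test_that("bond orders are equivariant under atom relabelling", {
  w <- make_random_model(6, 2, seed = 11)
  dm <- density_matrix(w)
  B <- mayer_bond_orders(dm$Q, w$basis$ao_atom)
  perm <- c(3L, 1L, 2L, 6L, 4L, 5L)
  # relabel atoms: AO -> atom map through the permutation
  B2 <- mayer_bond_orders(dm$Q, perm[w$basis$ao_atom])
  expect_equal(B2[perm, perm], unclass(B)[seq_along(perm), seq_along(perm)],
               ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("Mulliken charges conserve charge and give positive H in polar H-X", {
  h2 <- run_scf(molecule(c("H", "H"), rbind(c(0, 0, 0), c(0, 0, 1.4)),
                         unit = "bohr"),
                scf_method(functional = "hf", basis = "sto-3g"))
  q <- mulliken_charges(h2)
  expect_equal(unname(q), c(0, 0), tolerance = 1e-8)
  whf <- cached_wfn("hf-b3lyp-6311gss")
  qhf <- mulliken_charges(whf)
  expect_equal(sum(qhf), 0, tolerance = 1e-8)
  expect_gt(qhf[["H2"]], 0)   # hydrogen is the positive end of H-F
})

test_that("diffuse-marker basis names trigger the population-analysis warning", {
  m <- molecule("H", matrix(0, 1, 3), charge = -1L)
  lib <- read_basis_library("sto-3g")
  f <- withr::local_tempfile(fileext = ".bas")
  writeLines(c("ELEMENT H", "S 1", " 1.0 1.0", "END"), f)
  file.copy(f, fp <- file.path(tempdir(), "6-31++gss.bas"),
            overwrite = TRUE)
  expect_warning(build_basis(m, fp), "diffuse")
})
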