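# Molecule/XYZ handling, SCF contracts, MO evaluation, Molden exchange.

test_that("XYZ parsing converts units, reads charge tokens and rejects bad input", {
  f <- withr::local_tempfile(fileext = ".xyz")
  writeLines(c("3", "water charge=0 mult=1",
               "O 0.0 0.0 0.0",
               "H 0.0 0.0 1.0",
               "H 0.0 0.9572 0.0"), f)
  m <- load_xyz(f)
  expect_length(m$symbols, 3L)
  expect_equal(m$multiplicity, 1L)
  # 1 Angstrom -> CODATA Bohr
  expect_equal(m$coords[2, 3], 1.8897261255, tolerance = 1e-9)

  writeLines(c("1", "", "Xx 0 0 0"), f)
  expect_error(load_xyz(f), "unknown element")
  writeLines(c("1", "", "H 0 zero 0"), f)
  expect_error(load_xyz(f), "non-numeric")
  # open-shell requests are out of scope
  expect_error(molecule("O", matrix(0, 1, 3), multiplicity = 3L),
               "unsupported")
})

test_that("run_scf returns a validated closed-shell wavefunction", {
  m <- molecule(c("H", "H"), rbind(c(0, 0, 0), c(0, 0, 1.4)),
                unit = "bohr")
  w <- run_scf(m, scf_method(functional = "hf", basis = "sto-3g"))
  expect_s3_class(w, "wavefunction")
  expect_equal(sum(w$occ), 2)
  orth <- max(abs(crossprod(w$C, w$S %*% w$C) - diag(w$nmo)))
  expect_lt(orth, 1e-6)
  # electron count via Tr(PS)
  dm <- density_matrix(w)
  expect_equal(sum(diag(dm$Q)), 2, tolerance = 1e-8)
})

test_that("water wavefunction has 5 doubly occupied orbitals and 10 electrons", {
  w <- cached_wfn("h2o-b3lyp-6311gss")
  expect_equal(sum(w$occ > 0), 5)
  expect_equal(sum(w$occ), 10)
  expect_lt(max(abs(crossprod(w$C, w$S %*% w$C) - diag(w$nmo))), 1e-6)
})

test_that("eval_mos decays far from the molecule and equals AO x C", {
  w <- water_sto3g()
  far <- matrix(c(50, 0, 0), 1, 3)
  expect_lt(max(abs(eval_mos(w, far))), 1e-12)
  set.seed(42)
  pts <- matrix(rnorm(30), 10, 3)
  ao <- eval_ao(w$basis, pts)$v
  expect_equal(eval_mos(w, pts), ao %*% w$C, tolerance = 1e-12)
  expect_error(eval_mos(w, matrix(c(NA, 0, 0), 1, 3)), "finite")
})

test_that("quadrature recovers MO orthonormality for water", {
  w <- water_sto3g()
  g <- build_partitioned_grid(w$mol, 75L, 302L)
  ro <- region_overlaps(w, g)
  tot <- apply(ro$G, c(2, 3), sum)
  expect_lt(max(abs(tot - diag(w$nmo))), 1e-4 * 200) # 2e-2 grid tolerance
  occ <- which(w$occ > 0)
  for (i in occ) expect_equal(tot[i, i], 1, tolerance = 2e-2)
})

test_that("Molden round trip preserves the wavefunction", {
  w <- water_sto3g()
  f <- withr::local_tempfile(fileext = ".molden")
  write_molden(w, f)
  w2 <- read_molden(f)
  expect_equal(abs(w2$C), abs(w$C), tolerance = 1e-8)
  expect_equal(w2$eps, w$eps, tolerance = 1e-8)
  expect_equal(mayer_bond_orders(wfn = w2), mayer_bond_orders(wfn = w),
               tolerance = 1e-6)
})

test_that("Molden reader rejects unrestricted and corrupt files", {
  w <- make_h2_minimal(0.4)
  f <- withr::local_tempfile(fileext = ".molden")
  write_molden(w, f)
  # fabricate a differing beta block
  lines <- readLines(f)
  mo_at <- grep("\\[MO\\]", lines)
  blk <- lines[(mo_at + 1):length(lines)]
  beta <- gsub("Spin= Alpha", "Spin= Beta", blk)
  cid <- grep("^ [0-9]+ ", beta)
  beta[cid[1]] <- " 1 9.9e-01"
  writeLines(c(lines, beta), f)
  expect_error(read_molden(f), "unrestricted")
  # corrupt coefficients break orthonormality validation
  write_molden(w, f)
  lines <- readLines(f)
  lines <- sub("^ 1 [-0-9.eE+]+$", " 1 5.0", lines)
  writeLines(lines, f)
  expect_error(read_molden(f), "orthonormality violated")
})

test_that("d shells count 6 Cartesian or 5 spherical AOs", {
  m <- molecule("O", matrix(0, 1, 3))
  b6 <- build_basis(m, "6-311gss", harmonic = "cartesian")
  b5 <- build_basis(m, "6-311gss", harmonic = "spherical")
  expect_equal(sum(b6$ao_l == 2), 6L)
  expect_equal(sum(b5$ao_l == 2), 5L)
  # both representations give the same Mulliken-invariant trace structure
  expect_equal(nrow(overlap_matrix(b5)), b5$nao)
})
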