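# The uncoupled linear-response engine: pair structure, factorized vs
# direct evaluation, an independent finite-difference oracle, sum rules.

test_that("pair basis enumerates occ x virt with negative denominators", {
  w <- cached_wfn("h2o-b3lyp-6311gss")
  pb <- build_pair_basis(w)
  expect_equal(nrow(pb), 5L * (w$nmo - 5L))
  expect_true(all(pb$d < 0))
  # degenerate HOMO-LUMO gap is a hard error
  wd <- make_random_model(6, 2, seed = 3)
  wd$eps[3] <- wd$eps[2]
  expect_error(build_pair_basis(wd), "degenerate")
  # energy-window truncation is recorded
  pbw <- build_pair_basis(w, energy_window = 1.0)
  expect_lt(nrow(pbw), nrow(pb))
  expect_equal(attr(pbw, "energy_window"), 1.0)
})

test_that("pair weights satisfy the exact trace identity and I-J symmetry", {
  w <- water_sto3g()
  dm <- density_matrix(w)
  pb <- build_pair_basis(w)
  pw <- pair_bond_weights(w, dm, pb)
  expect_lt(max(abs(apply(pw$w, 1, sum))), 1e-10)
  for (p in c(1L, 7L, nrow(pb)))
    expect_equal(pw$w[p, , ], t(pw$w[p, , ]), tolerance = 1e-12)
})

test_that("the H2 bond weight and bond response vanish identically", {
  w <- make_h2_minimal(0.5)
  dm <- density_matrix(w)
  pb <- build_pair_basis(w)
  pw <- pair_bond_weights(w, dm, pb)
  expect_equal(pw$w[1, 1, 2], 0, tolerance = 1e-14)
  expect_equal(pw$w[1, 2, 1], 0, tolerance = 1e-14)
  set.seed(1)
  pts <- matrix(rnorm(60), 20, 3)
  v <- lrf_bo_pointwise(w, dm, pb, pw, pts, rbind(c(1, 2)))
  expect_lt(max(abs(v)), 1e-12)
})

test_that("factorized and direct pointwise paths agree to near machine precision", {
  for (seed in c(7L, 21L)) {
    m <- make_random_model(8, 3, seed = seed)
    dm <- density_matrix(m)
    pb <- build_pair_basis(m)
    pw <- pair_bond_weights(m, dm, pb)
    set.seed(seed)
    pts <- matrix(rnorm(60) * 1.2, 20, 3)
    ap <- as.matrix(expand.grid(1:8, 1:8))
    vf <- lrf_bo_pointwise(m, dm, pb, pw, pts, ap, method = "factorized")
    vd <- lrf_bo_pointwise(m, dm, pb, pw, pts, ap, method = "direct")
    expect_lt(max(abs(vf - vd)), 1e-10)
    # all-pair pointwise sum vanishes for an idempotent density
    expect_lt(max(abs(rowSums(vf))), 1e-10)
  }
})

test_that("kernel matches a finite-difference uncoupled response oracle", {
  m <- make_random_model(7, 3, seed = 5)
  dm <- density_matrix(m)
  pb <- build_pair_basis(m)
  pw <- pair_bond_weights(m, dm, pb)
  S <- m$S; C <- m$C
  F <- S %*% C %*% diag(m$eps) %*% t(C) %*% S  # Fock with these orbitals
  r0 <- c(0.3, -0.2, 0.5)
  sp <- seq(-0.8, 0.8, length.out = 33)
  pts <- as.matrix(expand.grid(sp + r0[1], sp + r0[2], sp + r0[3]))
  h3 <- diff(sp)[1]^3
  gv <- exp(-40 * rowSums(sweep(pts, 2, r0)^2))
  ao <- eval_ao(m$basis, pts)$v
  V1 <- crossprod(ao, gv * ao) * h3
  es <- eigen(S, symmetric = TRUE)
  X <- es$vectors %*% diag(1 / sqrt(es$values)) %*% t(es$vectors)
  bond_orders_at <- function(lambda) {
    e <- eigen(t(X) %*% (F + lambda * V1) %*% X, symmetric = TRUE)
    ord <- order(e$values)
    Cn <- X %*% e$vectors[, ord]
    P <- 2 * tcrossprod(Cn[, 1:3])
    mayer_bond_orders(P %*% S, m$basis$ao_atom)
  }
  lam <- 1e-5
  dB_fd <- (bond_orders_at(lam) - bond_orders_at(-lam)) / (2 * lam)
  ap <- as.matrix(expand.grid(1:7, 1:7))
  v <- lrf_bo_pointwise(m, dm, pb, pw, pts, ap)
  dB_kernel <- matrix(colSums(gv * v) * h3, 7, 7)
  expect_equal(unclass(dB_fd), dB_kernel, tolerance = 1e-5,
               ignore_attr = TRUE)
})

test_that("condensed table is I-J symmetric with vanishing row sums", {
  w <- water_sto3g()
  st <- response_stack(w)
  expect_equal(st$bo$values, aperm(st$bo$values, c(2, 1, 3)),
               tolerance = 1e-10)
  sr <- sum_rule_report(st$bo, w, st$dm, st$pairs, st$weights)
  expect_lt(sr$max_row_residual, 2e-2)
  expect_lt(sr$pointwise_residual, 1e-9)
})

test_that("condensed density response is symmetric with non-positive diagonal", {
  w <- water_sto3g()
  st <- response_stack(w, 50L, 194L)
  ld <- lrf_density_condensed(st$pairs, st$overlaps)
  expect_equal(ld$values, t(ld$values), tolerance = 1e-10)
  expect_true(all(diag(ld$values) <= 0))
})

test_that("long-format export carries the CSV schema", {
  w <- make_h2_minimal(0.3)
  st <- response_stack(w, 35L, 110L)
  d <- as.data.frame(st$bo)
  expect_named(d, c("atom_I", "atom_J", "perturb_atom_L", "channel",
                    "value"))
  expect_equal(nrow(d), 8L)
})
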