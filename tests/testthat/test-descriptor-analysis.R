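# Sign semantics, leaving-group ranking, Hammett regression layer.

test_that("sign interpretation implements all four table cells plus zero", {
  expect_equal(interpret_sign(1.2, "repulsive"), "increase")
  expect_equal(interpret_sign(1.2, "attractive"), "decrease")
  expect_equal(interpret_sign(-0.4, "repulsive"), "decrease")
  expect_equal(interpret_sign(-0.4, "attractive"), "increase")
  expect_equal(interpret_sign(0, "repulsive"), "no first-order change")
  expect_error(interpret_sign(NaN), "finite")
})

test_that("leaving-group ranking orders literature Pt-complex values correctly", {
  # printed reference values for [Pt(NH3)Cl3]-: the three Pt-Cl bonds and
  # Pt-N, used here as input data for the ranking layer
  v <- c("Pt-Cl(1)" = 6.064, "Pt-Cl(2)" = 5.890, "Pt-Cl(3)" = 5.952,
         "Pt-N" = 2.091)
  r <- rank_leaving_groups(v)
  expect_equal(r$bond[1], "Pt-Cl(1)")    # predicted substitution site
  expect_equal(r$bond[4], "Pt-N")        # ammine ranks last
  expect_true(all(r$value > 0))          # electrophilic attack labilises
  expect_equal(interpret_sign(r$value[1], "repulsive"), "increase")
  # singleton input
  expect_equal(nrow(rank_leaving_groups(c("M-X" = 1.0))), 1L)
})

test_that("ranking from a condensed table is a pure, order-stable function", {
  w <- water_sto3g()
  st <- response_stack(w, 35L, 110L)
  bonds <- rbind(c(1L, 2L), c(1L, 3L))
  r1 <- rank_leaving_groups(st$bo, bonds)
  r2 <- rank_leaving_groups(st$bo, bonds[2:1, , drop = FALSE])
  expect_equal(r1$value, r2$value, tolerance = 1e-12)
  expect_equal(r1$ligand, r2$ligand)  # ties broken by atom index
  expect_error(rank_leaving_groups(st$bo, rbind(c(1L, 9L))),
               "out of range")
})

test_that("linear_fit recovers collinear data exactly and rejects degeneracy", {
  f <- linear_fit(c(1, 2, 3), c(2, 4, 6))
  expect_equal(f$r2, 1, tolerance = 1e-12)
  expect_equal(f$slope, 2, tolerance = 1e-12)
  expect_equal(f$predict(10), 20, tolerance = 1e-10)
  expect_error(linear_fit(rep(1, 5), 1:5), "degenerate")
  # permutation null: shuffled responses decorrelate
  set.seed(99)
  x <- rnorm(20); y <- 2 * x + rnorm(20, sd = 0.05)
  f0 <- linear_fit(x, sample(y))
  expect_lt(f0$r2, 0.3)
  # affine rescaling of x leaves R^2 unchanged
  f1 <- linear_fit(x, y); f2 <- linear_fit(3 * x - 5, y)
  expect_equal(f1$r2, f2$r2, tolerance = 1e-12)
  expect_equal(f2$slope, f1$slope / 3, tolerance = 1e-10)
})

test_that("hammett records enforce the scope rules", {
  expect_error(
    hammett_records("NMe3+", "para", 0.8, -1.0, charged = TRUE),
    "charged")
  expect_error(hammett_records("X", "ortho", 0.1, -1.0), "meta, para")
  r <- hammett_records(c("H", "F"), c("none", "meta"), c(0, 0.34),
                       c(-1.0, -1.1))
  expect_s3_class(r, "hammett_records")
})

test_that("per-site report recovers a synthetic linear relation within 5%", {
  set.seed(17)
  n <- 15L
  a_true <- -0.85; b_true <- 0.12
  for (pos in c("meta", "para")) {
    d <- runif(n, -2.5, -0.5)
    sig <- a_true * d + b_true + rnorm(n, sd = 0.002)
    rec <- hammett_records(sprintf("X%02d", 1:n), rep(pos, n), sig, d)
    rep_ <- hammett_report(rec, sites = "atomH")
    row <- rep_[rep_$position == pos, ]
    expect_equal(nrow(row), 1L)
    expect_lt(abs(row$slope - a_true) / abs(a_true), 0.05)
    expect_lt(abs(row$intercept - b_true) / abs(b_true), 0.05)
    expect_gt(row$r2, 0.95)
  }
  # identical descriptor values -> degenerate-x error
  rec0 <- hammett_records(sprintf("X%d", 1:5), rep("meta", 5),
                          runif(5), rep(-1, 5))
  expect_error(hammett_report(rec0), "degenerate")
})

test_that("report flags high-correlation sites with negligible descriptors", {
  set.seed(4)
  n <- 10L
  d_small <- runif(n, -5e-3, -1e-3)
  sig <- -100 * d_small + rnorm(n, sd = 0.01)
  rec <- hammett_records(sprintf("X%d", 1:n), rep("para", n), sig,
                         d_small)
  rp <- hammett_report(rec, sites = "phenylC")
  expect_true(rp$flagged[1])
})
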