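# Exchange-correlation functionals (closed-shell / spin-restricted forms).
#
# Energy densities are implemented analytically as vectorised functions of
# (rho, gamma = |grad rho|^2); the potentials v_rho = d e/d rho and
# v_gamma = d e/d gamma entering the Kohn-Sham matrix are obtained by
# central finite differences of the energy density, which is accurate to
# ~1e-9 here and keeps every functional's code to its textbook formula.
#
# B3LYP = 0.20 E_x^HF + 0.08 E_x^Slater + 0.72 E_x^B88
#         + 0.19 E_c^VWN + 0.81 E_c^LYP,
# with the VWN flavour (VWN5 vs VWN3/RPA) selectable.

.RHO_FLOOR <- 1e-12

# Slater (LDA) exchange, closed shell: e = -Cx rho^(4/3)
.ex_slater <- function(rho, gam) {
  cx <- (3 / 4) * (3 / pi)^(1 / 3)
  -cx * rho^(4 / 3)
}

# Becke 1988 gradient-corrected exchange (the correction plus LDA is the
# usual B88; here only the gradient correction term, beta form, per spin,
# summed for the closed shell)
.ex_b88 <- function(rho, gam) {
  beta <- 0.0042
  rs <- rho / 2                      # per-spin density
  gs <- pmax(gam, 0) / 4             # per-spin |grad|^2
  x <- sqrt(gs) / rs^(4 / 3)
  e1 <- -beta * rs^(4 / 3) * x^2 / (1 + 6 * beta * x * asinh(x))
  2 * e1
}

.vwn_params <- list(
  vwn5 = c(A = 0.0310907, x0 = -0.10498, b = 3.72744, c = 12.9352),
  vwn3 = c(A = 0.0310907, x0 = -0.409286, b = 13.0720, c = 42.7198))

# VWN correlation (paramagnetic fit), closed shell: e = rho * ec(rs)
.ec_vwn <- function(rho, gam, flavor = "vwn5") {
  p <- .vwn_params[[flavor]]
  A <- p["A"]; x0 <- p["x0"]; b <- p["b"]; cc <- p["c"]
  rs <- (3 / (4 * pi * rho))^(1 / 3)
  x <- sqrt(rs)
  X <- x^2 + b * x + cc
  X0 <- x0^2 + b * x0 + cc
  Q <- sqrt(4 * cc - b^2)
  at <- atan(Q / (2 * x + b))
  ec <- A * (log(x^2 / X) + 2 * b / Q * at -
             b * x0 / X0 * (log((x - x0)^2 / X) +
                            2 * (b + 2 * x0) / Q * at))
  rho * as.numeric(ec)
}

# Lee-Yang-Parr correlation (Miehlich et al. form), closed shell
.ec_lyp <- function(rho, gam) {
  a <- 0.04918; b <- 0.132; cc <- 0.2533; d <- 0.349
  cf <- 0.3 * (3 * pi^2)^(2 / 3)
  g <- pmax(gam, 0)
  r13 <- rho^(-1 / 3)
  denom <- 1 + d * r13
  om <- exp(-cc * r13) / denom * rho^(-11 / 3)
  de <- cc * r13 + d * r13 / denom
  ra <- rho / 2; rb <- rho / 2
  gaa <- g / 4; gbb <- g / 4; gab <- g / 4
  t1 <- -a * 4 / denom * ra * rb / rho
  t2 <- 2^(11 / 3) * cf * (ra^(8 / 3) + rb^(8 / 3))
  t3 <- (47 / 18 - 7 * de / 18) * g
  t4 <- -(5 / 2 - de / 18) * (gaa + gbb)
  t5 <- -(de - 11) / 9 * (ra / rho * gaa + rb / rho * gbb)
  t6 <- -2 / 3 * rho^2 * g
  t7 <- (2 / 3 * rho^2 - ra^2) * gbb + (2 / 3 * rho^2 - rb^2) * gaa
  t1 - a * b * om * (ra * rb * (t2 + t3 + t4 + t5) + t6 + t7)
}

# assemble the functional's energy density e(rho, gamma) given weights
.xc_energy_density <- function(rho, gam, spec) {
  e <- 0
  if (spec["slater"] != 0) e <- e + spec["slater"] * .ex_slater(rho, gam)
  if (spec["b88"] != 0) e <- e + spec["b88"] * .ex_b88(rho, gam)
  if (spec["vwn"] != 0)
    e <- e + spec["vwn"] * .ec_vwn(rho, gam, attr(spec, "vwn_flavor"))
  if (spec["lyp"] != 0) e <- e + spec["lyp"] * .ec_lyp(rho, gam)
  e
}

# e, v_rho, v_gamma on a vector of grid values
xc_eval <- function(rho, gam, spec) {
  ok <- rho > .RHO_FLOOR
  e <- vr <- vg <- numeric(length(rho))
  r <- rho[ok]; g <- gam[ok]
  e[ok] <- .xc_energy_density(r, g, spec)
  hr <- pmax(1e-7 * r, 1e-14)
  vr[ok] <- (.xc_energy_density(r + hr, g, spec) -
             .xc_energy_density(r - hr, g, spec)) / (2 * hr)
  hg <- pmax(1e-7 * g, 1e-16)
  vg[ok] <- (.xc_energy_density(r, g + hg, spec) -
             .xc_energy_density(r, g - hg, spec)) / (2 * hg)
  list(e = e, vrho = vr, vgamma = vg)
}

# functional specification: coefficients of the components + HF exchange
xc_spec <- function(functional = c("b3lyp", "hf", "svwn", "blyp"),
                    b3lyp_flavor = c("vwn5", "vwn3")) {
  functional <- match.arg(functional)
  b3lyp_flavor <- match.arg(b3lyp_flavor)
  spec <- switch(functional,
    hf    = c(slater = 0, b88 = 0, vwn = 0, lyp = 0, hfx = 1),
    svwn  = c(slater = 1, b88 = 0, vwn = 1, lyp = 0, hfx = 0),
    blyp  = c(slater = 1, b88 = 1, vwn = 0, lyp = 1, hfx = 0),
    b3lyp = c(slater = 0.80, b88 = 0.72, vwn = 0.19, lyp = 0.81,
              hfx = 0.20))
  attr(spec, "vwn_flavor") <- b3lyp_flavor
  attr(spec, "name") <- functional
  spec
}
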