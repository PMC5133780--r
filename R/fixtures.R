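# Analytic model wavefunctions.  Every numerical module is testable on
# these without any SCF run: the AO bases are real spherical/For p-type
# Gaussian shells evaluated by the same engine as production bases, and
# the MOs are orthonormalised against the analytic overlap by
# construction, so all wavefunction invariants hold exactly.

# build an aobasis object directly from shell descriptions
.model_basis <- function(mol, shells) {
  .make_aobasis(mol, shells, harmonic = "cartesian", name = "model")
}

#' Minimal two-AO dihydrogen model
#'
#' Two 1s Gaussians with analytic AO overlap `s` (the intercentre distance
#' is chosen so that the unit-exponent Gaussians overlap to exactly `s`).
#' The occupied bonding MO is `(1,1)/sqrt(2(1+s))`, the virtual
#' antibonding MO `(1,-1)/sqrt(2(1-s))`; orbital energies -0.5 and +0.5
#' hartree.  The textbook system in which the bond-order response
#' vanishes identically.
#'
#' @param ao_overlap AO overlap `s` in (0, 1).
#' @return a [wavefunction_data()] object.
#' @export
make_h2_minimal <- function(ao_overlap = 0.5) {
  s <- ao_overlap
  if (!(s > 0 && s < 1)) stop("ao_overlap must lie in (0, 1)")
  alpha <- 1.0
  # normalized s Gaussians, exponent a: <g_A|g_B> = exp(-a R^2 / 2)
  R <- sqrt(-2 * log(s) / alpha)
  mol <- molecule(c("H", "H"), rbind(c(0, 0, 0), c(0, 0, R)),
                  unit = "bohr")
  bas <- .model_basis(mol, list(
    list(l = 0L, atom = 1L, exp = alpha, coef = 1),
    list(l = 0L, atom = 2L, exp = alpha, coef = 1)))
  S <- matrix(c(1, s, s, 1), 2, 2)
  C <- cbind(c(1, 1) / sqrt(2 * (1 + s)),
             c(1, -1) / sqrt(2 * (1 - s)))
  wavefunction_data(C, eps = c(-0.5, 0.5), occ = c(2, 0), S = S,
                    basis = bas, mol = mol,
                    method = list(functional = "model",
                                  basis = "h2-minimal", backend = "model"))
}

#' Seeded random model wavefunction
#'
#' `n_ao` s-type Gaussians at random centres with random exponents; MOs
#' are the symmetric (Loewdin) orthogonalisation of a seeded random
#' matrix against the analytic overlap, so every wavefunction invariant
#' holds to machine precision.  Orbital energies are strictly increasing
#' with gaps of at least 0.05 hartree.
#'
#' @param n_ao number of AOs (2..12).
#' @param n_occ number of doubly occupied MOs (0 < n_occ < n_ao).
#' @param seed integer seed; same seed, same wavefunction.
#' @return a [wavefunction_data()] object.
#' @export
make_random_model <- function(n_ao = 6L, n_occ = 2L, seed = 1L) {
  if (!(n_occ > 0 && n_occ < n_ao && n_ao <= 12))
    stop("need 0 < n_occ < n_ao <= 12")
  set.seed(seed)
  centers <- matrix(stats::runif(3 * n_ao, -1.5, 1.5), n_ao, 3)
  exps <- stats::runif(n_ao, 0.6, 1.8)
  mol <- molecule(rep("H", n_ao), centers,
                  charge = as.integer(n_ao - 2 * n_occ), unit = "bohr")
  bas <- .model_basis(mol, lapply(seq_len(n_ao), function(a)
    list(l = 0L, atom = a, exp = exps[a], coef = 1)))
  S <- overlap_matrix(bas)
  M <- matrix(stats::rnorm(n_ao * n_ao), n_ao, n_ao)
  # Loewdin orthogonalisation against S
  W <- crossprod(M, S %*% M)
  e <- eigen(W, symmetric = TRUE)
  C <- M %*% e$vectors %*% diag(1 / sqrt(e$values), n_ao) %*%
    t(e$vectors)
  eps <- -1 + cumsum(stats::runif(n_ao, 0.05, 0.3))
  wavefunction_data(C, eps = eps,
                    occ = c(rep(2, n_occ), rep(0, n_ao - n_occ)), S = S,
                    basis = bas, mol = mol,
                    method = list(functional = "model",
                                  basis = sprintf("random-%d-%d-%d",
                                                  n_ao, n_occ, seed),
                                  backend = "model"))
}

#' Planar two-centre sigma/pi test-bed
#'
#' Two centres on the x axis, each carrying an s shell (in-plane) and a p
#' shell whose y component points out of the xz plane.  The four MOs used
#' are sigma(s+s), pi(p_y+p_y) (both occupied), pi*(p_y-p_y) and
#' sigma*(s-s); exactly one occupied MO is of pi symmetry with respect to
#' the xz plane.
#'
#' @param distance intercentre distance (Bohr).
#' @return a [wavefunction_data()] object (4 electrons; model charge).
#' @export
make_ethylene_like <- function(distance = 2.5) {
  R <- distance
  mol <- molecule(c("H", "H"), rbind(c(-R / 2, 0, 0), c(R / 2, 0, 0)),
                  charge = -2L, unit = "bohr")
  bas <- .model_basis(mol, list(
    list(l = 0L, atom = 1L, exp = 1.0, coef = 1),
    list(l = 1L, atom = 1L, exp = 0.8, coef = 1),
    list(l = 0L, atom = 2L, exp = 1.0, coef = 1),
    list(l = 1L, atom = 2L, exp = 0.8, coef = 1)))
  S <- overlap_matrix(bas)
  # AO order: s1, px1, py1, pz1, s2, px2, py2, pz2
  ss <- S[1, 5]          # s-s overlap
  pp <- S[3, 7]          # py-py overlap
  Csig  <- c(1, 0, 0, 0, 1, 0, 0, 0) / sqrt(2 * (1 + ss))
  Cpi   <- c(0, 0, 1, 0, 0, 0, 1, 0) / sqrt(2 * (1 + pp))
  Cpis  <- c(0, 0, 1, 0, 0, 0, -1, 0) / sqrt(2 * (1 - pp))
  Csigs <- c(1, 0, 0, 0, -1, 0, 0, 0) / sqrt(2 * (1 - ss))
  C <- cbind(Csig, Cpi, Cpis, Csigs)
  wavefunction_data(C, eps = c(-1.0, -0.4, 0.3, 1.0),
                    occ = c(2, 2, 0, 0), S = S, basis = bas, mol = mol,
                    method = list(functional = "model",
                                  basis = "ethylene-like",
                                  backend = "model"))
}
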