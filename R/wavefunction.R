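#' Closed-shell wavefunction container
#'
#' Holds spatial MO coefficients over the AO basis, orbital energies,
#' occupations (2/0), the AO overlap matrix, the AO basis (including the
#' AO -> atom map) and the molecule.  Validation enforces the closed-shell
#' contracts: MO orthonormality against S, electron-count consistency and
#' a symmetric positive-definite overlap.
#'
#' @param C AO x MO coefficient matrix.
#' @param eps orbital energies (hartree).
#' @param occ occupation numbers (2 for occupied, 0 for virtual).
#' @param S AO overlap matrix.
#' @param basis an [build_basis()] object (supplies the AO -> atom map).
#' @param mol the [molecule()].
#' @param method list of method metadata (functional, basis name, flavor,
#'   backend, ...).
#' @param orth_tol tolerance on `max |C'SC - I|`.
#' @return object of class `"wavefunction"`.
#' @export
wavefunction_data <- function(C, eps, occ, S, basis, mol, method = list(),
                              orth_tol = 1e-6) {
  C <- unname(as.matrix(C)); S <- unname(as.matrix(S))
  nao <- nrow(C); nmo <- ncol(C)
  if (length(eps) != nmo) stop("length(eps) must equal ncol(C)")
  if (length(occ) != nmo) stop("length(occ) must equal ncol(C)")
  if (!all(occ %in% c(0, 2)))
    stop("unsupported system: occupations must be 0 or 2 (restricted ",
         "closed shell)")
  if (nrow(S) != nao || ncol(S) != nao)
    stop("S must be nao x nao")
  if (basis$nao != nao) stop("basis AO count does not match C")
  orth <- max(abs(crossprod(C, S %*% C) - diag(nmo)))
  if (orth > orth_tol)
    stop(sprintf(
      "MO orthonormality violated: max |C'SC - I| = %.3e (tol %.1e); %s",
      orth, orth_tol,
      "corrupt coefficients or mismatched d-shell convention"))
  if (!isTRUE(all.equal(S, t(S), tolerance = 1e-8)))
    stop("overlap matrix is not symmetric")
  if (min(eigen(S, symmetric = TRUE, only.values = TRUE)$values) <= 0)
    stop("overlap matrix is not positive definite")
  if (sum(occ) != mol$nelec)
    stop("sum of occupations (", sum(occ),
         ") does not match the molecular electron count (", mol$nelec, ")")
  structure(list(C = C, eps = as.numeric(eps), occ = as.numeric(occ),
                 S = S, basis = basis, mol = mol, method = method,
                 nocc = sum(occ > 0), nao = nao, nmo = nmo),
            class = "wavefunction")
}

#' @export
print.wavefunction <- function(x, ...) {
  cat(sprintf(
    "<wavefunction> %s/%s: %d AOs, %d MOs, %d electrons%s\n",
    toupper(x$method$functional %||% "?"), x$method$basis %||% "?",
    x$nao, x$nmo, sum(x$occ),
    if (!is.null(x$method$energy))
      sprintf(", E = %.8f hartree", x$method$energy) else ""))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate molecular orbitals at points
#'
#' @param wfn a [wavefunction_data()] object.
#' @param points npt x 3 matrix of Cartesian points (Bohr).
#' @param mos optional MO index subset.
#' @return npt x length(mos) matrix of MO amplitudes.
#' @export
eval_mos <- function(wfn, points, mos = NULL) {
  points <- as.matrix(points)
  if (!all(is.finite(points))) stop("points must be finite")
  ao <- eval_ao(wfn$basis, points)$v
  C <- if (is.null(mos)) wfn$C else wfn$C[, mos, drop = FALSE]
  ao %*% C
}

# indices of occupied / virtual spatial orbitals
occupied <- function(wfn) which(wfn$occ > 0)
virtuals <- function(wfn) which(wfn$occ == 0)
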