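# Density-matrix algebra: P, Q = PS, Mayer bond orders, Mulliken charges.

#' One-particle density matrix and Q matrix
#'
#' For a restricted closed-shell wavefunction, `P = sum_occ 2 c_i c_i'` and
#' `Q = P S` (the Mayer bond-order matrix product).
#'
#' @param wfn a [wavefunction_data()] object.
#' @return object of class `"density_matrices"`: list with `P`, `Q`.
#' @export
density_matrix <- function(wfn) {
  stopifnot(inherits(wfn, "wavefunction"))
  Cocc <- wfn$C[, wfn$occ > 0, drop = FALSE]
  P <- tcrossprod(Cocc %*% diag(wfn$occ[wfn$occ > 0],
                                nrow = sum(wfn$occ > 0)), Cocc)
  structure(list(P = P, Q = q_matrix(P, wfn$S)),
            class = "density_matrices")
}

#' Q matrix
#' @param P density matrix (AO x AO).
#' @param S overlap matrix (AO x AO).
#' @return `Q = P %*% S`.
#' @export
q_matrix <- function(P, S) {
  if (!is.matrix(P) || !is.matrix(S) || any(dim(P) != dim(S)))
    stop("P and S must be square matrices of equal dimension")
  P %*% S
}

.atom_labels <- function(mol) paste0(mol$symbols, seq_along(mol$symbols))

# atom x AO indicator (aggregation) matrix
.atom_agg <- function(ao_atom, nat) {
  A <- matrix(0, nat, length(ao_atom))
  A[cbind(ao_atom, seq_along(ao_atom))] <- 1
  A
}

#' Mayer bond orders
#'
#' `B_IJ = sum_{mu in I, nu in J} Q_munu Q_numu`, including the diagonal
#' (`I = J`) entries, whose presence makes the response sum rules close.
#'
#' @param Q the Q matrix (or a [density_matrix()] result).
#' @param ao_atom integer AO -> atom map (1-based); taken from `wfn` when a
#'   wavefunction is supplied via `wfn`.
#' @param wfn optional [wavefunction_data()]; supplies `Q` and the map.
#' @return symmetric atom x atom matrix of class `"bond_order_table"` with
#'   `El#` dimnames.
#' @export
mayer_bond_orders <- function(Q = NULL, ao_atom = NULL, wfn = NULL) {
  if (!is.null(wfn)) {
    dm <- density_matrix(wfn)
    Q <- dm$Q
    ao_atom <- wfn$basis$ao_atom
    labels <- .atom_labels(wfn$mol)
  } else {
    labels <- NULL
  }
  if (length(ao_atom) != nrow(Q))
    stop("ao_atom must map every AO index")
  nat <- max(ao_atom)
  A <- .atom_agg(ao_atom, nat)
  B <- A %*% (Q * t(Q)) %*% t(A)
  B <- (B + t(B)) / 2
  if (!is.null(labels)) dimnames(B) <- list(labels, labels)
  class(B) <- c("bond_order_table", class(B))
  B
}

#' @export
print.bond_order_table <- function(x, digits = 3, ...) {
  m <- unclass(x)
  print(round(m, digits))
  invisible(x)
}

#' Mulliken atomic charges
#'
#' `q_A = Z_A - sum_{mu in A} Q_mumu`.
#'
#' @param wfn a [wavefunction_data()] object.
#' @param dm optional precomputed [density_matrix()].
#' @return named numeric vector of charges (e); sums to the total charge.
#' @export
mulliken_charges <- function(wfn, dm = density_matrix(wfn)) {
  pop <- vapply(seq_along(wfn$mol$z), function(a)
    sum(diag(dm$Q)[wfn$basis$ao_atom == a]), numeric(1))
  setNames(wfn$mol$z - pop, .atom_labels(wfn$mol))
}

#' Export a bond-order table as CSV
#' @param B a [mayer_bond_orders()] table.
#' @param path output CSV path.
#' @export
write_bond_orders <- function(B, path) {
  write.csv(as.data.frame(as.matrix(B)), path, row.names = TRUE)
  invisible(path)
}
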