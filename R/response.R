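# The uncoupled linear-response engine.
#
# First-order response of the density matrix to a local potential
# perturbation delta-v(r), over occupied (i) x virtual (j) pairs of a
# closed-shell determinant (spin summation = global factor 2):
#
#   dP_munu/dv(r) = 2 sum_ij psi_i(r) psi_j(r) / (eps_i - eps_j)
#                      * (C_jmu C_inu + C_imu C_jnu)
#
# dQ/dv follows by right-multiplication with S, and the bond-order response
# is dB_IJ/dv(r) = sum_{mu in I, nu in J} (dQ_munu Q_numu + Q_munu dQ_numu).
# The production path factorises this into per-pair condensed bond weights
# w^(ij)_IJ (geometry-independent) times region overlaps
# G^L_ij = int_L psi_i psi_j dr, so that
#
#   dB_IJ/dv(L) = 2 sum_ij w^(ij)_IJ G^L_ij / (eps_i - eps_j).
#
# A direct (unfactorised) pointwise evaluation is retained as an oracle.

#' Occupied-virtual pair basis
#'
#' Enumerates all occupied x virtual MO pairs with their energy
#' denominators `d_ij = 1/(eps_i - eps_j)` (hartree^-1, all negative for an
#' aufbau ground state).
#'
#' @param wfn a [wavefunction_data()] object.
#' @param energy_window optional maximum `eps_j - eps_i` (hartree) beyond
#'   which pairs are dropped (virtual-space truncation; recorded in the
#'   result).
#' @param degeneracy_tol pairs with `|eps_i - eps_j|` at or below this are a
#'   hard error (the uncoupled response diverges).
#' @return object of class `"pair_basis"`: data frame columns `i`, `j`,
#'   `d` plus metadata attributes.
#' @export
build_pair_basis <- function(wfn, energy_window = NULL,
                             degeneracy_tol = 1e-6) {
  occ <- occupied(wfn); vir <- virtuals(wfn)
  if (length(vir) == 0L) stop("no virtual orbitals: response undefined")
  pb <- expand.grid(i = occ, j = vir)
  gap <- wfn$eps[pb$i] - wfn$eps[pb$j]
  if (any(abs(gap) <= degeneracy_tol))
    stop(sprintf(
      "degenerate occupied-virtual gap (min |gap| = %.2e hartree <= %.1e): %s",
      min(abs(gap)), degeneracy_tol,
      "the uncoupled linear response diverges"))
  pb$d <- 1 / gap
  if (!is.null(energy_window)) {
    keep <- (-gap) <= energy_window
    pb <- pb[keep, , drop = FALSE]
  }
  attr(pb, "energy_window") <- energy_window
  attr(pb, "degeneracy_tol") <- degeneracy_tol
  class(pb) <- c("pair_basis", class(pb))
  pb
}

#' Per-pair condensed bond-response weights
#'
#' For each occupied-virtual pair (i,j), builds the pair Q-derivative
#' matrix `M^(ij) = (c_j c_i' + c_i c_j') S` and condenses it onto atom
#' pairs: `w^(ij)_IJ = sum_{mu in I, nu in J} (M_munu Q_numu + Q_munu
#' M_numu)`.  By MO orthonormality, `sum_IJ w^(ij)_IJ = 0` exactly.
#'
#' @param wfn a [wavefunction_data()] object.
#' @param dm [density_matrix()] result.
#' @param pairs [build_pair_basis()] result.
#' @return object of class `"pair_weights"`: array `w` of dimension
#'   (npairs, natoms, natoms).
#' @export
pair_bond_weights <- function(wfn, dm = density_matrix(wfn),
                              pairs = build_pair_basis(wfn)) {
  nat <- length(wfn$mol$z)
  A <- .atom_agg(wfn$basis$ao_atom, nat)
  S <- wfn$S; Q <- dm$Q; Qt <- t(Q)
  w <- array(0, dim = c(nrow(pairs), nat, nat))
  SC <- S %*% wfn$C
  for (p in seq_len(nrow(pairs))) {
    ci <- wfn$C[, pairs$i[p]]; cj <- wfn$C[, pairs$j[p]]
    sci <- SC[, pairs$i[p]]; scj <- SC[, pairs$j[p]]
    M <- tcrossprod(cj, sci) + tcrossprod(ci, scj)  # (c_j c_i' + c_i c_j')S
    X <- M * Qt + Q * t(M)
    w[p, , ] <- A %*% X %*% t(A)
  }
  structure(list(w = w, npairs = nrow(pairs), natoms = nat,
                 labels = .atom_labels(wfn$mol)),
            class = "pair_weights")
}

#' Pointwise bond-order response (oracle-grade)
#'
#' Evaluates `dB_IJ/dv(r)` at arbitrary points, either through the
#' factorised pair weights (production algebra) or by the direct
#' element-by-element chain dP -> dQ -> dB (cross-validation oracle).
#'
#' @param wfn,dm,pairs,weights as in [pair_bond_weights()].
#' @param points npt x 3 matrix (Bohr).
#' @param atom_pairs matrix or data frame of (I, J) atom index pairs.
#' @param method `"factorized"` or `"direct"`.
#' @return npt x npair matrix; columns named `I-J`.
#' @export
lrf_bo_pointwise <- function(wfn, dm, pairs, weights, points,
                             atom_pairs, method = c("factorized",
                                                    "direct")) {
  method <- match.arg(method)
  points <- as.matrix(points)
  atom_pairs <- as.matrix(atom_pairs)
  psi <- eval_mos(wfn, points)
  out <- matrix(0, nrow(points), nrow(atom_pairs))
  colnames(out) <- paste0(weights$labels[atom_pairs[, 1]], "-",
                          weights$labels[atom_pairs[, 2]])
  if (method == "factorized") {
    prod_ij <- psi[, pairs$i, drop = FALSE] * psi[, pairs$j, drop = FALSE]
    for (k in seq_len(nrow(atom_pairs))) {
      wij <- weights$w[, atom_pairs[k, 1], atom_pairs[k, 2]]
      out[, k] <- 2 * prod_ij %*% (pairs$d * wij)
    }
  } else {
    ao_atom <- wfn$basis$ao_atom
    S <- wfn$S; Q <- dm$Q
    for (g in seq_len(nrow(points))) {
      dP <- matrix(0, wfn$nao, wfn$nao)
      for (p in seq_len(nrow(pairs))) {
        ci <- wfn$C[, pairs$i[p]]; cj <- wfn$C[, pairs$j[p]]
        amp <- 2 * pairs$d[p] * psi[g, pairs$i[p]] * psi[g, pairs$j[p]]
        dP <- dP + amp * (tcrossprod(cj, ci) + tcrossprod(ci, cj))
      }
      dQ <- dP %*% S
      for (k in seq_len(nrow(atom_pairs))) {
        mi <- ao_atom == atom_pairs[k, 1]
        mj <- ao_atom == atom_pairs[k, 2]
        out[g, k] <- sum(dQ[mi, mj, drop = FALSE] *
                           t(Q[mj, mi, drop = FALSE])) +
                     sum(Q[mi, mj, drop = FALSE] *
                           t(dQ[mj, mi, drop = FALSE]))
      }
    }
  }
  out
}

#' Atom-condensed bond-order response table
#'
#' `dB_IJ/dv(L)`: the response of the Mayer bond order B_IJ to a virtual
#' local potential integrated over atom L's Wigner-Seitz cell.  Positive
#' values mean a repulsive perturbation at L increases the bond order.
#'
#' @param weights [pair_bond_weights()] result.
#' @param pairs [build_pair_basis()] result.
#' @param overlaps [region_overlaps()] result on the same wavefunction.
#' @param channel channel tag stored in the result (`"total"` unless
#'   produced by [decompose_response()]).
#' @return object of class `"condensed_lrf"` with `values[I, J, L]`.
#' @export
lrf_bo_condensed <- function(weights, pairs, overlaps,
                             channel = "total") {
  G <- overlaps$G  # dim (nat, nmo, nmo)
  if (dim(G)[2] < max(pairs$j))
    stop("region overlaps do not cover all MO pairs")
  nat <- weights$natoms
  npair <- nrow(pairs)
  # gather G[L, i_p, j_p] into npair x nat
  Gp <- matrix(0, npair, nat)
  for (L in seq_len(nat))
    Gp[, L] <- G[L, , ][cbind(pairs$i, pairs$j)]
  vals <- array(0, dim = c(nat, nat, nat),
                dimnames = list(weights$labels, weights$labels,
                                weights$labels))
  wd <- weights$w * pairs$d  # recycles d over pairs dimension
  for (L in seq_len(nat)) {
    acc <- matrix(0, nat, nat)
    for (p in seq_len(npair))
      acc <- acc + wd[p, , ] * Gp[p, L]
    vals[, , L] <- 2 * acc
  }
  structure(list(values = vals, type = "bond", channel = channel,
                 labels = weights$labels,
                 grid = overlaps$grid_spec),
            class = "condensed_lrf")
}

#' Atom-condensed density response table
#'
#' `drho(K)/dv(L) = 4 sum_ij G^K_ij G^L_ij / (eps_i - eps_j)`; symmetric,
#' with non-positive diagonal.
#'
#' @param pairs [build_pair_basis()] result.
#' @param overlaps [region_overlaps()] result.
#' @param channel channel tag.
#' @return `"condensed_lrf"` with matrix `values[K, L]`.
#' @export
lrf_density_condensed <- function(pairs, overlaps, channel = "total") {
  G <- overlaps$G
  nat <- dim(G)[1L]
  Gp <- matrix(0, nrow(pairs), nat)
  for (L in seq_len(nat))
    Gp[, L] <- G[L, , ][cbind(pairs$i, pairs$j)]
  vals <- 4 * t(Gp) %*% (pairs$d * Gp)
  vals <- (vals + t(vals)) / 2
  dimnames(vals) <- list(overlaps$labels, overlaps$labels)
  structure(list(values = vals, type = "density", channel = channel,
                 labels = overlaps$labels, grid = overlaps$grid_spec),
            class = "condensed_lrf")
}

#' @export
print.condensed_lrf <- function(x, digits = 4, ...) {
  cat(sprintf("<condensed_lrf> %s response, channel %s\n", x$type,
              x$channel))
  if (x$type == "density") {
    print(round(x$values, digits))
  } else {
    cat("slices values[, , L] give dB_IJ/dv(L); atoms: ",
        paste(x$labels, collapse = " "), "\n")
  }
  invisible(x)
}

#' Long-format view of a condensed response table
#' @param x a `"condensed_lrf"`.
#' @param ... unused.
#' @return data frame with columns (atom_I, atom_J | atom_K),
#'   perturb_atom_L, channel, value.
#' @export
as.data.frame.condensed_lrf <- function(x, ...) {
  if (x$type == "bond") {
    d <- expand.grid(atom_I = x$labels, atom_J = x$labels,
                     perturb_atom_L = x$labels, stringsAsFactors = FALSE)
    d$channel <- x$channel
    d$value <- as.vector(x$values)
  } else {
    d <- expand.grid(atom_K = x$labels, perturb_atom_L = x$labels,
                     stringsAsFactors = FALSE)
    d$channel <- x$channel
    d$value <- as.vector(x$values)
  }
  d
}

#' Sum-rule diagnostics
#'
#' Two exact identities diagnose the numerics: (a) summed over all
#' perturbation cells L, every `dB_IJ/dv(L)` must vanish (exact in the
#' complete integral, accurate to quadrature error on a grid); (b) summed
#' over *all* atom pairs (I,J) including diagonals, the pointwise response
#' `dB/dv(r)` vanishes identically (grid-independent, holds to machine
#' precision for an idempotent density).
#'
#' @param tbl a bond-type `"condensed_lrf"`.
#' @param wfn,dm,pairs,weights optional: when supplied, the pointwise
#'   identity (b) is also measured at `npts` random points.
#' @param npts number of sample points for (b).
#' @param tol row-sum residual flag threshold.
#' @param seed RNG seed for the sample points.
#' @return list with `row_residuals` (per bond), `max_row_residual`,
#'   `pointwise_residual` (or NA), `flagged`.
#' @export
sum_rule_report <- function(tbl, wfn = NULL, dm = NULL, pairs = NULL,
                            weights = NULL, npts = 20L, tol = 2e-2,
                            seed = 1L) {
  stopifnot(inherits(tbl, "condensed_lrf"), tbl$type == "bond")
  rowres <- apply(tbl$values, c(1, 2), sum)
  maxrow <- max(abs(rowres))
  pw <- NA_real_
  if (!is.null(wfn)) {
    if (is.null(dm)) dm <- density_matrix(wfn)
    if (is.null(pairs)) pairs <- build_pair_basis(wfn)
    if (is.null(weights)) weights <- pair_bond_weights(wfn, dm, pairs)
    set.seed(seed)
    pts <- matrix(stats::runif(3 * npts, -3, 3), npts, 3)
    nat <- weights$natoms
    ap <- as.matrix(expand.grid(seq_len(nat), seq_len(nat)))
    v <- lrf_bo_pointwise(wfn, dm, pairs, weights, pts, ap)
    pw <- max(abs(rowSums(v)))
  }
  list(row_residuals = rowres, max_row_residual = maxrow,
       pointwise_residual = pw, flagged = maxrow > tol)
}
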