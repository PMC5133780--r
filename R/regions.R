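# Per-atom MO-pair region overlaps G^L_ij = int_L psi_i psi_j dr,
# approximated on the Wigner-Seitz-partitioned grid.  These are the
# reusable building block of every condensed response table.

#' Region overlaps of MO products
#'
#' For each atom L, `G[L, i, j] = sum_g w_g psi_i(g) psi_j(g)` over grid
#' points inside L's Wigner-Seitz cell.  In `"own"` mode (production,
#' matching the per-centre reading of the quadrature) only atom L's own
#' single-centre grid contributes, with points outside L's cell
#' zero-weighted.  In `"union"` mode (cross-check) the points of *all*
#' centres are combined with Becke partition-of-unity factors so that
#' space is covered exactly once, then binned by Wigner-Seitz owner; the
#' two estimates must agree to within a few times the orthonormality
#' residual.
#'
#' @param wfn a [wavefunction_data()] object.
#' @param grid a [build_partitioned_grid()] for the same molecule.
#' @param mos optional MO index subset (default: all MOs).
#' @param mode `"own"` or `"union"`.
#' @param block points per evaluation block.
#' @return object of class `"region_overlaps"`: array `G` of dimension
#'   (natoms, nmo, nmo) (subset MOs leave zero rows), labels and grid
#'   metadata.
#' @export
region_overlaps <- function(wfn, grid, mos = NULL,
                            mode = c("own", "union"), block = 50000L) {
  mode <- match.arg(mode)
  stopifnot(inherits(wfn, "wavefunction"),
            inherits(grid, "partitioned_grid"))
  if (grid$natoms != length(wfn$mol$z))
    stop("grid was built for a different molecule")
  if (is.null(mos)) mos <- seq_len(wfn$nmo)
  nat <- grid$natoms
  G <- array(0, dim = c(nat, wfn$nmo, wfn$nmo))
  if (mode == "own") {
    sel_all <- grid$w_eff > 0
    wsel <- grid$w_eff
  } else {
    bw <- becke_weights(wfn$mol, grid$points, grid$center)
    wsel <- grid$w_base * bw
    sel_all <- wsel > 1e-16
  }
  for (L in seq_len(nat)) {
    sel <- sel_all & (if (mode == "own") grid$center == L else
                        grid$owner == L)
    if (!any(sel)) next
    idx <- which(sel)
    acc <- matrix(0, length(mos), length(mos))
    for (s in split(idx, ceiling(seq_along(idx) / block))) {
      psi <- eval_mos(wfn, grid$points[s, , drop = FALSE], mos = mos)
      acc <- acc + crossprod(psi, wsel[s] * psi)
    }
    G[L, mos, mos] <- (acc + t(acc)) / 2
  }
  structure(list(G = G, labels = .atom_labels(wfn$mol), mos = mos,
                 mode = mode,
                 grid_spec = list(n_radial = grid$n_radial,
                                  lebedev_order = grid$lebedev_order,
                                  mode = mode)),
            class = "region_overlaps")
}

#' Orthonormality residual of a region-overlap tensor
#'
#' `max_ij |sum_L G[L,i,j] - delta_ij|` over the computed MO set; an
#' empirical measure of the hard-boundary quadrature error.
#'
#' @param overlaps a [region_overlaps()] result.
#' @return the maximum absolute residual.
#' @export
overlap_residual <- function(overlaps) {
  tot <- apply(overlaps$G, c(2, 3), sum)
  mos <- overlaps$mos
  max(abs(tot[mos, mos] - diag(length(mos))[seq_along(mos),
                                            seq_along(mos)]))
}
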