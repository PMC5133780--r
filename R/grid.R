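# Atom-centred molecular quadrature.
#
# Radial: Euler-Maclaurin map of [0, Inf) in the Murray-Handy-Laming (m = 2)
# form, r_i = R * i^2/(n+1-i)^2, with the element's Bragg-Slater radius as
# the scale R.  Angular: Lebedev point sets (embedded tables).  Ownership of
# each point is assigned to the nearest atom (the molecular Wigner-Seitz /
# Voronoi cell, hard boundary, no fuzzy switching); ties go to the lowest
# atom index.

#' Lebedev angular quadrature points
#'
#' @param order number of angular points; supported values are listed in the
#'   error message of an unsupported request.
#' @return matrix with columns x, y, z, w; weights sum to `4*pi`.
#' @export
lebedev_points <- function(order) {
  key <- as.character(as.integer(order))
  tab <- .lebedev_tables[[key]]
  if (is.null(tab))
    stop("unsupported Lebedev order ", order, "; supported orders: ",
         paste(.lebedev_orders, collapse = ", "))
  tab
}

# radial points/weights for integrals of f(r) r^2 dr on [0, Inf)
.radial_em <- function(n, R) {
  i <- seq_len(n)
  den <- n + 1 - i
  r <- R * i^2 / den^2
  w <- 2 * R^3 * (n + 1) * i^5 / den^7
  list(r = r, w = w)
}

#' Build a Wigner-Seitz-partitioned molecular grid
#'
#' Each atom carries a full single-centre Euler-Maclaurin x Lebedev grid.
#' The effective weight of a point equals its base quadrature weight if the
#' point lies inside the generating atom's Wigner-Seitz cell (nearest-atom
#' rule, ties to the lowest atom index) and zero otherwise.
#'
#' @param mol a [molecule()].
#' @param n_radial radial points per atom (>= 10).
#' @param lebedev_order angular points per radial shell (see
#'   [lebedev_points()]).
#' @return object of class `"partitioned_grid"`: `points` (N x 3, Bohr),
#'   `w_base`, `center` (generating atom, 1-based), `owner` (Wigner-Seitz
#'   owner), `w_eff`.
#' @export
build_partitioned_grid <- function(mol, n_radial = 75L,
                                   lebedev_order = 302L) {
  stopifnot(inherits(mol, "molecule"))
  if (n_radial < 10L) stop("n_radial must be >= 10")
  ang <- lebedev_points(lebedev_order)
  nat <- nrow(mol$coords)
  pts <- vector("list", nat)
  wts <- vector("list", nat)
  cen <- vector("list", nat)
  for (a in seq_len(nat)) {
    rad <- .radial_em(n_radial, bragg_slater_radius(mol$z[a]))
    # outer product of radial shells and angular points
    p <- kronecker(rad$r, ang[, 1:3])
    p <- sweep(p, 2L, mol$coords[a, ], "+")
    # kronecker stacks one angular block per radial point
    w <- as.vector(vapply(seq_len(n_radial),
                          function(i) rad$w[i] * ang[, 4L],
                          numeric(nrow(ang))))
    pts[[a]] <- p
    wts[[a]] <- w
    cen[[a]] <- rep.int(a, length(w))
  }
  points <- do.call(rbind, pts)
  w_base <- unlist(wts, use.names = FALSE)
  center <- unlist(cen, use.names = FALSE)
  owner <- nearest_atom(points, mol$coords)
  w_eff <- ifelse(owner == center, w_base, 0)
  if (any(tabulate(owner[w_eff > 0], nbins = nat) == 0L))
    stop("an atom owns no grid points; grid too coarse")
  structure(list(points = points, w_base = w_base, center = center,
                 owner = owner, w_eff = w_eff,
                 n_radial = as.integer(n_radial),
                 lebedev_order = as.integer(lebedev_order),
                 natoms = nat),
            class = "partitioned_grid")
}

# nearest atom index per point; ties resolved to the lowest atom index
nearest_atom <- function(points, coords) {
  n <- nrow(points)
  d2 <- matrix(0, n, nrow(coords))
  for (a in seq_len(nrow(coords))) {
    d2[, a] <- (points[, 1] - coords[a, 1])^2 +
               (points[, 2] - coords[a, 2])^2 +
               (points[, 3] - coords[a, 3])^2
  }
  max.col(-d2, ties.method = "first")
}

#' @export
print.partitioned_grid <- function(x, ...) {
  cat(sprintf(
    "<partitioned_grid> %d atoms x (%d radial x %d angular) = %d points; %d inside own cell\n",
    x$natoms, x$n_radial, x$lebedev_order, length(x$w_base),
    sum(x$w_eff > 0)))
  invisible(x)
}

# Becke fuzzy-cell relative weights (used only for SCF exchange-correlation
# quadrature, never for the response condensation): standard three-fold
# iterated switching polynomial with Bragg-Slater size adjustment.
becke_weights <- function(mol, points, center) {
  nat <- nrow(mol$coords)
  npt <- nrow(points)
  if (nat == 1L) return(rep(1, npt))
  d <- matrix(0, npt, nat)
  for (a in seq_len(nat))
    d[, a] <- sqrt((points[, 1] - mol$coords[a, 1])^2 +
                   (points[, 2] - mol$coords[a, 2])^2 +
                   (points[, 3] - mol$coords[a, 3])^2)
  R <- bragg_slater_radius(mol$z)
  P <- matrix(1, npt, nat)
  fcut <- function(mu) {
    for (k in 1:3) mu <- 0.5 * mu * (3 - mu^2)
    mu
  }
  for (i in seq_len(nat)) for (j in seq_len(nat)) {
    if (i == j) next
    Rij <- sqrt(sum((mol$coords[i, ] - mol$coords[j, ])^2))
    mu <- (d[, i] - d[, j]) / Rij
    chi <- R[i] / R[j]
    u <- (chi - 1) / (chi + 1)
    aij <- u / (u^2 - 1)
    aij <- max(min(aij, 0.5), -0.5)
    nu <- mu + aij * (1 - mu^2)
    P[, i] <- P[, i] * 0.5 * (1 - fcut(nu))
  }
  tot <- rowSums(P)
  P[cbind(seq_len(npt), center)] / pmax(tot, 1e-300)
}
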