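# Sigma/pi classification of MOs of (near-)planar molecules and channel
# decomposition of condensed response tables.
#
# The classifier computes the exact reflection-parity score
#   score_k = <psi_k | sigma_h psi_k>  in [-1, 1]
# through the plane: +1 for sigma (symmetric), -1 for pi (antisymmetric).
# The reflected MO is expanded analytically: reflecting a Cartesian
# Gaussian through a plane gives a Gaussian at the mirrored centre whose
# polynomial part transforms by the Householder matrix H = I - 2 n n';
# the score is then an exact AO overlap contraction, no numerical grid.

#' Detect the molecular plane
#'
#' Least-squares plane through the heavy atoms (all atoms when fewer than
#' three heavy atoms exist).  Returns `NULL` when the structure is not
#' planar within `tol`; collinear molecules return the axis with a
#' `degenerate` flag (sigma/pi remain well defined for linear systems).
#'
#' @param mol a [molecule()].
#' @param tol maximum RMS out-of-plane deviation (Angstrom).
#' @return `NULL` or list(point, normal, rms, degenerate).
#' @export
detect_molecular_plane <- function(mol, tol = 1e-3) {
  X <- mol$coords
  heavy <- mol$z > 1L
  # fit on heavy atoms (all atoms when fewer than three are heavy), but a
  # molecule only counts as planar when EVERY atom sits in the plane:
  # sigma/pi parity needs the full nuclear frame to be mirror-symmetric
  fitX <- if (sum(heavy) >= 3L) X[heavy, , drop = FALSE] else X
  ctr <- colMeans(fitX)
  Xc <- sweep(fitX, 2L, ctr)
  sv <- svd(Xc)
  d <- sv$d
  tol_b <- tol * .ang2bohr
  if (nrow(fitX) < 3L || d[2] < 1e-8) {
    # collinear (or a diatomic): return the axis direction
    axis <- sv$v[, 1L]
    return(list(point = ctr, normal = NULL, axis = axis, rms = 0,
                degenerate = TRUE))
  }
  normal <- sv$v[, 3L]
  rms <- sqrt(mean((sweep(X, 2L, ctr) %*% normal)^2))
  if (rms > tol_b) return(NULL)
  list(point = ctr, normal = normal, rms = rms, degenerate = FALSE)
}

# reflected-basis AO overlap: S_refl[mu, nu] = int phi_mu(sigma r) phi_nu(r)
.reflection_overlap <- function(bas, point, normal) {
  n <- normal / sqrt(sum(normal^2))
  H <- diag(3) - 2 * tcrossprod(n)
  refl_center <- function(cc) as.numeric(cc - 2 * sum((cc - point) * n) * n)
  # combined basis: original shells followed by mirrored shells
  nsh <- length(bas$shell_l)
  centers2 <- t(apply(bas$shell_center, 1L, refl_center))
  comb <- list(shell_l = c(bas$shell_l, bas$shell_l),
               shell_atom = c(bas$shell_atom, bas$shell_atom),
               shell_center = rbind(bas$shell_center, centers2),
               shell_ptr = c(bas$shell_ptr, bas$shell_ptr),
               shell_nprim = c(bas$shell_nprim, bas$shell_nprim),
               prim_exp = bas$prim_exp, prim_coef = bas$prim_coef)
  Sfull <- .cxx_overlap(as.integer(comb$shell_l),
                        as.integer(comb$shell_atom - 1L),
                        comb$shell_center, as.integer(comb$shell_ptr),
                        as.integer(comb$shell_nprim), comb$prim_exp,
                        comb$prim_coef)
  ncart <- bas$ncart
  Scross <- Sfull[ncart + seq_len(ncart), seq_len(ncart)]
  # polynomial transform of the mirrored components, blockwise per shell
  d6pairs <- rbind(c(1, 1), c(2, 2), c(3, 3), c(1, 2), c(1, 3), c(2, 3))
  d6fac <- c(1, 1, 1, sqrt(3), sqrt(3), sqrt(3)) # normalised cartesians
  U <- matrix(0, ncart, ncart)
  o <- 0L
  for (s in seq_len(nsh)) {
    l <- bas$shell_l[s]
    if (l == 0L) {
      U[o + 1L, o + 1L] <- 1
      o <- o + 1L
    } else if (l == 1L) {
      U[o + 1:3, o + 1:3] <- H
      o <- o + 3L
    } else if (l == 2L) {
      # x_a x_b -> sum_cd H_ac H_bd x_c x_d, in the normalised 6-component
      # cartesian basis (cross terms carry sqrt(3))
      B <- matrix(0, 6, 6)
      for (r in 1:6) for (cidx in 1:6) {
        a <- d6pairs[r, 1]; b <- d6pairs[r, 2]
        cc <- d6pairs[cidx, 1]; dd <- d6pairs[cidx, 2]
        v <- H[a, cc] * H[b, dd] + (if (cc != dd) H[a, dd] * H[b, cc]
                                    else 0)
        B[r, cidx] <- v * d6fac[r] / d6fac[cidx]
      }
      # rows: target component expressed in source components.  The
      # mirrored AO with component (a,b) equals sum over (c<=d) of B.
      U[o + 1:6, o + 1:6] <- B
      o <- o + 6L
    } else stop("sigma/pi reflection supports shells up to l = 2")
  }
  # mirrored AO mu = sum_k U[mu, k] * (standard AO k at mirrored centre),
  # so S_refl[mu, nu] = int phi_mu(sigma r) phi_nu(r) = (U Scross)_{mu,nu}
  U %*% Scross
}

#' Classify MOs as sigma or pi by reflection parity
#'
#' @param wfn a [wavefunction_data()] object.
#' @param plane a [detect_molecular_plane()] result (non-degenerate), or a
#'   list with `point` and `normal`; for linear molecules pass the axis
#'   plane of choice.
#' @param purity parity-score magnitude required for a sigma/pi label;
#'   orbitals below it are `"mixed"` (flagged with a warning).
#' @return object of class `"orbital_symmetry"`: `label` (factor
#'   sigma/pi/mixed per MO), `score` in [-1, 1], the plane.
#' @export
classify_orbitals <- function(wfn, plane, purity = 0.95) {
  if (is.null(plane) || is.null(plane$normal))
    stop("no molecular plane: sigma/pi classification needs a planar ",
         "molecule (or an explicit plane)")
  if (wfn$basis$harmonic != "cartesian")
    stop("sigma/pi classification requires the cartesian AO representation")
  Sr <- .reflection_overlap(wfn$basis, plane$point, plane$normal)
  score <- colSums(wfn$C * (Sr %*% wfn$C))
  label <- ifelse(score > purity, "sigma",
                  ifelse(score < -purity, "pi", "mixed"))
  if (any(label == "mixed"))
    warning("mixed-parity orbitals (|score| < ", purity, "): MOs ",
            paste(which(label == "mixed"), collapse = ", "))
  structure(list(label = label, score = score, plane = plane,
                 purity = purity), class = "orbital_symmetry")
}

#' Decompose a condensed response table into sigma/pi/cross channels
#'
#' Pair-level assignment: a pair (i occupied, j virtual) belongs to the
#' pi channel when both orbitals are pi, to the sigma channel when both
#' are sigma, and to the cross channel otherwise (pairs involving mixed
#' orbitals are counted as cross and reported as contamination).  The
#' three channels sum to the total exactly.
#'
#' @param labels [classify_orbitals()] result.
#' @param pairs [build_pair_basis()] result.
#' @param overlaps [region_overlaps()] result.
#' @param weights [pair_bond_weights()] result (bond tables only).
#' @param type `"bond"` or `"density"`.
#' @return named list of `"condensed_lrf"` tables: `total`, `sigma`,
#'   `pi`, `cross`, plus `contamination` (fraction of pairs involving
#'   mixed orbitals).
#' @export
decompose_response <- function(labels, pairs, overlaps, weights = NULL,
                               type = c("bond", "density")) {
  type <- match.arg(type)
  li <- labels$label[pairs$i]; lj <- labels$label[pairs$j]
  chan <- ifelse(li == "pi" & lj == "pi", "pi",
                 ifelse(li == "sigma" & lj == "sigma", "sigma", "cross"))
  mixed_frac <- mean(li == "mixed" | lj == "mixed")
  build <- function(sel, name) {
    psub <- pairs[sel, , drop = FALSE]
    class(psub) <- class(pairs)
    if (type == "bond") {
      wsub <- weights
      wsub$w <- weights$w[sel, , , drop = FALSE]
      lrf_bo_condensed(wsub, psub, overlaps, channel = name)
    } else {
      lrf_density_condensed(psub, overlaps, channel = name)
    }
  }
  if (type == "bond" && is.null(weights))
    stop("bond-channel decomposition needs pair weights")
  out <- list(
    total = build(rep(TRUE, nrow(pairs)), "total"),
    sigma = build(chan == "sigma", "sigma"),
    pi = build(chan == "pi", "pi"),
    cross = build(chan == "cross", "cross"))
  out$contamination <- mixed_frac
  out
}
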