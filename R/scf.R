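# Restricted SCF (RHF / hybrid GGA Kohn-Sham) over the package's own
# integral engine.  Convergence by DIIS on the orthonormalised
# FPS - SPF commutator with early damping; initial guess is the
# generalised Wolfsberg-Helmholz (GWH) one-electron Hamiltonian.

#' SCF method specification
#'
#' @param functional `"b3lyp"` (default), `"hf"`, `"blyp"` or `"svwn"`.
#' @param basis bundled basis name or basis file path (default
#'   `"6-311gss"`).
#' @param b3lyp_flavor `"vwn5"` (default, GAMESS-like) or `"vwn3"`
#'   (Gaussian-like) correlation mixing inside B3LYP.
#' @param harmonic `"cartesian"` (6d, default) or `"spherical"` (5d).
#' @param grid `c(n_radial, lebedev_order)` for the exchange-correlation
#'   quadrature.
#' @param conv convergence threshold on the maximum DIIS error element.
#' @param maxit maximum SCF iterations.
#' @return a `"scf_method"` list used by [run_scf()].
#' @export
scf_method <- function(functional = "b3lyp", basis = "6-311gss",
                       b3lyp_flavor = "vwn5", harmonic = "cartesian",
                       grid = c(50L, 194L), conv = 1e-6, maxit = 150L) {
  structure(list(functional = functional, basis = basis,
                 b3lyp_flavor = b3lyp_flavor, harmonic = harmonic,
                 grid = as.integer(grid), conv = conv,
                 maxit = as.integer(maxit), backend = "native"),
            class = "scf_method")
}

# Fock exchange-correlation contribution and energy on a Becke-weighted grid
.xc_fock <- function(P, grid_ao, w, spec) {
  phi <- grid_ao$v; gx <- grid_ao$gx; gy <- grid_ao$gy; gz <- grid_ao$gz
  PP <- phi %*% P
  rho <- rowSums(PP * phi)
  drx <- 2 * rowSums(PP * gx)
  dry <- 2 * rowSums(PP * gy)
  drz <- 2 * rowSums(PP * gz)
  gam <- drx^2 + dry^2 + drz^2
  xc <- xc_eval(rho, gam, spec)
  exc <- sum(w * xc$e)
  wv <- w * xc$vrho
  A <- crossprod(phi, wv * phi)
  wg <- 2 * w * xc$vgamma
  B <- crossprod(phi, wg * (drx * gx + dry * gy + drz * gz))
  list(V = A + B + t(B), exc = exc, nelec = sum(w * rho))
}

# core SCF loop; returns orbitals for a fixed geometry
scf_solve <- function(mol, bas, spec, grid_spec, conv = 1e-6,
                      maxit = 150L, verbose = FALSE) {
  S <- overlap_matrix(bas)
  Tm <- kinetic_matrix(bas)
  V <- nuclear_matrix(bas, mol)
  H <- Tm + V
  n <- nrow(S)
  nocc <- mol$nelec / 2
  if (nocc < 1 || nocc > n) stop("electron count incompatible with basis")
  es <- eigen(S, symmetric = TRUE)
  if (min(es$values) < 1e-8)
    stop("AO overlap matrix is numerically singular")
  X <- es$vectors %*% (diag(1 / sqrt(es$values), n)) %*% t(es$vectors)
  G <- eri_tensor(bas)
  dim(G) <- c(n * n, n * n)
  Gk <- G
  dim(Gk) <- c(n, n, n, n)
  Gk <- aperm(Gk, c(1, 3, 2, 4))
  dim(Gk) <- c(n * n, n * n)

  needs_xc <- any(spec[c("slater", "b88", "vwn", "lyp")] != 0)
  grid_ao <- NULL; w <- NULL
  if (needs_xc) {
    g <- build_partitioned_grid(mol, grid_spec[1L], grid_spec[2L])
    bw <- becke_weights(mol, g$points, g$center)
    w <- g$w_base * bw
    keep <- w > 1e-14
    w <- w[keep]
    grid_ao <- eval_ao(bas, g$points[keep, , drop = FALSE], deriv = TRUE)
  }

  # GWH guess
  F0 <- 0.875 * S * (matrix(diag(H), n, n) + matrix(diag(H), n, n,
                                                    byrow = TRUE))
  diag(F0) <- diag(H)
  solve_fock <- function(F) {
    Fp <- t(X) %*% F %*% X
    e <- eigen(Fp, symmetric = TRUE)
    ord <- order(e$values)          # ascending orbital energies
    C <- X %*% e$vectors[, ord, drop = FALSE]
    list(C = C, eps = e$values[ord])
  }
  o <- solve_fock(F0)
  Cocc <- o$C[, seq_len(nocc), drop = FALSE]
  P <- 2 * tcrossprod(Cocc)

  diis_F <- list(); diis_e <- list()
  E_old <- Inf; a_hfx <- unname(spec["hfx"])
  for (it in seq_len(maxit)) {
    J <- matrix(G %*% as.vector(P), n, n)
    F <- H + J
    EK <- 0
    if (a_hfx != 0) {
      K <- matrix(Gk %*% as.vector(P), n, n)
      F <- F - 0.5 * a_hfx * K
      EK <- -0.25 * a_hfx * sum(P * K)
    }
    exc <- 0
    if (needs_xc) {
      xcr <- .xc_fock(P, grid_ao, w, spec)
      F <- F + xcr$V
      exc <- xcr$exc
    }
    E <- sum(P * H) + 0.5 * sum(P * J) + EK + exc + nuclear_repulsion(mol)
    err <- F %*% P %*% S - S %*% P %*% F
    err <- t(X) %*% err %*% X
    emax <- max(abs(err))
    if (verbose)
      message(sprintf("  iter %3d  E = %.10f  dE = %+.3e  |err| = %.3e",
                      it, E, E - E_old, emax))
    if (emax < conv && abs(E - E_old) < 1e-8 && it > 1) {
      o <- solve_fock(F)
      return(list(C = o$C, eps = o$eps, nocc = nocc, S = S, H = H,
                  energy = E, niter = it, converged = TRUE))
    }
    E_old <- E
    # DIIS
    diis_F[[length(diis_F) + 1L]] <- F
    diis_e[[length(diis_e) + 1L]] <- err
    if (length(diis_F) > 8L) { diis_F <- diis_F[-1L]; diis_e <- diis_e[-1L] }
    m <- length(diis_F)
    if (m >= 2L) {
      B <- matrix(0, m + 1L, m + 1L)
      for (i in seq_len(m)) for (j in seq_len(m))
        B[i, j] <- sum(diis_e[[i]] * diis_e[[j]])
      B[m + 1L, seq_len(m)] <- -1; B[seq_len(m), m + 1L] <- -1
      rhs <- c(rep(0, m), -1)
      cf <- tryCatch(solve(B, rhs)[seq_len(m)], error = function(e) NULL)
      if (!is.null(cf) && all(is.finite(cf))) {
        F <- Reduce("+", Map("*", diis_F, cf))
      }
    }
    o <- solve_fock(F)
    Cocc <- o$C[, seq_len(nocc), drop = FALSE]
    Pn <- 2 * tcrossprod(Cocc)
    P <- if (m < 2L) 0.7 * Pn + 0.3 * P else Pn
  }
  stop("SCF failed to converge in ", maxit, " iterations ",
       sprintf("(last max DIIS error %.2e)", emax))
}

#' Run a restricted SCF calculation
#'
#' Computes a converged closed-shell RHF or Kohn-Sham wavefunction with the
#' package's native engine.  Geometry optimization (`optimize = TRUE`) is
#' available for diatomics (bond-length scan) and C2v AB2 triatomics
#' (bond length + angle); other systems must be supplied pre-optimized.
#'
#' @param mol a [molecule()] (multiplicity 1).
#' @param method an [scf_method()].
#' @param optimize logical; optimize the geometry first.
#' @param verbose print iteration diagnostics.
#' @return a [wavefunction_data()] object.
#' @export
run_scf <- function(mol, method = scf_method(), optimize = FALSE,
                    verbose = FALSE) {
  stopifnot(inherits(mol, "molecule"))
  if (mol$multiplicity != 1L)
    stop("unsupported system: only closed-shell (multiplicity 1) supported")
  if (optimize) mol <- optimize_geometry(mol, method, verbose = verbose)
  spec <- xc_spec(method$functional, method$b3lyp_flavor)
  bas <- build_basis(mol, method$basis, method$harmonic)
  r <- scf_solve(mol, bas, spec, method$grid, conv = method$conv,
                 maxit = method$maxit, verbose = verbose)
  occ <- c(rep(2, r$nocc), rep(0, ncol(r$C) - r$nocc))
  wavefunction_data(
    C = r$C, eps = r$eps, occ = occ, S = r$S, basis = bas, mol = mol,
    method = list(functional = method$functional, basis = method$basis,
                  b3lyp_flavor = method$b3lyp_flavor,
                  harmonic = method$harmonic, backend = "native",
                  grid = method$grid, energy = r$energy,
                  niter = r$niter))
}

# total energy at a geometry (helper for the optimizer)
.energy_at <- function(mol, method) {
  spec <- xc_spec(method$functional, method$b3lyp_flavor)
  bas <- build_basis(mol, method$basis, method$harmonic)
  scf_solve(mol, bas, spec, method$grid, conv = method$conv,
            maxit = method$maxit)$energy
}

#' Optimize a geometry (diatomics and C2v AB2 triatomics)
#'
#' Gradient-free minimisation over the symmetry-unique internal
#' coordinates: Brent line search for diatomics, Nelder-Mead over
#' (bond length, bond angle) for symmetric AB2 systems.
#'
#' @param mol a [molecule()].
#' @param method an [scf_method()].
#' @param verbose print progress.
#' @return the optimized [molecule()].
#' @export
optimize_geometry <- function(mol, method = scf_method(), verbose = FALSE) {
  nat <- nrow(mol$coords)
  if (nat == 2L) {
    r0 <- sqrt(sum((mol$coords[1, ] - mol$coords[2, ])^2))
    f <- function(r) {
      m <- molecule(mol$symbols,
                    rbind(c(0, 0, 0), c(0, 0, r)),
                    charge = mol$charge, unit = "bohr")
      e <- .energy_at(m, method)
      if (verbose) message(sprintf("  r = %.6f bohr  E = %.10f", r, e))
      e
    }
    op <- stats::optimize(f, interval = c(0.7 * r0, 1.4 * r0),
                          tol = 1e-4)
    return(molecule(mol$symbols, rbind(c(0, 0, 0), c(0, 0, op$minimum)),
                    charge = mol$charge, unit = "bohr"))
  }
  if (nat == 3L && mol$symbols[2] == mol$symbols[3]) {
    # A-B2: place A at origin, B atoms symmetric about z in the xz plane
    r0 <- mean(c(sqrt(sum((mol$coords[1, ] - mol$coords[2, ])^2)),
                 sqrt(sum((mol$coords[1, ] - mol$coords[3, ])^2))))
    v1 <- mol$coords[2, ] - mol$coords[1, ]
    v2 <- mol$coords[3, ] - mol$coords[1, ]
    a0 <- acos(sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2)))
    geom <- function(p) {
      r <- p[1]; a <- p[2]
      rbind(c(0, 0, 0),
            c(r * sin(a / 2), 0, r * cos(a / 2)),
            c(-r * sin(a / 2), 0, r * cos(a / 2)))
    }
    f <- function(p) {
      m <- molecule(mol$symbols, geom(p), charge = mol$charge,
                    unit = "bohr")
      e <- .energy_at(m, method)
      if (verbose)
        message(sprintf("  r = %.5f bohr  angle = %.3f deg  E = %.10f",
                        p[1], p[2] * 180 / pi, e))
      e
    }
    op <- stats::optim(c(r0, a0), f, method = "Nelder-Mead",
                       control = list(reltol = 1e-9, maxit = 60))
    return(molecule(mol$symbols, geom(op$par), charge = mol$charge,
                    unit = "bohr"))
  }
  stop("native geometry optimization supports diatomics and C2v AB2 ",
       "triatomics only; supply a pre-optimized geometry")
}
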