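# Contracted Gaussian basis handling.
#
# A "basis" object holds flattened shell data ready for the C++ integral
# kernels plus the AO -> atom map.  Cartesian components follow the
# Molden/GAMESS ordering; d shells may be used either as 6 Cartesian
# components (default, GAMESS-like for Pople sets) or transformed to the
# 5 real spherical harmonics.

.basis_cache <- new.env(parent = emptyenv())

.ao_labels_l <- list(
  "0" = "s",
  "1" = c("px", "py", "pz"),
  "2" = c("dxx", "dyy", "dzz", "dxy", "dxz", "dyz"),
  "2s" = c("d0", "d+1", "d-1", "d+2", "d-2"))

#' Read a basis-set definition file
#'
#' The plain-text format is one `ELEMENT <symbol>` block per element, each
#' shell given as `<S|P|D> <nprim>` followed by `exponent coefficient`
#' lines, terminated by `END`.  Two sets ship with the package:
#' `"6-311gss"` (H, C, N, O, F, Cl) and `"sto-3g"`.
#'
#' @param name bundled set name or a path to a basis file.
#' @return named list: per element, a list of shells `list(l, exp, coef)`.
#' @export
read_basis_library <- function(name) {
  path <- if (file.exists(name)) name else
    system.file("extdata", "basis", paste0(tolower(name), ".bas"),
                package = "lrfbo")
  if (!nzchar(path) || !file.exists(path))
    stop("basis set '", name, "' not found (bundled sets: 6-311gss, sto-3g)")
  key <- normalizePath(path)
  if (!is.null(.basis_cache[[key]])) return(.basis_cache[[key]])
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "!")]
  lib <- list()
  i <- 1L
  lmap <- c(S = 0L, P = 1L, D = 2L, F = 3L)
  while (i <= length(lines)) {
    tok <- strsplit(lines[i], "[[:space:]]+")[[1L]]
    if (toupper(tok[1L]) != "ELEMENT")
      stop("basis file parse error at line: ", lines[i])
    el <- tok[2L]
    i <- i + 1L
    shells <- list()
    while (toupper(lines[i]) != "END") {
      tok <- strsplit(lines[i], "[[:space:]]+")[[1L]]
      l <- lmap[[toupper(tok[1L])]]
      np <- as.integer(tok[2L])
      prim <- matrix(NA_real_, np, 2L)
      for (k in seq_len(np)) {
        v <- as.numeric(strsplit(lines[i + k], "[[:space:]]+")[[1L]])
        prim[k, ] <- v[1:2]
      }
      shells[[length(shells) + 1L]] <-
        list(l = l, exp = prim[, 1L], coef = prim[, 2L])
      i <- i + np + 1L
    }
    lib[[el]] <- shells
    i <- i + 1L
  }
  .basis_cache[[key]] <- lib
  lib
}

# normalisation: primitive norms for the (l,0,0) component, then scale the
# contraction so the contracted (l,0,0) AO has unit self-overlap.
.normalize_shell <- function(l, exps, coefs) {
  dfact <- function(n) if (n <= 1) 1 else prod(seq(2 * n - 1, 1, by = -2))
  nprim <- (2 * exps / pi)^0.75 * (4 * exps)^(l / 2) / sqrt(dfact(l))
  c1 <- coefs * nprim
  p <- outer(exps, exps, "+")
  sprim <- (pi / p)^1.5 * dfact(l) / (2 * p)^l
  self <- as.numeric(t(c1) %*% sprim %*% c1)
  c1 / sqrt(self)
}

#' Build the AO basis for a molecule
#'
#' @param mol a [molecule()].
#' @param basis bundled basis-set name or path (see
#'   [read_basis_library()]), or an already-read library list.
#' @param harmonic `"cartesian"` (6d) or `"spherical"` (5d).
#' @return an object of class `"aobasis"`: flattened shell arrays, the
#'   AO -> atom map (`ao_atom`, 1-based), AO angular labels and, for
#'   spherical harmonics, the Cartesian-to-spherical transform `Tsph`.
#' @export
build_basis <- function(mol, basis = "6-311gss",
                        harmonic = c("cartesian", "spherical")) {
  harmonic <- match.arg(harmonic)
  lib <- if (is.list(basis)) basis else read_basis_library(basis)
  bname <- if (is.list(basis)) "custom" else basis
  if (grepl("\\+", bname))
    warning("basis name contains diffuse-function markers; Mulliken-type ",
            "population analyses are unreliable with diffuse functions")
  shells <- list()
  for (a in seq_along(mol$symbols)) {
    el <- mol$symbols[a]
    if (is.null(lib[[el]]))
      stop("no basis functions for element ", el, " in basis '", bname, "'")
    for (sh in lib[[el]])
      shells[[length(shells) + 1L]] <-
        list(l = sh$l, atom = a, exp = sh$exp, coef = sh$coef)
  }
  .make_aobasis(mol, shells, harmonic, bname)
}

# assemble an aobasis object from a list of shells
# (each: list(l, atom, exp, coef) with raw contraction coefficients)
.make_aobasis <- function(mol, shells, harmonic, name) {
  shell_l <- vapply(shells, function(s) as.integer(s$l), 0L)
  if (any(shell_l > 3L)) stop("shells with l > 3 are not supported")
  shell_atom <- vapply(shells, function(s) as.integer(s$atom), 0L)
  shell_np <- vapply(shells, function(s) length(s$exp), 0L)
  shell_ptr <- cumsum(c(0L, shell_np))[seq_along(shells)]
  pexp <- unlist(lapply(shells, `[[`, "exp"))
  praw <- unlist(lapply(shells, `[[`, "coef"))
  pcoef <- unlist(lapply(shells, function(s)
    .normalize_shell(s$l, s$exp, s$coef)))
  centers <- t(vapply(shells, function(s) mol$coords[s$atom, ],
                      numeric(3)))
  ncart_l <- c(1L, 3L, 6L, 10L)
  nsph_l <- c(1L, 3L, 5L, 7L)
  ao_atom <- integer(0); ao_l <- integer(0); ao_shell <- integer(0)
  ao_lab <- character(0)
  ncart <- sum(ncart_l[shell_l + 1L])
  for (s in seq_along(shell_l)) {
    k <- if (harmonic == "spherical" && shell_l[s] >= 2L)
      nsph_l[shell_l[s] + 1L] else ncart_l[shell_l[s] + 1L]
    ao_atom <- c(ao_atom, rep(shell_atom[s], k))
    ao_l <- c(ao_l, rep(shell_l[s], k))
    ao_shell <- c(ao_shell, rep(s, k))
    lab <- if (shell_l[s] == 2L && harmonic == "spherical")
      .ao_labels_l[["2s"]] else .ao_labels_l[[as.character(shell_l[s])]]
    ao_lab <- c(ao_lab, lab)
  }
  obj <- structure(list(
    name = name, harmonic = harmonic,
    shell_l = shell_l, shell_atom = shell_atom,
    shell_center = unname(as.matrix(centers)),
    shell_ptr = shell_ptr, shell_nprim = shell_np,
    prim_exp = pexp, prim_coef = pcoef, prim_coef_raw = praw,
    ao_atom = ao_atom, ao_l = ao_l, ao_shell = ao_shell,
    ao_label = ao_lab,
    nao = length(ao_atom), ncart = ncart), class = "aobasis")
  obj$Tsph <- if (harmonic == "spherical") .sph_transform(obj) else NULL
  obj
}

# block-diagonal Cartesian -> real-spherical transform (nao_sph x nao_cart).
# d ordering (Molden): cart xx,yy,zz,xy,xz,yz -> sph d0,d+1,d-1,d+2,d-2.
.sph_transform <- function(bas) {
  d5 <- matrix(0, 5, 6)
  # normalised cartesians: xx etc. have <xx|xx>=1; cross terms xy carry
  # the sqrt(3) factor already, so the transform uses:
  d5[1, ] <- c(-0.5, -0.5, 1, 0, 0, 0)            # (2zz-xx-yy)/2
  d5[2, 5] <- 1                                    # xz
  d5[3, 6] <- 1                                    # yz
  d5[4, 1:2] <- c(sqrt(3) / 2, -sqrt(3) / 2)       # (xx-yy)*sqrt(3)/2
  d5[5, 4] <- 1                                    # xy
  rows <- list()
  for (s in seq_along(bas$shell_l)) {
    l <- bas$shell_l[s]
    if (l == 0L) rows[[s]] <- matrix(1, 1, 1)
    else if (l == 1L) rows[[s]] <- diag(3)
    else if (l == 2L) rows[[s]] <- d5
    else stop("spherical transform implemented for l <= 2 only")
  }
  nr <- sum(vapply(rows, nrow, 1L)); ncl <- sum(vapply(rows, ncol, 1L))
  Tm <- matrix(0, nr, ncl)
  i <- 0L; j <- 0L
  for (s in seq_along(rows)) {
    r <- rows[[s]]
    Tm[i + seq_len(nrow(r)), j + seq_len(ncol(r))] <- r
    i <- i + nrow(r); j <- j + ncol(r)
  }
  Tm
}

.shell_args <- function(bas) {
  list(as.integer(bas$shell_l), as.integer(bas$shell_atom - 1L),
       bas$shell_center, as.integer(bas$shell_ptr),
       as.integer(bas$shell_nprim), bas$prim_exp, bas$prim_coef)
}

# transform a cartesian AO matrix M (cart x cart) into the basis convention
.to_basis_rep <- function(bas, M) {
  if (bas$harmonic == "cartesian") return(M)
  Tm <- bas$Tsph
  Mm <- Tm %*% M %*% t(Tm)
  # renormalise spherical components to unit self-overlap is not needed:
  # the d0 and d+2 rows as defined are already normalised for normalised
  # cartesian inputs with the standard sqrt(3) cross-term convention.
  Mm
}

#' AO overlap matrix
#' @param bas an [build_basis()] object.
#' @return nao x nao overlap matrix.
#' @export
overlap_matrix <- function(bas) {
  S <- do.call(.cxx_overlap, .shell_args(bas))
  .to_basis_rep(bas, S)
}

kinetic_matrix <- function(bas) {
  .to_basis_rep(bas, do.call(.cxx_kinetic, .shell_args(bas)))
}

nuclear_matrix <- function(bas, mol, charges = NULL) {
  if (is.null(charges)) charges <- as.numeric(mol$z)
  V <- do.call(.cxx_nuclear,
               c(.shell_args(bas), list(mol$coords, charges)))
  .to_basis_rep(bas, V)
}

eri_tensor <- function(bas) {
  G <- do.call(.cxx_eri, .shell_args(bas))
  if (bas$harmonic == "spherical") {
    Tm <- bas$Tsph
    n <- nrow(Tm); m <- ncol(Tm)
    # transform one index at a time, rotating axes so the ordering is
    # restored after four passes
    dims <- rep(m, 4L)
    for (pass in 1:4) {
      dim(G) <- c(dims[1L], prod(dims[-1L]))
      G <- Tm %*% G
      dims[1L] <- n
      dim(G) <- dims
      G <- aperm(G, c(2, 3, 4, 1))
      dims <- dims[c(2, 3, 4, 1)]
    }
  }
  G
}

#' Evaluate AO amplitudes at points
#' @param bas an [build_basis()] object.
#' @param points npt x 3 matrix (Bohr).
#' @param deriv logical: also return Cartesian gradients.
#' @return list with `v` (npt x nao) and, if `deriv`, `gx`, `gy`, `gz`.
#' @export
eval_ao <- function(bas, points, deriv = FALSE) {
  points <- as.matrix(points)
  if (!all(is.finite(points))) stop("points must be finite")
  r <- do.call(.cxx_eval_ao,
               c(.shell_args(bas), list(points, as.logical(deriv))))
  if (bas$harmonic == "spherical") {
    Tt <- t(bas$Tsph)
    r <- lapply(r, function(m) m %*% Tt)
  }
  r
}
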