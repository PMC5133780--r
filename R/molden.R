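# Molden-format wavefunction exchange.
#
# The writer emits [Molden Format] with [Atoms] in AU, the [GTO] section
# with raw contraction coefficients (the usual normalised-primitive
# convention) and restricted [MO] blocks (Spin= Alpha, Occup= 2/0).
# Cartesian d shells are the default (no [5D] flag); spherical bases are
# flagged [5D].  The reader recomputes the overlap matrix from the parsed
# basis and validates MO orthonormality before returning, so corrupt
# files or mismatched d-shell conventions fail loudly.

#' Write a wavefunction to a Molden file
#'
#' @param wfn a [wavefunction_data()] object.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_molden <- function(wfn, path) {
  stopifnot(inherits(wfn, "wavefunction"))
  bas <- wfn$basis
  if (is.null(bas$prim_coef_raw))
    stop("basis carries no raw contraction coefficients")
  mol <- wfn$mol
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(sprintf(...), con)
  w("[Molden Format]")
  w("[Title]")
  w("lrfbo export functional=%s basis=%s flavor=%s",
    wfn$method$functional %||% "unknown", wfn$method$basis %||% "unknown",
    wfn$method$b3lyp_flavor %||% "none")
  w("[Atoms] AU")
  for (a in seq_along(mol$symbols))
    w("%-3s %4d %4d %20.12f %20.12f %20.12f", mol$symbols[a], a,
      mol$z[a], mol$coords[a, 1], mol$coords[a, 2], mol$coords[a, 3])
  w("[GTO]")
  lchar <- c("s", "p", "d", "f")
  for (a in seq_along(mol$symbols)) {
    w("%4d 0", a)
    for (s in which(bas$shell_atom == a)) {
      np <- bas$shell_nprim[s]
      w(" %s %4d 1.00", lchar[bas$shell_l[s] + 1L], np)
      for (k in seq_len(np)) {
        idx <- bas$shell_ptr[s] + k
        w("  %20.10e %20.10e", bas$prim_exp[idx], bas$prim_coef_raw[idx])
      }
    }
    w("")
  }
  if (bas$harmonic == "spherical") w("[5D]")
  w("[MO]")
  for (m in seq_len(wfn$nmo)) {
    w(" Sym= A")
    w(" Ene= %.10f", wfn$eps[m])
    w(" Spin= Alpha")
    w(" Occup= %.6f", wfn$occ[m])
    for (mu in seq_len(wfn$nao))
      if (abs(wfn$C[mu, m]) > 1e-12)
        w(" %d %.10e", mu, wfn$C[mu, m])
  }
  invisible(path)
}

#' Read a wavefunction from a Molden file
#'
#' Restricted closed-shell files only: separate alpha/beta blocks that
#' differ raise an unsupported-system error.  The AO overlap matrix is
#' recomputed from the parsed basis; an orthonormality residual above
#' `orth_tol` raises a corrupt-file/mismatched-convention error.
#'
#' @param path Molden file path.
#' @param orth_tol maximum tolerated `max |C'SC - I|`.
#' @return a [wavefunction_data()] object.
#' @export
read_molden <- function(path, orth_tol = 1e-4) {
  lines <- readLines(path, warn = FALSE)
  if (!any(grepl("\\[Molden Format\\]", lines, ignore.case = TRUE)))
    stop("not a Molden file: missing [Molden Format] header")
  sec <- function(name) grep(paste0("^\\s*\\[", name, "\\]"), lines,
                             ignore.case = TRUE)
  spherical_d <- any(grepl("^\\s*\\[5D", lines, ignore.case = TRUE))
  # ---- atoms
  ia <- sec("Atoms")
  if (length(ia) != 1L) stop("Molden file needs exactly one [Atoms] section")
  unit <- if (grepl("AU", lines[ia], ignore.case = TRUE)) "bohr"
          else "angstrom"
  symbols <- character(0); zs <- integer(0); coords <- NULL
  i <- ia + 1L
  while (i <= length(lines) && !grepl("^\\s*\\[", lines[i])) {
    tok <- strsplit(trimws(lines[i]), "[[:space:]]+")[[1L]]
    if (length(tok) >= 6L) {
      symbols <- c(symbols, tok[1L])
      zs <- c(zs, as.integer(tok[3L]))
      coords <- rbind(coords, as.numeric(tok[4:6]))
    }
    i <- i + 1L
  }
  # ---- GTO
  ig <- sec("GTO")
  if (length(ig) != 1L) stop("Molden file needs a [GTO] section")
  lmap <- c(s = 0L, p = 1L, d = 2L, f = 3L, sp = -1L)
  shells <- list()
  i <- ig + 1L
  cur_atom <- NA_integer_
  while (i <= length(lines) && !grepl("^\\s*\\[", lines[i])) {
    ln <- trimws(lines[i])
    if (!nzchar(ln)) { i <- i + 1L; next }
    tok <- strsplit(ln, "[[:space:]]+")[[1L]]
    if (length(tok) == 2L && !is.na(suppressWarnings(as.integer(tok[1L])))
        && tolower(tok[1L]) == tok[1L]) {
      cur_atom <- as.integer(tok[1L])
      i <- i + 1L
      next
    }
    ltag <- tolower(tok[1L])
    if (!ltag %in% names(lmap))
      stop("unsupported shell type '", tok[1L], "' in [GTO]")
    if (ltag == "sp")
      stop("sp shells are not supported; split them into s and p")
    np <- as.integer(tok[2L])
    prim <- matrix(NA_real_, np, 2L)
    for (k in seq_len(np)) {
      v <- strsplit(trimws(lines[i + k]), "[[:space:]]+")[[1L]]
      v <- as.numeric(gsub("[dD]", "e", v))
      prim[k, ] <- v[1:2]
    }
    shells[[length(shells) + 1L]] <-
      list(l = lmap[[ltag]], atom = cur_atom, exp = prim[, 1L],
           coef = prim[, 2L])
    i <- i + np + 1L
  }
  # ---- MO
  im <- sec("MO")
  if (length(im) != 1L) stop("Molden file needs a [MO] section")
  i <- im + 1L
  mos <- list()
  cur <- NULL
  flush_mo <- function(cur, mos) {
    if (!is.null(cur)) mos[[length(mos) + 1L]] <- cur
    mos
  }
  while (i <= length(lines) && !grepl("^\\s*\\[", lines[i])) {
    ln <- trimws(lines[i])
    if (grepl("^Sym\\s*=", ln, ignore.case = TRUE)) {
      mos <- flush_mo(cur, mos)
      cur <- list(ene = NA_real_, spin = "Alpha", occ = 0,
                  coef_idx = integer(0), coef_val = numeric(0))
    } else if (grepl("^Ene\\s*=", ln, ignore.case = TRUE)) {
      if (is.null(cur)) cur <- list(spin = "Alpha", occ = 0,
                                    coef_idx = integer(0),
                                    coef_val = numeric(0))
      cur$ene <- as.numeric(sub(".*=", "", ln))
    } else if (grepl("^Spin\\s*=", ln, ignore.case = TRUE)) {
      cur$spin <- trimws(sub(".*=", "", ln))
    } else if (grepl("^Occup\\s*=", ln, ignore.case = TRUE)) {
      cur$occ <- as.numeric(sub(".*=", "", ln))
    } else if (nzchar(ln)) {
      tok <- strsplit(ln, "[[:space:]]+")[[1L]]
      cur$coef_idx <- c(cur$coef_idx, as.integer(tok[1L]))
      cur$coef_val <- c(cur$coef_val, as.numeric(gsub("[dD]", "e",
                                                      tok[2L])))
    }
    i <- i + 1L
  }
  mos <- flush_mo(cur, mos)
  spins <- vapply(mos, function(m) tolower(m$spin), "")
  if (any(spins == "beta")) {
    al <- mos[spins != "beta"]; be <- mos[spins == "beta"]
    same <- length(al) == length(be) &&
      all(vapply(seq_along(al), function(k)
        isTRUE(all.equal(al[[k]]$coef_val, be[[k]]$coef_val,
                         tolerance = 1e-8)) &&
          isTRUE(all.equal(al[[k]]$occ, be[[k]]$occ)), TRUE))
    if (!same)
      stop("unsupported system: unrestricted (differing alpha/beta) ",
           "orbitals in Molden file")
    mos <- lapply(seq_along(al), function(k) {
      m <- al[[k]]; m$occ <- m$occ + be[[k]]$occ; m
    })
  }
  occ <- vapply(mos, function(m) m$occ, 0)
  if (!all(abs(occ) < 1e-8 | abs(occ - 2) < 1e-8))
    stop("unsupported system: fractional or open-shell occupations")
  occ <- ifelse(abs(occ - 2) < 1e-8, 2, 0)
  nelec <- sum(occ)
  charge <- sum(zs) - nelec
  mol <- molecule(symbols, coords, charge = as.integer(round(charge)),
                  unit = unit)
  harmonic <- if (spherical_d) "spherical" else "cartesian"
  bas <- .make_aobasis(mol, shells, harmonic = harmonic, name = "molden")
  nao <- bas$nao
  C <- matrix(0, nao, length(mos))
  for (m in seq_along(mos)) {
    if (max(mos[[m]]$coef_idx) > nao)
      stop("MO coefficient index exceeds AO count (", nao, "); ",
           "possible d-shell convention mismatch")
    C[mos[[m]]$coef_idx, m] <- mos[[m]]$coef_val
  }
  eps <- vapply(mos, function(m) m$ene, 0)
  if (anyNA(C) || anyNA(eps))
    stop("corrupt Molden file: unparseable MO coefficients or energies")
  S <- overlap_matrix(bas)
  title <- grep("functional=", lines, value = TRUE)
  meta <- list(functional = "unknown", basis = "molden",
               backend = "molden", path = path)
  if (length(title) == 1L) {
    gv <- function(k) {
      mm <- regmatches(title, regexec(paste0(k, "=([^ ]+)"), title))[[1L]]
      if (length(mm) == 2L) mm[2L] else NULL
    }
    meta$functional <- gv("functional") %||% "unknown"
    meta$basis <- gv("basis") %||% "molden"
    meta$b3lyp_flavor <- gv("flavor")
  }
  wavefunction_data(C, eps = eps, occ = occ, S = S, basis = bas,
                    mol = mol, method = meta, orth_tol = orth_tol)
}
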