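#' Construct a molecule
#'
#' Coordinates are stored internally in Bohr.  Only closed-shell systems
#' (multiplicity 1) are in scope for the response machinery.
#'
#' @param symbols character vector of element symbols.
#' @param coords numeric matrix (n x 3) of Cartesian coordinates.
#' @param charge integer total charge (e).
#' @param multiplicity integer spin multiplicity.
#' @param unit `"bohr"` or `"angstrom"` for the incoming coordinates.
#' @return an object of class `"molecule"` with fields `symbols`, `z`,
#'   `coords` (Bohr), `charge`, `multiplicity`.
#' @export
molecule <- function(symbols, coords, charge = 0L, multiplicity = 1L,
                     unit = c("bohr", "angstrom")) {
  unit <- match.arg(unit)
  coords <- as.matrix(coords)
  if (length(symbols) < 1L) stop("a molecule needs at least one atom")
  if (nrow(coords) != length(symbols) || ncol(coords) != 3L)
    stop("coords must be a length(symbols) x 3 matrix")
  if (!all(is.finite(coords))) stop("all coordinates must be finite")
  z <- element_number(symbols)
  if (unit == "angstrom") coords <- coords * .ang2bohr
  nelec <- sum(z) - as.integer(charge)
  if (as.integer(multiplicity) != 1L)
    stop("unsupported system: only closed-shell (multiplicity 1) molecules ",
         "are supported")
  if (nelec %% 2L != 0L)
    stop("unsupported system: odd electron count (", nelec,
         ") cannot be closed-shell")
  structure(list(symbols = as.character(symbols), z = z,
                 coords = unname(coords), charge = as.integer(charge),
                 multiplicity = as.integer(multiplicity),
                 nelec = nelec),
            class = "molecule")
}

#' Read a molecule from an XYZ file
#'
#' Standard XYZ: atom count line, comment line, then one `El x y z` line per
#' atom in Angstrom.  If the comment line contains tokens `charge=<int>`
#' and/or `mult=<int>` they are honoured; otherwise charge 0, multiplicity 1.
#'
#' @param path path to the XYZ file.
#' @return a [molecule()].
#' @export
load_xyz <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 2L) stop("malformed XYZ file: fewer than 2 lines")
  n <- suppressWarnings(as.integer(trimws(lines[1L])))
  if (is.na(n) || n < 1L)
    stop("malformed XYZ file: line 1 is not a positive atom count")
  if (length(lines) < 2L + n)
    stop("malformed XYZ file: expected ", n, " atom lines")
  comment <- lines[2L]
  charge <- 0L; mult <- 1L
  m <- regmatches(comment, regexec("charge=(-?[0-9]+)", comment))[[1L]]
  if (length(m) == 2L) charge <- as.integer(m[2L])
  m <- regmatches(comment, regexec("mult=([0-9]+)", comment))[[1L]]
  if (length(m) == 2L) mult <- as.integer(m[2L])
  symbols <- character(n)
  coords <- matrix(NA_real_, n, 3L)
  for (i in seq_len(n)) {
    ln <- trimws(lines[2L + i])
    tok <- strsplit(ln, "[[:space:]]+")[[1L]]
    if (length(tok) < 4L)
      stop("malformed XYZ atom line ", 2L + i, ": '", ln, "'")
    xyz <- suppressWarnings(as.numeric(tok[2:4]))
    if (anyNA(xyz))
      stop("malformed XYZ atom line ", 2L + i, ": non-numeric coordinate")
    symbols[i] <- tok[1L]
    coords[i, ] <- xyz
  }
  molecule(symbols, coords, charge = charge, multiplicity = mult,
           unit = "angstrom")
}

#' Write a molecule to an XYZ file
#' @param mol a [molecule()].
#' @param path output path.
#' @param comment comment line (charge/multiplicity tokens are appended).
#' @export
write_xyz <- function(mol, path, comment = "") {
  stopifnot(inherits(mol, "molecule"))
  ang <- mol$coords / .ang2bohr
  hdr <- sprintf("%s charge=%d mult=%d", comment, mol$charge,
                 mol$multiplicity)
  lines <- c(sprintf("%d", length(mol$symbols)), trimws(hdr),
             sprintf("%-3s %18.12f %18.12f %18.12f", mol$symbols,
                     ang[, 1], ang[, 2], ang[, 3]))
  writeLines(lines, path)
  invisible(path)
}

#' @export
print.molecule <- function(x, ...) {
  cat(sprintf("<molecule> %d atoms, charge %+d, multiplicity %d\n",
              length(x$symbols), x$charge, x$multiplicity))
  ang <- x$coords / .ang2bohr
  for (i in seq_along(x$symbols))
    cat(sprintf("  %-3s %12.6f %12.6f %12.6f\n", x$symbols[i],
                ang[i, 1], ang[i, 2], ang[i, 3]))
  invisible(x)
}

# nuclear repulsion energy (hartree)
nuclear_repulsion <- function(mol) {
  n <- nrow(mol$coords)
  e <- 0
  if (n < 2L) return(0)
  for (i in seq_len(n - 1L)) for (j in seq((i + 1L), n)) {
    r <- sqrt(sum((mol$coords[i, ] - mol$coords[j, ])^2))
    e <- e + mol$z[i] * mol$z[j] / r
  }
  e
}
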