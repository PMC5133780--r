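# Periodic-table data for elements 1..54.

.element_symbols <- c(
  "H", "He",
  "Li", "Be", "B", "C", "N", "O", "F", "Ne",
  "Na", "Mg", "Al", "Si", "P", "S", "Cl", "Ar",
  "K", "Ca", "Sc", "Ti", "V", "Cr", "Mn", "Fe", "Co", "Ni", "Cu", "Zn",
  "Ga", "Ge", "As", "Se", "Br", "Kr",
  "Rb", "Sr", "Y", "Zr", "Nb", "Mo", "Tc", "Ru", "Rh", "Pd", "Ag", "Cd",
  "In", "Sn", "Sb", "Te", "I", "Xe")

# Bragg-Slater atomic radii (Angstrom) used to scale radial quadrature maps.
# H uses 0.35 (the common molecular-quadrature choice rather than 0.25).
.bragg_slater <- c(
  0.35, 0.31,
  1.45, 1.05, 0.85, 0.70, 0.65, 0.60, 0.50, 0.38,
  1.80, 1.50, 1.25, 1.10, 1.00, 1.00, 1.00, 0.71,
  2.20, 1.80, 1.60, 1.40, 1.35, 1.40, 1.40, 1.40, 1.35, 1.35, 1.35, 1.35,
  1.30, 1.25, 1.15, 1.15, 1.15, 0.88,
  2.35, 2.00, 1.80, 1.55, 1.45, 1.45, 1.35, 1.30, 1.35, 1.40, 1.60, 1.55,
  1.55, 1.45, 1.45, 1.40, 1.40, 1.08)

#' Atomic number for an element symbol
#'
#' @param symbol character vector of element symbols (case sensitive,
#'   standard capitalisation, e.g. `"Cl"`).
#' @return integer vector of atomic numbers.
#' @keywords internal
element_number <- function(symbol) {
  z <- match(symbol, .element_symbols)
  if (anyNA(z)) {
    stop("unknown element symbol(s): ",
         paste(unique(symbol[is.na(z)]), collapse = ", "))
  }
  z
}

bragg_slater_radius <- function(z) {
  stopifnot(all(z >= 1L), all(z <= length(.bragg_slater)))
  # in Bohr
  .bragg_slater[z] / 0.52917721067
}

# CODATA Angstrom -> Bohr
.ang2bohr <- 1.8897261254578281
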