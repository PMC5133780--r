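# Reporting layer: sign semantics, leaving-group ranking, and the
# Hammett-constant regression interface.

#' Interpret the sign of a bond-order response value
#'
#' First-order estimate `Delta B ~ (dB/dv) * dv`: a positive response
#' value with a repulsive (positive) perturbation increases the bond
#' order; flipping either sign flips the direction.
#'
#' @param value the condensed response value.
#' @param perturbation `"repulsive"` (dv > 0) or `"attractive"` (dv < 0).
#' @return `"increase"`, `"decrease"` or `"no first-order change"`.
#' @export
interpret_sign <- function(value,
                           perturbation = c("repulsive", "attractive")) {
  perturbation <- match.arg(perturbation)
  if (!is.finite(value)) stop("value must be finite")
  if (value == 0) return("no first-order change")
  s <- value * (if (perturbation == "repulsive") 1 else -1)
  if (s > 0) "increase" else "decrease"
}

#' Rank candidate leaving groups by self-perturbation response
#'
#' Orders metal-ligand bonds by `dB(M-X)/dv(X)` (descending; a larger
#' positive value means an electrophilic attack on X labilises the M-X
#' bond more strongly, the trans-effect ordering).  Ties are broken by
#' atom index.
#'
#' @param tbl a bond-type `"condensed_lrf"` table, or a numeric vector of
#'   `dB(M-X)/dv(X)` values named by bond.
#' @param bonds matrix/data frame of (metal_atom, ligand_atom) index
#'   pairs (ignored for a named-vector `tbl`).
#' @return data frame (bond, metal, ligand, value) sorted by rank.
#' @export
rank_leaving_groups <- function(tbl, bonds = NULL) {
  if (is.numeric(tbl) && !is.null(names(tbl))) {
    d <- data.frame(bond = names(tbl), metal = NA_integer_,
                    ligand = seq_along(tbl), value = as.numeric(tbl),
                    stringsAsFactors = FALSE)
  } else {
    stopifnot(inherits(tbl, "condensed_lrf"), tbl$type == "bond")
    bonds <- as.matrix(bonds)
    nat <- length(tbl$labels)
    if (any(bonds < 1 | bonds > nat))
      stop("bond atom index out of range")
    v <- vapply(seq_len(nrow(bonds)), function(k)
      tbl$values[bonds[k, 1], bonds[k, 2], bonds[k, 2]], numeric(1))
    d <- data.frame(
      bond = paste0(tbl$labels[bonds[, 1]], "-", tbl$labels[bonds[, 2]]),
      metal = bonds[, 1], ligand = bonds[, 2], value = v,
      stringsAsFactors = FALSE)
  }
  d[order(-d$value, d$ligand), , drop = FALSE]
}

#' Ordinary least-squares fit of sigma constants on descriptor values
#'
#' @param x descriptor values (e.g. `dB(O-H)/dv(L)` across substituents).
#' @param y literature Hammett sigma constants.
#' @return list(slope, intercept, r2, n, predict) where `predict(x)`
#'   returns fitted sigma values.
#' @export
linear_fit <- function(x, y) {
  if (length(x) != length(y)) stop("x and y lengths differ")
  if (length(x) < 3) stop("need at least 3 points")
  if (stats::sd(x) == 0) stop("degenerate x: all descriptor values equal")
  fit <- lm(y ~ x)
  cf <- coef(fit)
  r2 <- cor(x, y)^2   # R^2 = squared Pearson correlation for simple OLS
  list(slope = unname(cf[2]), intercept = unname(cf[1]), r2 = r2,
       n = length(x),
       predict = function(xnew) unname(cf[1] + cf[2] * xnew))
}

#' Build a Hammett record table
#'
#' @param substituent character labels.
#' @param position `"meta"`, `"para"` or `"none"` (the unsubstituted
#'   reference).
#' @param sigma literature Hammett constants (input data, never computed
#'   here).
#' @param descriptor the bond-order response descriptor value for each
#'   record (single consistent method/grid across the set).
#' @param charged logical; charged substituents are refused (their
#'   hydrated-cluster structures fluctuate beyond this model's scope).
#' @param provenance free-text provenance note.
#' @return data frame of class `"hammett_records"`.
#' @export
hammett_records <- function(substituent, position, sigma, descriptor,
                            charged = FALSE, provenance = "") {
  position <- as.character(position)
  if (!all(position %in% c("meta", "para", "none")))
    stop("position must be meta, para or none")
  if (any(charged))
    stop("charged substituent groups are excluded: hydrated charged ",
         "clusters are outside the descriptor's scope")
  if (any(is.na(sigma) & position != "none"))
    stop("every substituted record needs position and sigma together")
  d <- data.frame(substituent = substituent, position = position,
                  sigma = sigma, descriptor = descriptor,
                  provenance = provenance, stringsAsFactors = FALSE)
  class(d) <- c("hammett_records", class(d))
  d
}

#' Per-site Hammett regressions
#'
#' Fits sigma against the descriptor separately for the meta and para
#' sets (they follow different substituent scales) for each perturbation
#' site, and flags sites whose correlation is high while the descriptor
#' magnitudes are negligible (correlation without leverage).
#'
#' @param records a [hammett_records()] data frame; the `descriptor`
#'   column may be a matrix with one column per perturbation site.
#' @param sites character vector naming the perturbation sites (columns).
#' @param small_descriptor magnitude below which a site is flagged.
#' @return data frame: one row per (site, position) with slope,
#'   intercept, r2, n, max_abs_descriptor, flagged.
#' @export
hammett_report <- function(records, sites = NULL,
                           small_descriptor = 1e-2) {
  stopifnot(inherits(records, "hammett_records"))
  D <- as.matrix(records$descriptor)
  if (is.null(sites)) sites <- colnames(D)
  if (is.null(sites)) sites <- paste0("site", seq_len(ncol(D)))
  out <- NULL
  for (s in seq_len(ncol(D))) {
    for (pos in c("meta", "para")) {
      sel <- records$position == pos
      if (sum(sel) < 3) next
      f <- linear_fit(D[sel, s], records$sigma[sel])
      out <- rbind(out, data.frame(
        site = sites[s], position = pos, slope = f$slope,
        intercept = f$intercept, r2 = f$r2, n = f$n,
        max_abs_descriptor = max(abs(D[sel, s])),
        flagged = f$r2 > 0.7 & max(abs(D[sel, s])) < small_descriptor,
        stringsAsFactors = FALSE))
    }
  }
  if (is.null(out)) stop("no position set has >= 3 records")
  out
}
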