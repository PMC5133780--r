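# Shared fixtures: cached converged wavefunctions shipped with the
# package (computed with the native engine) and small live SCF runs,
# memoised per test session.

.wfn_cache <- new.env(parent = emptyenv())

cached_wfn <- function(name) {
  if (is.null(.wfn_cache[[name]])) {
    path <- system.file("extdata", "wavefunctions",
                        paste0(name, ".molden"), package = "lrfbo")
    stopifnot(nzchar(path))
    .wfn_cache[[name]] <- read_molden(path)
  }
  .wfn_cache[[name]]
}

water_geometry <- function(r = 0.9572, adeg = 104.52) {
  a <- adeg * pi / 180
  molecule(c("O", "H", "H"),
           rbind(c(0, 0, 0),
                 c(r * sin(a / 2), 0, r * cos(a / 2)),
                 c(-r * sin(a / 2), 0, r * cos(a / 2))),
           unit = "angstrom")
}

water_sto3g <- function() {
  if (is.null(.wfn_cache$water_sto3g))
    .wfn_cache$water_sto3g <-
      run_scf(water_geometry(), scf_method(functional = "hf",
                                           basis = "sto-3g"))
  .wfn_cache$water_sto3g
}

# full response stack for a wavefunction at a given grid
response_stack <- function(wfn, n_radial = 75L, lebedev_order = 302L,
                           mode = "own") {
  g <- build_partitioned_grid(wfn$mol, n_radial, lebedev_order)
  dm <- density_matrix(wfn)
  pairs <- build_pair_basis(wfn)
  weights <- pair_bond_weights(wfn, dm, pairs)
  overlaps <- region_overlaps(wfn, g, mode = mode)
  list(grid = g, dm = dm, pairs = pairs, weights = weights,
       overlaps = overlaps,
       bo = lrf_bo_condensed(weights, pairs, overlaps))
}

shipped_xyz <- function(name)
  system.file("extdata", "geometries", paste0(name, ".xyz"),
              package = "lrfbo")
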