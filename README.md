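# lrfbo — linear response functions of Mayer bond orders

`lrfbo` computes how every chemical bond in a closed-shell molecule
responds to a *virtual local perturbation* applied at any atomic site —
a reactivity descriptor for chemists who want to ask "if a reagent,
catalyst or solvent pushed on the electrons at atom L, which bonds
would strengthen and which would break?" without simulating the actual
encounter.

For a restricted single-determinant wavefunction (Hartree–Fock or
Kohn–Sham orbitals ψ with energies ε over an AO basis with overlap S),
the first-order uncoupled response of the density matrix to a local
potential δv(**r**) is

    δP_μν/δv(r) = 2 Σ_i^occ Σ_j^virt  ψ_j(r) ψ_i(r) / (ε_i − ε_j) · (C_jμ C_iν + C_iμ C_jν)

and propagating it through the Mayer bond order
B_IJ = Σ_{μ∈I} Σ_{ν∈J} (PS)_μν (PS)_νμ gives a pointwise kernel
δB_IJ/δv(**r**).  The package condenses that kernel over the
**Wigner–Seitz cell** of each atom (the region closer to that nucleus
than to any other — a hard, non-fuzzy partition) with an
Euler–Maclaurin × Lebedev quadrature:

    δB_IJ/δv(L) = ∫_L δB_IJ/δv(r) dr .

A positive value means a perturbation that is repulsive for electrons
at atom L *increases* the I–J bond order; a negative value means it
labilises the bond.  The same machinery condenses the density response
δρ(K)/δv(L), and for planar molecules both tables can be split exactly
into σ, π and cross channels by reflection parity.  An analysis layer
ranks leaving groups by self-perturbation response and regresses
Hammett σ constants on descriptor values.

Everything is self-contained: the package includes its own restricted
RHF/B3LYP engine (McMurchie–Davidson Gaussian integrals in C++, DIIS,
Becke-weighted XC quadrature), bundled STO-3G and 6-311G**-type basis
tables for H/C/N/O/F/Cl, Molden import/export, and analytic model
wavefunctions for testing.

## Worked example: water

```r
library(lrfbo)

xyz <- system.file("extdata", "geometries", "h2o-b3lyp-6311gss.xyz",
                   package = "lrfbo")
mol <- load_xyz(xyz)                    # B3LYP/6-311G** optimized H2O
wfn <- run_scf(mol, scf_method())       # native B3LYP(VWN5)/6-311G**
#> <wavefunction> B3LYP/6-311gss: 31 AOs, 31 MOs, 10 electrons, E = -76.41117129 hartree

mayer_bond_orders(wfn = wfn)
#>        O1    H2    H3
#> O1 15.004 0.970 0.970
#> H2  0.970 0.553 0.005
#> H3  0.970 0.005 0.553

grid     <- build_partitioned_grid(mol, 75, 302)
dm       <- density_matrix(wfn)
pairs    <- build_pair_basis(wfn)
weights  <- pair_bond_weights(wfn, dm, pairs)
overlaps <- region_overlaps(wfn, grid)
tbl      <- lrf_bo_condensed(weights, pairs, overlaps)

subset(as.data.frame(tbl), atom_I == "O1" & atom_J != "O1")
#>  atom_I atom_J perturb_atom_L channel      value
#>      O1     H2             O1   total  0.8159124
#>      O1     H3             O1   total  0.8159124
#>      O1     H2             H2   total -0.9638634
#>      O1     H3             H2   total  0.1488626
#>      O1     H2             H3   total  0.1488626
#>      O1     H3             H3   total -0.9638634
```

Reading the table: a repulsive perturbation inside the oxygen cell
*strengthens* both O–H bonds (+0.816 each); the same perturbation on
one hydrogen *weakens its own* O–H bond (−0.964) while slightly
strengthening the other one (+0.149) — the first-order signature of
proton abstraction.  `interpret_sign(-0.964, "repulsive")` returns
`"decrease"`.  The built-in diagnostics confirm the numerics:

```r
sum_rule_report(tbl, wfn, dm, pairs, weights)[c("max_row_residual",
                                                "pointwise_residual")]
#> $max_row_residual    0.0147     # Σ_L δB/δv(L) = 0, grid-limited
#> $pointwise_residual  9.3e-16    # Σ_IJ δB_IJ/δv(r) = 0, exact identity
```

The condensed response values are validated in the test suite against
an independent finite-difference oracle (one-shot diagonalisation of
the perturbed Fock operator), so the reported scale is the true
derivative dB/dv.

A command-line wrapper is installed as `exec/lrfbo`:

```sh
lrfbo run --input h2o.xyz --optimize --density --outdir results/
lrfbo validate --input wfn.molden
lrfbo hammett --records records.csv --bond 14,15 --site 4
```

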