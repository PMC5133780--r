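---
title: "Bond-order response functions: model, numerics and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bond-order response functions: model, numerics and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

`lrfbo` computes conceptual-DFT-style reactivity descriptors built on the
*uncoupled orbital linear response* of a closed-shell single-determinant
wavefunction.  Given converged restricted orbitals $\psi_k$ with energies
$\varepsilon_k$ over a contracted Gaussian AO basis with overlap matrix
$S$, the first-order response of the one-particle density matrix to a
local external potential $\delta v(\mathbf r)$ is

$$
\frac{\delta P_{\mu\nu}}{\delta v(\mathbf r)}
 = 2\sum_{i}^{\mathrm{occ}}\sum_{j}^{\mathrm{virt}}
   \frac{\psi_j(\mathbf r)\,\psi_i(\mathbf r)}
        {\varepsilon_i-\varepsilon_j}
   \left(C_{j\mu}C_{i\nu}+C_{i\mu}C_{j\nu}\right),
$$

the global factor 2 being the spin summation over identical
$\alpha/\beta$ spatial orbitals.  The Mayer bond order
$B_{IJ}=\sum_{\mu\in I}\sum_{\nu\in J}Q_{\mu\nu}Q_{\nu\mu}$ with
$Q = PS$ then responds as

$$
\frac{\delta B_{IJ}}{\delta v(\mathbf r)}
 = \sum_{\mu\in I}\sum_{\nu\in J}
   \left(\frac{\delta Q_{\mu\nu}}{\delta v(\mathbf r)}Q_{\nu\mu}
        +Q_{\mu\nu}\frac{\delta Q_{\nu\mu}}{\delta v(\mathbf r)}\right).
$$

A positive atom-condensed value means that a potential that is
*repulsive for electrons* applied inside that atom's cell increases the
bond order at first order (`interpret_sign()` encodes all four
sign/perturbation combinations).  The analogous density response
$\delta\rho(K)/\delta v(L)$ is condensed over two atomic cells and is
symmetric with a non-positive diagonal.

Three modelling assumptions delimit scope:

* **Closed shell only.**  Occupations are 2/0; open-shell systems are
  rejected at construction.
* **Uncoupled response.**  The bare occupied-virtual energy denominators
  are used; no coupled-perturbed self-consistency, so there is no
  screening of the perturbation.  The reported kernel is exactly the
  derivative of the bond order under a one-shot re-diagonalisation of
  the perturbed Fock operator — the test suite checks this against a
  finite-difference oracle at localized Gaussian perturbations.
* **Frozen AOs.**  The perturbation represents an approaching reagent
  or environment, not a nuclear displacement, so basis functions do not
  respond.

Degenerate occupied-virtual gaps make the response diverge; gaps below
`1e-6` hartree are a hard error rather than a silent skip.

## Real-space condensation

Atom condensation integrates the pointwise kernel over the molecular
*Wigner-Seitz cell* of each atom: the region closer to that nucleus than
to any other, bounded by perpendicular-bisector planes.  Cells are hard
— a quadrature point is either inside or outside — because the virtual
perturbation is meant to be strictly local to one atomic site; fuzzy
(Becke-type) switching would smear it over neighbouring atoms.  Becke
partitioning *is* used in two auxiliary roles where a partition of
unity is the right tool: the exchange-correlation quadrature of the SCF
engine, and the `mode = "union"` cross-check described below.

Each atom carries a single-centre grid: a Murray-Handy-Laming
Euler-Maclaurin radial map $r_i = R\,i^2/(n+1-i)^2$ (scale $R$ = the
element's Bragg-Slater radius, covering $[0,\infty)$ so unbounded outer
cells need no truncation radius) times a Lebedev angular set.  Defaults
are $75\times302$, a standard "fine" molecular-quadrature choice; all
stated tolerances are tied to it.  Points of atom $L$'s grid that leave
$L$'s cell get effective weight zero; boundary ties (a measure-zero
set) go to the lowest atom index.  No pruning is applied — pruning
interacts unpredictably with hard cell boundaries.

The factorised production path computes per-pair condensed bond weights
$w^{(ij)}_{IJ}$ once (they satisfy $\sum_{IJ}w^{(ij)}_{IJ}=0$ exactly,
by MO orthonormality) and per-atom region overlaps
$G^L_{ij}=\int_L\psi_i\psi_j\,d\mathbf r$ on the grid, giving
$\delta B_{IJ}/\delta v(L) = 2\sum_{ij} w^{(ij)}_{IJ}
G^L_{ij}/(\varepsilon_i-\varepsilon_j)$ at cost
$O(N_\mathrm{pairs}N_\mathrm{at}^2 + N_\mathrm{grid}N_\mathrm{MO}^2)$.
The unfactorised element-by-element chain is retained
(`lrf_bo_pointwise(method = "direct")`) purely as a test oracle; the
two agree to $10^{-10}$.

**Quadrature diagnostics.**  Two exact identities calibrate the grid:
summed over all atom pairs including diagonals, the pointwise kernel
vanishes identically (machine precision, grid-independent); summed over
all perturbation cells, each condensed value vanishes (grid-limited).
On water at $75\times302$ the orthonormality residual
$\max_{ij}|\sum_L G^L_{ij}-\delta_{ij}|$ is $\sim7\times10^{-3}$ and
the worst row sum $\sim1.5\times10^{-2}$.  Along the standard ladder
$35\times110 \to 50\times194 \to 75\times302$ both residuals fall
strictly; beyond the default the *row-sum* residual — a signed
cancellation — is no longer strictly monotone (it bumps at
$99\times434$ before falling again by $120\times434$), which is why the
refinement test asserts decrease along the documented ladder.  A second
estimator (`region_overlaps(mode = "union")`) bins the union of all
centres' points by cell owner with Becke partition-of-unity factors;
own-centre and union estimates agree within a few times the
orthonormality residual, bounding the hard-boundary discretisation
error.

## The native SCF backend and bundled bases

No external quantum-chemistry engine is assumed: the package carries a
restricted Hartree-Fock / hybrid-GGA Kohn-Sham engine (McMurchie-
Davidson integrals over Cartesian Gaussians up to $d$, DIIS on the
orthonormalised $FPS-SPF$ commutator, generalised Wolfsberg-Helmholz
guess).  B3LYP is assembled as
$0.20\,E_x^{HF}+0.80\,E_x^{Slater}+0.72\,\Delta E_x^{B88}
+0.19\,E_c^{VWN}+0.81\,E_c^{LYP}$ with the VWN flavour selectable:
`vwn5` (default) or `vwn3` (RPA-parameterised); the choice is recorded
in the method metadata.  On the systems treated here the two flavours
move condensed response values by well under 0.1%.  Exchange-
correlation quadrature uses the same grid machinery with Becke weights;
XC potentials are obtained by central finite differences of the
analytic energy density ($\sim10^{-9}$ accuracy), keeping each
functional's code at its textbook formula.  Engine checkpoints
reproduced during development: H$_2$/STO-3G RHF $-1.11671$,
H$_2$O/STO-3G RHF $-74.9629$, H$_2$O/6-311G** RHF $-76.0465$,
H$_2$O/6-311G** B3LYP(VWN3) $-76.4482$ hartree — all at their standard
literature values.

Two basis sets ship as plain text (`inst/extdata/basis/`): STO-3G and a
6-311G**-type triple-split set for H, C, N, O, F, Cl.  The Cl set is
carried *uncontracted* (12s,9p,1d): with the standard exponent list the
uncontracted form reproduces the expected RHF total energy of HCl to
$<0.01$ hartree, and the condensed response values move by only
$\sim0.1$% relative to a contracted variant, so the decontraction is a
safe representation.  Elements outside the bundled tables require a
user-supplied basis file in the same format.  Cartesian $d$ shells (6
components) are the default, matching the common Cartesian-Gaussian
convention for Pople-style sets; spherical (5$d$) is available and is
honoured when reading `[5D]` Molden files.  Shells with $l>3$ (and
effective core potentials) are out of engine scope, which is what
excludes heavy-metal complexes from ab initio reproduction here.

Geometry optimization is gradient-free over symmetry-unique internal
coordinates and intentionally minimal: Brent line search for diatomics,
Nelder-Mead over (bond, angle) for C2v AB$_2$ triatomics.  Native
optima land close to literature geometries (HF 0.9205 A, HCl 1.288 A,
water $r=0.962$ A); the water angle settles at $103.8^\circ$, about
$1.3^\circ$ below the literature B3LYP value — the bending potential is
extremely flat ($\sim4\times10^{-5}$ hartree over that range) and the
residual XC-grid sensitivity shifts the minimum; the condensed
responses move by $<0.002$ across that interval.  Larger molecules are
accepted as pre-optimized geometries; the shipped hexan-1-ol and
hexa-1,3,5-trien-1-ol structures are MMFF94-optimized, with the trienol
symmetrised to exact planarity.

## Sigma/pi decomposition

For a planar molecule every MO has a reflection parity through the
molecular plane.  The classifier computes the exact parity score
$\langle\psi_k|\sigma_h\psi_k\rangle\in[-1,1]$ analytically: reflecting
a Cartesian Gaussian gives a Gaussian at the mirrored centre whose
polynomial transforms by the Householder matrix $I-2nn^{\mathsf T}$, so
the score is an AO-overlap contraction, not a numerical grid (the test
suite still cross-checks it against brute-force numerical reflection).
Scores above $+0.95$ are sigma, below $-0.95$ pi, in between "mixed"
(flagged, counted as contamination).  The plane itself is the
least-squares plane through the heavy atoms, but a molecule only
qualifies as planar when *all* atoms sit within tolerance
(default RMS $10^{-3}$ A) — parity needs the full nuclear frame to be
mirror-symmetric, which is why an all-anti alkyl chain (heavy atoms
coplanar, hydrogens not) is correctly rejected.  Collinear molecules
return a degenerate-plane flag.

Channels are assigned at the *pair* level: both orbitals pi — pi
channel; both sigma — sigma channel; everything else (including pairs
with mixed orbitals) — cross.  Sigma, pi and cross sum to the total
exactly by construction.  For in-plane atoms the cross channel
integrates to approximately zero over their mirror-symmetric cells
($\psi_\sigma\psi_\pi$ is odd under the reflection), which is what
makes the pair-level and occupied-orbital-level conventions agree on
condensed values; the cross channel is always reported so the
convention stays auditable.

## Fixtures: what they emulate and what they do not

* `make_h2_minimal(s)` — the analytic two-AO homonuclear model with
  tunable AO overlap: Q is the all-ones matrix, the bond order is
  exactly 1 for every $s$, and the bond-order response kernel vanishes
  identically (the bonding-antibonding product contributes no
  cross-block response).  Closed forms make it the sharpest fixture for
  the response algebra.
* `make_random_model(n_ao, n_occ, seed)` — random s-Gaussian centres
  with Loewdin-orthogonalised random MOs and strictly increasing
  energies (gap $\ge0.05$ hartree).  Satisfies every wavefunction
  invariant to machine precision and drives the exact identities
  (trace, pointwise sum rule, oracle equivalence, finite-difference
  response) on arbitrary valid wavefunctions.
* `make_ethylene_like()` — a planar two-centre s/p model with exactly
  one occupied pi MO, the minimal sigma/pi test bed.

These fixtures exercise the *algebra* completely, but they are not
chemistry: their energetics are synthetic, their AOs are s/p only, and
passing on them does not by itself validate basis-set or functional
behaviour on real molecules — that is what the cached native-engine
wavefunctions (water, HF, HCl at B3LYP/6-311G**; provenance recorded in
each Molden header) and the live STO-3G organic runs are for.

## Problem sizes and numerical choices

The test suite runs: live STO-3G SCF for water, H$_2$ and the two
C$_6$ alcohols (35 radial $\times$ 110 angular XC grid), cached
6-311G** wavefunctions for water/HF/HCl, response condensation at
$75\times302$, oracle comparisons on $\le8$-AO models at
$20\times50$.  The acceptance script re-optimizes water, HF and HCl
from textbook starting geometries and reports the five condensed
values; it completes in a few minutes on one CPU.  Other fixed
numerical choices: MO orthonormality tolerance $10^{-6}$
($10^{-4}$ for Molden imports, where coefficient printing precision
dominates), SCF convergence $10^{-6}$ on the DIIS error with
$10^{-8}$ on the energy, DIIS depth 8 with 30% damping before DIIS
engages, synthetic Hammett noise $\sigma=0.002$ chosen so sampling
error stays well inside the 5% parameter-recovery check.

## Known limitations

* Elements beyond the bundled H/C/N/O/F/Cl tables need user-supplied
  bases; no ECPs and no $f$ shells, so 5d-metal complexes are out of
  ab initio scope (the ranking layer still operates on externally
  supplied descriptor tables).
* The uncoupled kernel neglects self-consistent screening; trends
  across related bonds are its intended use, not absolute
  polarisabilities.
* Mulliken-based quantities degrade with diffuse bases; basis names
  containing diffuse markers trigger a warning.
* Geometry optimization is limited to diatomics and AB$_2$; everything
  else must arrive optimized.
* Hard Wigner-Seitz cells converge more slowly than fuzzy partitions;
  the row-sum residual ($\sim10^{-2}$ at the default grid) is the
  honest scale of condensation error, and differences smaller than it
  should not be interpreted.
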