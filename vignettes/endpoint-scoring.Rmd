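---
title: "End-point scoring on capped pocket models: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{End-point scoring on capped pocket models: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plscore)
```

## The model

`plscore` implements an end-point protein–ligand scoring framework: the
relative binding free energy of a ligand series is estimated from a single
representative structure per complex, as the sum of five physically
interpretable terms,

$$\mathrm{score} \;=\; \Delta E_\mathrm{int} \;+\; \Delta\Delta G_\mathrm{solv}
\;+\; \Delta G_\mathrm{conf}(L) \;+\; \Delta G_{H^+} \;-\; T\Delta S ,$$

where

* $\Delta E_\mathrm{int} = E(PL) - E(P) - E(L)$ is the gas-phase interaction
  energy, all three evaluations at the fixed complex geometry
  (`interaction_energy()`);
* $\Delta\Delta G_\mathrm{solv} = G_\mathrm{solv}(PL) - G_\mathrm{solv}(P) -
  G_\mathrm{solv}(L)$ is the desolvation penalty (`desolvation_penalty()`);
* $\Delta G_\mathrm{conf}(L)$ is the ligand strain: the energy of the bound
  pose relative to the free ligand relaxed in solvent from that pose
  (`ligand_strain()`);
* $\Delta G_{H^+}$ is the proton-transfer correction, applied only when the
  ligand changes protonation upon binding (`proton_transfer_term()`);
* $-T\Delta S$ is the ligand conformational-entropy penalty, by default
  1 kcal/mol per rotatable bond (`entropy_penalty()`).

More negative totals mean better predicted binding; because the score has
free-energy semantics, its correlation with experimental $\Delta G$ is
expected positive. The framework is an end-point one: it ranks ligands of a
common receptor and makes no claim to absolute binding free energies.

All energies pass through a backend contract: a deterministic map from
(atoms, coordinates, net charge, solvated flag) to a gas-phase energy and a
solvation free energy in kcal/mol, with optional analytic gradients. The
package ships a self-contained classical test backend
(`make_test_backend()`) and a text interface (`render_engine_input()`,
`parse_engine_output()`) for coupling an external semiempirical engine; the
electronic-structure method itself is deliberately outside the package
boundary. Externally parameterized pairwise corrections (hydrogen- or
halogen-bond terms) attach through `correction_backend()`, a plugin hook
with the same signature as the dispersion term; their parameter sets live
with the plugin, not here.

## Pocket models

The receptor is truncated to the residues having any atom within a cutoff
of the union of all overlaid ligands of the series (`select_residues()`;
default 10 Å, with 5–6 Å a typical "trimmed" choice). Selection is strictly
residue-granular and provably monotone in the cutoff. Each cut peptide bond
is terminated by a neutral cap: an $-\mathrm{NH}-\mathrm{CH_3}$ group on the
C-terminal side and a $-\mathrm{CH}=\mathrm{O}$ group on the N-terminal side.
Cap heavy atoms reuse the backbone positions (N/CA, or C/O) of the removed
neighbouring residue — the placement that perturbs the geometry least — and
hydrogens are added at standard bond lengths (C–H 1.09 Å, N–H 1.01 Å) with
tetrahedral/planar directions. The exact placement rule is a package
convention: reported atom counts include cap hydrogens.

Charge bookkeeping is explicit: the pocket's net charge is the sum of
per-residue formal charges (Asp/Glu −1, Lys/Arg +1 at neutral pH,
overridable), ion charges (Zn²⁺, Ca²⁺, Mg²⁺, Na⁺, K⁺, Cl⁻ from a fixed,
overridable table) and cofactor charges; caps are neutral. Charged residues
exposed at the truncation boundary are kept, not neutralized — they are far
from the ligands and screened by the solvent model — but `pocket_charge()`
lists them in a warning so that an implausibly charged trimmed model is
visible rather than silent. Structural waters, ions and cofactors are
retained by explicit whitelists in `pocket_spec()`: deciding *which* waters
define a binding mode is a judgment call we do not automate. Cysteines
joined by a disulfide bridge are pulled into the selection together, so the
boundary never creates a radical centre.

## Proton transfer and entropy

Whether the ligand binds in a different protonation state than it holds in
solution is recorded per complex (`protonation_case()`), with the two
directions treated via explicit acid–base reactions against water:
uptake $L + H_2O \to LH^+ + OH^-$ and release
$LH + H_2O \to L^- + H_3O^+$. The term weights the reaction free energy by
the solution fraction of the species that must change protonation, from the
rearranged Henderson–Hasselbalch equation
$f = 10^{pH-pK_a}/(1+10^{pH-pK_a})$: the uptake branch is weighted by $f$
and the release branch by $1-f$. The release weighting is printed
ambiguously in the background literature ("1 − f · (…)"); we read it as
$(1-f)\cdot(\ldots)$ by symmetry with the uptake branch, and flag this as a
documented interpretation rather than a silent fix. The assay pH has no
default — it is experimental metadata and must be supplied; a protonation
change without a pH is an error. Free energies for the ligand forms come
from the backend on relaxed free-ligand geometries (the geometry choice is
unstated in the background literature; relaxed solution-state geometries
are the thermodynamically consistent reading). Free energies of the water
species must combine a gas-phase energy with *experimental* solvation free
energies; the package deliberately ships no default values for these
constants — fixtures declare their own placeholder values.

The entropy penalty defaults to 1 kcal/mol per rotatable bond. No universal
rotatable-bond convention exists, so the package defines one and makes it
configurable: an acyclic single bond between two heavy atoms, each with at
least one further heavy neighbour, excluding amide C–N bonds. A
descriptor-based entropy estimator can be plugged in without touching the
rest of the pipeline.

## Benchmark evaluation

Experimental affinities convert to free energies as
$\Delta G = RT\ln(K_i/1\,\mathrm{M})$ with $R = 1.98720\times10^{-3}$
kcal/mol/K and $T = 298.15$ K by default ($T$ rescales all $\Delta G$
uniformly and cannot change a correlation). IC50 values stand in for
$K_i$ as IC50/2, valid when the substrate concentration is near the
Michaelis constant; the substitution is linear, so correlations are again
unaffected. Series enter the benchmark when their pKi range exceeds 1.5 and
they contain at least 10 ligands. Quality is the squared Pearson
correlation between score totals and experimental $\Delta G$ per target;
the aggregate is the unweighted mean over targets (every target counts
equally regardless of series size), reported with the population SD over
targets and the minimum. The bundled `plrex_summary()` table carries the
published composition of the public ten-target benchmark (164 complexes,
147 crystal structures), which the package reproduces by pure manifest
arithmetic.

## The test backend and the synthetic benchmark

The classical test backend exists so that the entire pipeline — pocket
construction, conformer selection, all five terms, batch scoring,
evaluation — runs and is testable end to end with no external engine. It is
a toy model and is documented as such; it is not a physical substitute for
a semiempirical Hamiltonian or a conductor-like solvation model. Its parts:

* pairwise Lennard-Jones plus Coulomb (constant 332.0636 kcal·Å/mol/e²),
  with harmonic bond stretches ($\tfrac12 k (r-r_0)^2$, $k = 600$
  kcal/mol/Å², $r_0$ the covalent-radius sum) replacing the non-bonded
  interaction on 1–2 pairs and a 0.5 scale on 1–3 pairs;
* a smooth Born-like solvation term: each atom's effective Born radius
  grows with a Gaussian burial measure $B_i = \sum_j e^{-r_{ij}^2/2w^2}$
  ($w = 3$ Å), plus a buried-surface term $\gamma\,a_i\,e^{-cB_i}$ with
  $\gamma < 0$, so burying atoms costs solvation — which is what produces a
  positive desolvation penalty on binding;
* optionally, the pairwise dispersion correction below;
* analytic gradients for all terms, verified against central differences.

The dispersion term is the two-term $-C_6/r^6 - C_8/r^8$ series with
rational Becke–Johnson damping, $f_0 = a_1\sqrt{C_8/C_6} + a_2$, finite at
contact. The default parameters are the refit for a range-separated hybrid
functional with a DZVP-quality basis: $s_8 = 0.9220$, $a_1 = 0.3419$,
$a_2 = 5.2955$ bohr, with $s_6$ fixed at 1. Coefficients come from a static
per-pair table (TSV; a compact 10-element table ships for tests). The
coordination-number interpolation of the full D3 machinery is deliberately
out of scope — scoring with a production engine sources its own dispersion —
so the built-in table is test plumbing, not reference data.

The synthetic generator (`make_toy_pocket()`, `make_toy_series()`) emulates
the *statistical shape* of a real benchmark: a small helical pocket with
ionizable residues (planted net charge, checked exactly), structural waters
and a divalent cation; ligand series spanning rotatable-bond counts 0–25
and formal charges −1 to +2 (the envelope of the real dataset the package
targets); a fraction of complexes with alternative conformers, with
modeled-not-crystal provenance, and with planted protonation changes.
"Experimental" affinities are generated as a linear map of the actual test
backend score plus Gaussian noise, then back-converted to $K_d$/$K_i$/IC50.
The default slope (0.02) compresses the toy score spread into a realistic
affinity window — pKi ranges of a few log units, as in experimental series —
so every generated affinity is a representable concentration; correlations
are invariant to this scale.
With the noise SD derived from a target $\rho^2$ via
$\rho^2 = \mathrm{var(signal)}/(\mathrm{var(signal)} + \sigma^2)$, the
evaluated per-target $R^2$ has a known analytic expectation, which the test
suite and the acceptance script check at 10 targets × 500 ligands (3
standard errors per target, ±0.02 on the ten-target mean; at $n = 500$ one
sampling SD of $R^2$ near $\rho^2 = 0.69$ is ≈ 0.023, so a ±0.02 band is
only meaningful for the aggregate). What passing these tests shows is that
the pipeline measures correlation without bias at realistic sample sizes —
not that the toy energetics resemble real protein–ligand physics: the
generator does not emulate conformational sampling, pose errors, activity
cliffs, or correlated assay noise.

All generators are pure functions of (seed, config), pinned to one named
RNG (Mersenne-Twister with inversion sampling) and restoring the caller's
RNG state, so fixtures are bit-reproducible across runs and platforms.

## Numerical choices

* Units: kcal/mol and Å at every interface; Hartree/bohr only inside the
  dispersion kernel (1 Ha = 627.509 kcal/mol, 1 Å = 1.8897259886 bohr).
* Atom indexing is 1-based throughout (R convention); PDB serials are
  preserved for I/O only.
* Altloc policy: keep blank and "A" records by default; exceptions are
  configuration, not code.
* Element inference: PDB columns 77–78, falling back to the leading letters
  of the atom name; failure is an error, never a silent guess.
* Bond perception: distance below 1.3 × covalent-radius sum; a hydrogen
  bonds only to its nearest heavy atom (or nearest atom if no heavy
  neighbour is in range). Ring membership is bridge detection on the bond
  graph.
* Relaxation: L-BFGS-B over free atoms, converged when the largest
  per-atom gradient norm is ≤ 0.1 kcal/mol/Å (default), max 2000 steps,
  deterministic; frozen atoms are returned bit-identical. A system already
  at the tolerance returns unchanged. Non-convergence is an error, never a
  silent partial result.
* Conformer selection minimises the complex total (gas + solvation) energy;
  ties break to the first conformer in input order. Scoring a batch caches
  backend evaluations keyed by a hash of geometry, charges and settings, so
  re-runs are free.
* The engine input renderer is bit-stable and adds the linear-scaling
  keyword above 300 atoms (configurable); the solvated template uses
  ε = 78.4 by default.
* Degenerate inputs error early with the offending entity named: empty
  ligand lists, selections referencing absent residues, superpositions of
  fewer than 3 or collinear points, unknown elements or residue charges,
  non-positive affinities.

## Problem sizes

The shipped tests run the statistical recovery study at 10 targets × 500
ligands on pockets of ~60–70 atoms with ligands of 3–28 heavy atoms —
sizes chosen so the full suite exercises every code path, including the
$n=500$ recovery conditions, in a few minutes on one core. The same
generator scales to larger pockets and series by configuration.

## Known limitations

* No electronic structure: the backend contract is the boundary. The test
  backend's numbers are internally consistent but not physical.
* No pose generation, docking, pKa prediction, protonation-state
  assignment, missing-atom reconstruction or crystallographic symmetry
  handling; inputs are assumed prepared.
* The dispersion coefficient table is static (no coordination-number
  dependence).
* Water retention is manual whitelisting by design.
* The score ranks ligands within a target; absolute binding free energies
  are out of scope.
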