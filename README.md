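# plscore

End-point protein–ligand binding-affinity scoring on truncated, capped
active-site models, in R.

## The problem

Structure-based drug design needs to rank a series of ligands of one
protein by binding affinity, from single representative structures of the
complexes — without the configurational sampling of full free-energy
methods. `plscore` implements that end-point workflow as a reusable
toolkit: it reads protein (PDB) and ligand (Tripos Mol2) structures, builds
a truncated active-site model around the union of overlaid ligands with
neutral peptide caps and explicit charge bookkeeping, and assembles a
five-term binding score

```
score = ΔE_int + ΔΔG_solv + ΔG_conf(L) + ΔG_H+ − TΔS
```

— gas-phase interaction energy, desolvation penalty, ligand strain, a
Henderson–Hasselbalch-weighted proton-transfer correction (applied only
when the ligand changes protonation upon binding), and a rotatable-bond
entropy penalty. More negative is better; the score ranks ligands and does
not claim absolute binding free energies.

Energies flow through a pluggable backend contract. The package ships a
self-contained classical test backend (Lennard-Jones + Coulomb + harmonic
bonds, with a smooth Born-like solvation model and analytic gradients) so
the whole pipeline runs with no external software, a Becke–Johnson-damped
pairwise dispersion term (refit parameters s8 = 0.9220, a1 = 0.3419,
a2 = 5.2955), and a text interface for external semiempirical engines
(MOPAC-style input rendering and heat-of-formation log parsing). Benchmark
evaluation converts Kd/Ki/IC50 (IC50/2) to free energies and reports the
per-target squared Pearson correlation with the unweighted mean ± SD and
minimum over targets. A deterministic synthetic-fixture generator produces
toy pockets and ligand series with planted, analytically known
correlations.

Who is it for: method developers who need a transparent, fully testable
end-point scoring scaffold, and anyone wanting the pocket-construction,
thermodynamic bookkeeping and benchmark statistics of that workflow
without the quantum-chemistry stack.

## Worked example

Generate a small two-target synthetic benchmark (25 ligands each), score
every complex with the test backend, and evaluate the correlation:

```r
library(plscore)

cfg    <- fixture_config(seed = 42, n_ligands = 25, n_targets = 2)
bench  <- make_toy_benchmark(cfg)
report <- evaluate_benchmark(bench$scores, bench$manifest)
report
#> <benchmark_report> 2 target(s): mean R2 = 0.615 +/- 0.002, min = 0.612 (T02)
#> # A tibble: 2 x 3
#>   target     n    r2
#>   <chr>  <int> <dbl>
#> 1 T01       25 0.617
#> 2 T02       25 0.612

head(bench$scores[, 1:7], 3)
#> # A tibble: 3 x 7
#>   id       de_int ddg_solv dg_conf dg_hplus tds_penalty total
#>   <chr>     <dbl>    <dbl>   <dbl>    <dbl>       <dbl> <dbl>
#> 1 T01-L001  -43.9    11.0     86.4        0          10  63.5
#> 2 T01-L002   33.3     9.72    88.8        0          15 147.
#> 3 T01-L003  -31.6    15.9    175.         0          24 184.
```

Each score row decomposes one complex: `de_int` is the pocket–ligand
interaction energy, `ddg_solv` the (positive) desolvation cost, `dg_conf`
the strain of the bound ligand conformation, `dg_hplus` the
proton-transfer correction (zero unless the record declares a protonation
change), `tds_penalty` one kcal/mol per rotatable bond. The report's per-
target R² lands near the generator's planted ρ² = 0.69 expectation, within
sampling error at n = 25. `tidy()`, `glance()` and `autoplot()` work on
the report; `plot_score_correlation()` shows the per-target scatter.

The same functions drive real structures: `parse_pdb()` +
`select_residues()` + `build_capped_pocket()` give the capped pocket,
`parse_mol2()` the ligands, `complex_record()` + `score_series()` the score
table, and `read_manifest()` + `evaluate_benchmark()` the report. A thin
command-line front end (`inst/cli/plscore`) exposes `score`, `evaluate`
and `fixtures` subcommands.

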