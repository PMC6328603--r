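# filterdyn

Analysis pipeline for **selectivity-filter modal gating in K⁺ channels**,
written for structural biologists and NMR spectroscopists who study how
mutations in the hydrogen-bond network behind the filter (the W67–E71–D80
triad in KcsA) reshape the filter's conformational and motional equilibrium.
Crystal structures of such mutants are nearly identical (filter backbone
RMSD < 0.25 Å), yet their gating behaviour differs drastically; the
resolution lies in quantities that average structures cannot show, and this
package computes all of them from standard inputs:

* **Chemical-shift perturbations** between channel variants, per nucleus
  (`Δδ = δ_mutant − δ_WT`) and combined amide
  (`Δδ_HN = sqrt(Δδ_H² + (α·Δδ_N)²)`, α = 0.14 by default), from NMR-STAR v3
  or TSV shift tables.
* **Relaxation-rate profiles** from R1rho/T1 decay series: per-residue
  bounded least-squares fits of `I(t) = I0·exp(−R·t)` with covariance
  standard errors, plus mutant-minus-WT difference profiles with errors
  propagated in quadrature.
* **H/D-exchange protection maps** from paired protonated/deuterated peak
  intensities, normalised to water-inaccessible reference residues
  (S69/V70) and classified exchanged/attenuated/protected, with an ordinal
  "cavity extent" summarising the buried-water cavity per variant.
* **Ensemble geometry**: backbone φ/ψ dihedrals, wrap-aware inwards/outwards
  carbonyl-state classification on ψ with populations and transition
  counts, hydrogen-bond occupancies, D80 rotamer classes (down/middle/up by
  carboxylate–indole distance), a buried-water census with exchange events,
  and Kabsch superposition/RMSD.
* **Back-calculated chemical shifts**: import of per-frame predictor output
  (or a built-in state-conditioned Gaussian surrogate), the +2.5 ppm
  carbonyl offset applied once per atom class, per-state histograms, and
  predicted CSPs, which for a two-state filter reduce to
  `Δδ_pred = Δp_in · (μ_in − μ_out)`.
* **Seeded synthetic generators** with planted ground truth for every input
  stream, and a config-driven `run_pipeline()` that orchestrates all stages
  into one reproducible report.

## Worked example

Compare a triad mutant against the wild type using the bundled *synthetic*
shift tables (stand-ins that encode published perturbation values on an
invented baseline — see `vignettes/filter-dynamics-methods.Rmd`):

```r
library(filterdyn)

wt   <- read_shift_table(system.file("extdata", "synthetic_shifts_WT.str",
                                     package = "filterdyn"), "nmrstar", "WT")
e71a <- read_shift_table(system.file("extdata", "synthetic_shifts_E71A.str",
                                     package = "filterdyn"), "nmrstar", "E71A")

co <- per_nucleus_csp(wt, e71a, "C")     # carbonyl-carbon CSPs
co$value[co$resno == 76]
#> [1] 0.94
rank_csp(combined_hn_csp(wt, e71a), 3)   # strongest amide perturbations
#>   key resno     value
#> 1  80    80 0.6060825
#> 2  67    67 0.5482664
#> 3  78    78 0.4891462
```

The +0.94 ppm V76 carbonyl CSP is the signature of an inwards-stabilised
filter carbonyl, and the three largest combined amide CSPs fall on the
D80/W67/Y78 triad residues whose hydrogen bonding the mutation rewires.

Relaxation fitting and state populations work the same way on synthetic
data with planted truth:

```r
g <- gen_decay_set(noise_sd = 0.02, seed = 42)   # planted rates, 2% noise
fit_rate_profile(g$set)
#> <rate_profile> R1rho - 5 residues, rates per ms
#>   residue        rate           se        I0 n flag
#> 1     V76 0.015231764 0.0005467126 1.0005559 6 <NA>
#> 2     G77 0.009908288 0.0006424836 0.9753232 6 <NA>
#> 3     Y78 0.019017652 0.0008699712 0.9913668 6 <NA>
#> 4     G79 0.029956705 0.0007288806 1.0138614 6 <NA>
#> 5     D80 0.017935030 0.0009078018 1.0050453 6 <NA>

dih  <- gen_two_state_dihedrals(n_frames = 10000, p_in = 0.6, seed = 42)
pops <- state_populations(classify_states(dih$dihedrals, dih$windows))
pops$populations
#>   resno p_inwards p_outwards p_other n_frames
#> 1    76    0.5999        0.4   1e-04    10000
```

Every fitted rate sits within its standard error of the planted value, and
the recovered inwards population (0.5999) matches the planted 60:40
equilibrium. A full synthetic study runs with one call:

```r
report <- run_pipeline(list(seed = 7), outdir = "results/run1")
report            # per-stage status, output tables, provenance hashes
```

A thin command-line wrapper lives at `inst/scripts/filterdyn-cli.R`
(`validate` and `run` subcommands; exit codes 0 ok / 1 stage failure /
2 config error).

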