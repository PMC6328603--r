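---
title: "Methods: quantifying selectivity-filter dynamics with filterdyn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying selectivity-filter dynamics with filterdyn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(filterdyn)
```

## The scientific problem

Potassium channels switch spontaneously between distinct activity patterns
(modal gating) without any change in conditions. In KcsA, substitutions at
E71 — the centre of the W67–E71–D80 hydrogen-bond triad behind the
selectivity filter — lock the channel into different gating modes, yet
crystal structures of these mutants show essentially unchanged filters
(backbone RMSD below 0.25 Å). `filterdyn` implements the analysis chain
needed to resolve this apparent contradiction from membrane-embedded NMR and
structural-ensemble data: the mutations shift the *statistical weighting* of
pre-existing filter states and the *dynamics* around them, which chemical
shifts, relaxation rates, H/D exchange and ensemble geometry can quantify
even when average structures cannot.

Residue numbering throughout follows the crystal-structure convention of the
channel: filter T75–G79, hydrogen-bond triad W67/E71/D80, reference residues
S69/V70.

## Chemical-shift perturbations (CSP)

For a nucleus `a` of residue `r` present in two variants, the per-nucleus
CSP is the signed difference

$$\Delta\delta_{r,a} = \delta^{query}_{r,a} - \delta^{ref}_{r,a}
\quad \text{(mutant minus wild type)},$$

and the combined amide CSP merges proton and nitrogen differences as

$$\Delta\delta_{HN} = \sqrt{\Delta\delta_H^2 + (\alpha\,\Delta\delta_N)^2}.$$

The nitrogen weighting `alpha` defaults to 0.14, the customary amide scaling
reflecting the roughly sevenfold wider nitrogen shift dispersion; because
conventions differ between laboratories it is a configuration parameter, and
absolute combined values should not be compared across different `alpha`
choices (per-nucleus CSPs are convention-free). Residues missing either
nucleus are excluded and logged, never zero-filled: a zero is a legitimate
measurement, absence is not. Side-chain NH pairs such as the tryptophan
indole (Nε1/Hε1) are tracked as separate keys because their perturbations
carry independent information about the triad.

## Relaxation-rate fitting

Rotating-frame (R1rho) and longitudinal (T1) series are fitted per residue
with the two-parameter mono-exponential

$$I(t) = I_0\, e^{-R t}, \qquad R \ge 0,$$

without a baseline offset: decays here are sampled to a small fraction of
the initial intensity, where an offset is unidentifiable from five or six
points and mostly absorbs noise. Fitting is bounded Levenberg–Marquardt with
a deterministic initialisation (I0 from the first intensity, R from a
log-linear regression over the positive intensities), so identical inputs
give bit-identical fits. Rates are reported in the reciprocal of the input
delay unit, with the unit echoed in output headers; no unit conversion is
attempted. Spin-lock off-resonance corrections are not applied: fitted rates
are observed decay rates.

The standard error of the rate comes from the fit's covariance matrix
(a residual-resampling Monte-Carlo alternative sits behind
`se_method = "montecarlo"`). One calibration fact matters for interpreting
error bars at these sample sizes: with six delays and two parameters the
standardised error $(\hat R - R)/\mathrm{SE}$ follows a t-distribution with
4 degrees of freedom, so a ±2 SE interval covers the true rate with
probability $2\,P(t_4 \le 2) - 1 \approx 88\%$, not the Gaussian 95%. The
package reports the plain covariance SE — the field's convention — rather
than inflating it; users who need nominal coverage at few delays should use
t-quantiles.

Mutant-vs-reference difference profiles subtract shared residues and
propagate errors in quadrature, $\sqrt{se_q^2 + se_r^2}$.

## H/D-exchange protection

Paired peak intensities from protonated and deuterated buffers are each
normalised so that the mean over water-inaccessible reference residues
(default S69 and V70, which face the membrane and do not exchange) is 1;
the per-residue ratio deuterated/protonated then measures retained amide
protonation, with attenuation reported as $100(\text{ratio}-1)$ percent.
Classification uses half-open bins: ratio < `t_low` is *exchanged*,
below `t_high` *attenuated*, otherwise *protected*. The defaults
(`t_low = 0.15`, `t_high = 0.85`) separate peaks that vanish, peaks
attenuated by tens of percent, and peaks showing no sign of exchange; they
are configuration-exposed because they are operational cut-offs, not
physical constants. A deuterated peak that is absent is coded as complete
exchange only when the protonated peak exceeds a noise floor (default 0.05
normalised units); otherwise the residue is excluded as insufficient
sensitivity rather than misread as exchange. The cavity summary counts, per
variant, how many cavity-lining residues (default G77, Y78, G79, L81) are
not protected — an ordinal "cavity extent" that grows as the buried-water
cavity widens.

## Conformational-state analysis

A peptide-plane (carbonyl) flip registers chiefly in the ψ dihedral of the
residue contributing the carbonyl, so classification is one-dimensional by
design: a residue's frame is *inwards* when ψ lies within a wrap-aware
window of half-width 60° around the inwards centre (for real ensembles, the
conductive crystal-structure ψ of that residue), *outwards* within the
antipodal window, and *other* elsewhere. Half-widths below 90° guarantee
disjoint windows; overlaps are rejected at construction time. Whether φ of
the following residue should participate in the classification is a genuine
design question; the one-dimensional ψ rule was chosen because the flip is
a two-state event on ψ and a second dimension adds boundary cases without
changing the populations at realistic angular noise.

Populations are fractions of frames per label (chains pooled by default,
matching monomer pooling of back-calculation snapshots), and transitions
count label changes between consecutive frames. Hydrogen bonds use standard
geometric criteria — heavy-atom distance ≤ 3.5 Å, D–H···A angle ≥ 120° when
hydrogens are present, distance-only otherwise. The D80 rotamer is defined
functionally by the distance from the carboxylate oxygens to W67 Nε1:
*down* ≤ 3.5 Å (hydrogen-bonding competent), *up* ≥ 6.5 Å, *middle*
between; the ladder is declared rather than inferred because only the down
state has an operational definition (it enables the 67–80 bond). The
buried-water census counts water oxygens within 5.0 Å of the centroid of
the 67/71/80 side chains per subunit — a radius that encloses the
crystallographic buried-water site — and an exchange event is any change in
the identity set of in-cavity waters between consecutive frames (each entry
and each exit counts once). Superposition is least-squares (Kabsch, SVD
with reflection guard); all geometric outputs are invariant under global
rigid motion, which the test suite verifies directly.

Angles are degrees on (−180, 180], distances Å, times ns. Snapshot
extraction retains frames on the stride grid, includes t = 0 only when the
trajectory marks it as a production frame, and splits each retained frame
into one structure per chain: a 1 μs tetramer sampled every 10 ns yields
100 × 4 = 400 monomer snapshots.

## Back-calculated shifts and predicted CSPs

External per-frame shift predictions are imported from tables; the package
deliberately manages no predictor subprocess. Predicted carbonyl shifts
carry a systematic offset relative to experiment; the calibrated correction
(+2.5 ppm for backbone carbonyls) is applied identically to every variant,
so between-variant differences are unaffected — the offset bookkeeping
refuses double application. For testing without an external predictor, a
surrogate emits shifts from state-conditioned Gaussians. Its default
calibration — inwards minus outwards separation of +2.5 ppm for backbone C
and +2.0 ppm for Cα, emission sd 0.5 ppm — sits mid-range of back-calculated
separations for filter carbonyl flips and makes the two-state arithmetic
transparent: the ensemble mean is the population-weighted state mean, and a
predicted CSP between two two-state ensembles with shared state means
reduces to

$$\Delta\delta^{pred} = \Delta p_{in}\,(\mu_{in} - \mu_{out}),$$

so a variant that stabilises the inwards carbonyl state produces a positive
carbonyl CSP and an outwards-enhanced variant a negative one.

## What the synthetic generators emulate — and what they do not

Each input stream has a seeded generator with planted truth: shift tables
with planted CSPs plus Gaussian noise; mono-exponential decays on the
0/5/10/20/40/80 ms grid (0–60 ms for a faster-relaxing variant; 0/2/4/10/20 s
for T1); two-state Markov ψ series with stationary inwards probability 0.60
by default (the 60:40 inwards:outwards equilibrium of the conductive
wild-type filter), switching propensity 0.25 and von Mises angular noise of
concentration κ = 20 (circular sd ≈ 13°, comfortably inside the ±60°
windows); a toy trajectory with scripted hydrogen-bond breaking and water
exchange; intensity pairs with planted protection classes (band centres
0.95/0.45/0.02); and an idealised filter tetramer whose "variant" copies
receive 0.08 Å per-coordinate noise plus a random rigid motion, emulating
independently solved, essentially identical filters. One integer seed
drives everything through a counter-based splitting rule, so sub-streams
are independent and runs are bit-reproducible.

These generators validate the *estimators*, not the physics: they contain
no force field, no lipids, no correlated multi-residue motions, no
spectral overlap or peak-picking ambiguity, and their noise is exactly
Gaussian/von Mises. Passing tests therefore demonstrate that the pipeline
recovers what was planted under its stated noise models — they say nothing
about whether a particular real channel obeys those models. The bundled
NMR-STAR files are likewise synthetic stand-ins whose variant-minus-WT
differences encode published perturbation values on an invented baseline;
they exercise the reader and the CSP arithmetic, not agreement with any
deposition.

## Problem sizes and numerical choices

The shipped tests and the acceptance script use 10,000-frame state series
(50,000 for the stationarity check), 200-replicate SE-calibration runs,
five-residue decay sets and 80-atom filter structures — sizes chosen so the
complete suite runs in well under a minute while keeping Monte-Carlo noise
far from every tolerance. Wrap-aware angular arithmetic is used everywhere
(differences mapped to (−180, 180]); window membership is inclusive at the
boundary; ranking ties break by ascending residue number; degenerate decay
inputs (all-zero series) are errors, constant series fit exactly to rate 0,
and a rate of 0 in a T1 profile is reported as an unbounded relaxation time
flag rather than a number.

## Known limitations

* Combined-CSP magnitudes depend on the `alpha` convention; only
  per-nucleus CSPs are convention-free quantities.
* Covariance SEs at five or six delays undercover at ±2 SE (t, not
  Gaussian, calibration — see above).
* The H/D analysis is a single-endpoint protection map, not exchange
  kinetics; protection factors are out of scope.
* The inwards/outwards windows are declared geometry, not learned
  boundaries; ensembles whose flipped states are not antipodal in ψ need
  custom windows.
* The surrogate predictor is a calibration device; quantitative
  reproduction of real back-calculated shift distributions requires an
  external predictor run over real trajectory snapshots, imported via
  `load_frame_shifts()`.
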