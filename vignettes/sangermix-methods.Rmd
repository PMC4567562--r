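---
title: "Deconvolving mixed-template Sanger 16S chromatograms: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deconvolving mixed-template Sanger 16S chromatograms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sangermix)
```

## The measurement and its model

Sanger sequencing of a *mixed* 16S amplicon pool produces, at every
aligned position, a four-channel signal in which each community member
contributes its own base in proportion to its template abundance. One
sample is therefore an `L x 4` non-negative matrix (`spectrum_matrix`),
and a study of `N` samples stacks into `X` (`N x 4L`, position-major with
channels contiguous). The community model is the bilinear factorization

$$X \approx C\,S, \qquad C \ge 0,\; S \ge 0,$$

with `K` components: `S` holds the per-component chromatogram spectra and
`C` the per-sample scores. Two modelling commitments matter:

* **No closure.** Rows of `C` are not constrained to sum to one. A noisy
  or weak chromatogram simply gets smaller scores; nothing forces the
  model to re-inflate a sample's composition to 100%. Score axes are made
  comparable instead by a scale convention (below).
* **Indicator peak shape.** The generative model treats each position as
  an indicator of the contributing bases — no inter-position peak
  broadening. The analysis operates on aligned per-position signals, so
  broadening would add realism without changing the inference contract.

## Alignment

Amplicons primed at a fixed site differ between samples by small integer
shifts only, so `align_spectra()` uses integer-offset alignment: every
sample is cross-correlated against the *consensus* (per-position mean)
profile over a configurable lag window (default ±25), the frame is pinned
to the median-length sample, and all samples are cropped to the common
overlap. Ties in the correlation resolve to the smallest absolute lag, so
aligning an already-aligned set is the identity.

Two design points were forced by the data class rather than chosen
freely. The correlation must be *channel-resolved*: a mixed
chromatogram's per-position total is nearly constant (each position sums
to about scale × total abundance), so totals carry almost no positional
information and matching them degenerates into matching noise. And the
reference must be the *consensus* rather than any single anchor sample:
two samples dominated by different community members share channel
structure only where their sequences happen to coincide, while the
consensus contains every component and correlates sharply with each
sample at the true lag. A dynamic-programming aligner could slot in
behind the same interface; it is not needed for indel-free amplicons.

## Fitting: alternating exact non-negative least squares

`mcr_als()` alternates two exact non-negative least-squares problems:
rows of `C` given `S`, then columns of `S` given `C`. Exactness per
subproblem (rather than clip-after-solve) is what guarantees the
monotonicity invariant: the recorded squared-residual sequence is
non-increasing, which the test suite asserts on every run.

Numerical choices:

* **NNLS by support enumeration.** With the small `K` this analysis uses,
  each column's exact solution is found by enumerating candidate supports
  and verifying the KKT conditions (feasibility on the support,
  non-negative gradient off it), vectorized across all columns at once;
  larger supports are tried first because most columns are interior.
  Columns that no enumerated support accepts — singular subsystems,
  razor-edge ties — fall back to the Lawson–Hanson active-set solver
  (`pracma::lsqnonneg`), which is also used outright for `K > 8`. The two
  routes agree to machine precision on random problems (tested).
* **Monotone extrapolation.** Plain ALS converges linearly and can crawl
  once the active sets are settled. After each sweep an extrapolated
  candidate along the last accepted step is evaluated and accepted *only
  if it strictly lowers the objective*, preserving the descent guarantee
  while cutting the iteration count by an order of magnitude on
  noiseless benchmarks.
* **Stopping.** Relative objective decrease below `tol` (default `1e-8`),
  an absolute floor at `1e-24` of the total sum of squares, or `max_iter`
  (default 500). Exactness benchmarks (noiseless data, residual fraction
  below `1e-10`) need the solver run to numerical stall (`tol = 1e-16`,
  more iterations); the routine analysis tolerance is deliberately looser.
* **Scale convention.** `X` is pre-divided by one global factor (the
  grand mean per-position total intensity), and after convergence each
  component spectrum is rescaled to unit mean per-position total
  intensity, the inverse factor absorbed into its score column. Scores
  are then dimensionless and comparable across samples and runs: a pure
  sample of one component at the dataset's typical signal level scores
  about 1. A *per-sample* normalization was rejected because it would
  reimpose closure-like behaviour and destroy the interpretation of
  scores as absolute contributions (a rank-one dataset must recover its
  per-sample scale ratios in `C`, which the tests assert).
* **Initialization.** Purest-sample seeding: the first pick is the
  largest-norm sample, each further pick the sample least similar (in
  maximal cosine similarity) to those already picked. Deterministic given
  the input order; the seed argument is reserved for optional random
  restarts.
* **Choosing K.** `estimate_k()` returns the smallest `K` whose top
  singular values explain a variance fraction (default 0.95) of the
  uncentred stacked matrix. In practice `K` is study configuration — four
  components for the seasonal dataset, five for the stable-environment
  one — and the estimator is a check, not an oracle.

## Quality filtering

Sequences the model cannot explain are removed by their *residual
fraction* `||x_n − c_n S||² / ||x_n||²` (threshold default 0.30, exposed
in configuration). `mcr_fit_filtered()` wraps the robust loop: triage by
the rank-`K` SVD-subspace residual, fit on the kept samples, re-score
*all* samples against the fitted spectra, re-partition, and repeat until
stable. Two failure modes of contaminated fits are handled explicitly:

* unstructured noise inflates a bad sample's own residual (caught by the
  threshold); and
* a single high-energy noise chromatogram can capture a whole component
  for itself, making its residual deceptively small. Such *private
  components* — one sample carrying more than half a component's total
  score mass — mark their owner as low quality outright, since a real
  community component is expressed across many samples.

The SVD triage exists because shared community structure concentrates in
the top singular directions while each bad chromatogram's noise is its
own direction; screening there prevents noise samples from distorting
the first factorization. On the study-scale synthetic design (180 bees,
15–20% noise-inflated at ×10) the loop recovers exactly the flagged
samples with no false keeps or removals. At much smaller problem sizes
(tens of samples, short amplicons, heavy contamination) the good and bad
residual bands genuinely overlap and no threshold separates them; the
filter is honest about this regime only in the sense that it degrades
visibly rather than silently.

## Base-calling and taxonomy

Components are base-called position-wise by the argmax channel of `S`,
with `N` whenever the top two channels are within a relative tie
tolerance (`1e-9`) or the position is empty — ties never resolve by
floating-point accident. Taxonomy is nearest-reference matching against
a local panel: percent identity over the call's non-`N` positions,
best hit reported, hits under a floor (default 80%) labelled
`unassigned`. Remote database search is deliberately out of scope; the
panel is an input.

## Nucleotide-mixing α-diversity

`alpha_diversity()` works on the *raw* aligned spectrum, independent of
the factorization: per position the channel proportions `p_b` give a
Gini–Simpson index `1 − Σ p_b²`, and the sample's α is the mean over
positions with usable signal. With four channels the index is bounded by
0.75 (uniform signal); a pure single-template chromatogram scores 0; a
50/50 mixture of two everywhere-different templates scores 0.5. The
index is scale invariant and strictly increasing as a second template is
mixed in up to 50%. "Usable signal" means a per-position total at or
above a floor, default 5% of the sample's own mean per-position total —
without it, empty positions would read as maximally mixed noise and
inflate α. The measure is internal to this assay: its numeric scale
depends on how templates differ across positions, so values are
comparable between samples profiled the same way but not with OTU-based
diversity indices.

## qPCR load and competition

Relative bacterial load uses the efficiency-weighted ΔCT with the host's
single-copy vitellogenin gene as denominator:

$$\log_{10}\text{ratio} = \log_{10}(E_\text{bee})\,CT_\text{bee} -
\log_{10}(E_\text{bact})\,CT_\text{bact}.$$

Logs are base 10 throughout — the formula as printed in qPCR practice
does not name a base, and base 10 is the field convention for "log
ratio" axes; the choice affects only the scale, never the ordering.
Efficiencies are *inputs* (per-assay or per-reaction estimates from the
fluorescence curves); estimating them is out of scope. The competition
experiment summarizes each replicate as the efficiency-corrected
alone:together quantity ratio `E^(CT_together − CT_alone)` (so 1 means no
suppression), then mean ± SEM with a two-sided one-sample t-test of the
log ratios against 0.

## Statistics layer

Per-bee values within each month are the unit of analysis (configurable;
"added and averaged" designs can also be run on monthly means). The
battery is classical: sample SD (`n − 1`), SEM = SD/√n; one-way
fixed-effects ANOVA for the whole trend (degenerate zero-within-variance
inputs are flagged, not silently computed); Tukey HSD on the pooled
within-group mean square with the Tukey–Kramer standard error for
unbalanced groups, reported either for all pairs or adjacent months
only; and pooled-variance Student's t-tests (Welch behind a flag) with
Bonferroni handled by *threshold division* — each test is significant
iff its raw p-value is below α divided by the number of tests, and raw
p-values are reported unchanged. Studentized-range probabilities come
from `ptukey`; the implementation is cross-checked against
`stats::TukeyHSD` and brute-force sums-of-squares oracles to `1e-6` in
the tests, and null ANOVA p-values are verified uniform by a
Kolmogorov–Smirnov check over 2,000 simulated null datasets.

## What the generator emulates — and what it does not

`seasonal_design()` encodes the study conditions: six months (May–Oct),
30 bees per month from three colonies, four components whose monthly
mean trajectories qualitatively follow the observed dynamics (a dominant
member declining through the season; a late-summer peak; an early-autumn
peak; a rare member rising roughly eight-fold into the final month), row
sums below 1 so the score axis is open. Per-bee proportions are drawn by
a Dirichlet perturbation around the monthly mean with an extra residual
category absorbing the closure deficit (concentration default 100,
within-month SD ≈ 0.05 on a component near 0.3 — the study reports no
numeric within-month variance, so this default is chosen for
testability, not fidelity). Per-sample total signal is log-normal (SD
0.1); channel noise is Gaussian truncated at zero (default SD 0.1, i.e.
10% of a pure-template peak) so intensities stay non-negative and the
ALS non-negativity assumption stays honest; 15% of chromatograms
(matching the overall attrition across the study's monthly pass rates)
are rendered with noise inflated ×10. `stable_design()` is the
two-time-point winter counterpart: five components, constant
proportions, 24 and 30 bees.

Deliberately *not* emulated: raw electropherogram traces (AB1/SCF), peak
broadening and mobility artefacts, indels, Phred-style quality values,
colony demography and age structure, and month-specific attrition rates.
Passing tests therefore demonstrate the inference machinery — recovery,
filtering, calibration of the statistics — under the stated noise model,
not robustness to every artefact of real trace files.

Design-level properties are part of the test contract: with the seasonal
preset the one-way ANOVA on the declining component reaches `p < 0.01`
in ≥ 90 of 100 seeded replicates, and with the stable preset
Bonferroni-corrected t-tests find no component difference in ≥ 95 of
100 — the second figure sits at its expected value (0.99⁵ ≈ 0.951 per
run), so it is a calibration check, not a safety margin.

## Problem sizes and determinism

Module tests run on reduced designs (60–150 positions, 10–20 bees per
month) chosen inside the regime where quality bands separate; the
acceptance-style tests and `scripts/acceptance.R` use the full design
scale (450 positions, 180 bees). Every stochastic entry point takes an
explicit seed and restores the caller's RNG state; identical seeds give
bit-identical outputs, which the pipeline manifest verifies by checksum.

## Known limitations

* Integer-shift alignment assumes indel-free, primer-anchored amplicons.
* The factorization's component identifiability rests on sequence
  divergence between community members; near-identical templates merge
  into one component.
* The quality filter has a breakdown regime (small N, short L, heavy
  contamination) where residual bands overlap.
* α-diversity values are assay-internal and not comparable across
  methods.
* Whether to fit months jointly or separately is configuration; the
  default fits jointly across the dataset.
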