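# sangermix

Community profiling from **mixed-template Sanger sequencing** of 16S rRNA
amplicons. When a single Sanger reaction is run on a mixed bacterial
community, every position of the chromatogram carries a superposition of
the members' bases. `sangermix` turns a collection of such chromatograms —
one per biological sample — into relative bacterial abundances, component
sequences with taxonomy, a per-sample diversity index, and the seasonal
statistics used to describe community dynamics, with a honey-bee
midgut/pylorus monitoring design as the motivating application.

## The model

Each sample's aligned chromatogram is an `L x 4` matrix of non-negative
channel intensities (A, C, G, T per position). Stacked over `N` samples as
rows of `X` (`N x 4L`), the community model is bilinear:

```
X ≈ C S,    C ≥ 0 (N x K scores),    S ≥ 0 (K x 4L component spectra)
```

fitted by **multivariate curve resolution with alternating least squares
(MCR-ALS)**: exact non-negative least squares for `C` given `S`, then for
`S` given `C`, iterated until the squared residual stalls. There is *no
closure constraint* — rows of `C` are not forced to sum to 1, so residual
noise lowers a sample's scores instead of being redistributed across
components. Components are base-called position-wise (argmax channel, `N`
on ties) and matched to a reference panel by percent identity.
Low-quality chromatograms are removed by the share of their signal energy
the model cannot explain (residual fraction, default threshold 0.30).

Around the factorization the package provides:

* a **nucleotide-mixing α-diversity**: the position-averaged Gini–Simpson
  index `mean_i (1 − Σ_b p_ib²)` over channel proportions, bounded by
  0.75 with four channels, computed from the raw spectra without any
  decomposition;
* **relative bacterial load** from paired 16S / vitellogenin qPCR:
  `log10(E_bee)·CT_bee − log10(E_bact)·CT_bact`, with per-assay
  amplification efficiencies as inputs, plus the competition-experiment
  ratio `E^(CT_together − CT_alone)`;
* the **statistics layer**: per-month mean/SD/SEM, one-way ANOVA across
  months, Tukey HSD between adjacent months, and two-sided Student's
  t-tests with Bonferroni threshold division;
* a **synthetic-data generator** reproducing the sampling design (six
  months × 30 bees, month-specific mixing trajectories, per-sample signal
  scale, truncated Gaussian channel noise, a fraction of noise-inflated
  chromatograms), so the whole pipeline is testable end to end.

## Worked example

```r
library(sangermix)

design <- seasonal_design(seed = 1)                 # 6 months x 30 bees
panel  <- make_reference_panel(4, L = 450, min_divergence = 0.1, seed = 2,
                               names = colnames(design$proportions))
sim     <- simulate_dataset(panel, design)
aligned <- align_spectra(sim$spectra)
fit     <- mcr_fit_filtered(aligned, K = 4)          # fit + quality filter

match_taxonomy(basecall_components(fit$model), panel)
#>   component          best_match identity
#> 1         1 Gilliamella_apicola      100
#> 2         2  Snodgrassella_alvi      100
#> 3         3  Enterobacteriaceae      100
#> 4         4  Frischella_perrara      100

scores <- merge(data.frame(sample_id = fit$model$sample_ids,
                           score = fit$model$C[, 1]),
                sim$meta[, c("sample_id", "month")])
g <- group_by_month(scores, "score")
summarize_groups(g)
#>   group  n   mean     sd     sem singleton
#> 1   May 27 1.0004 0.1212 0.02332     FALSE
#> 2   Jun 24 0.8532 0.1184 0.02418     FALSE
#> 3   Jul 22 0.6913 0.0883 0.01882     FALSE
#> 4   Aug 26 0.3062 0.0580 0.01138     FALSE
#> 5   Sep 28 0.1780 0.0603 0.01139     FALSE
#> 6   Oct 26 0.0513 0.0366 0.00718     FALSE

one_way_anova(g)$p          # 2.59e-92: the decline is a real trend
tukey_hsd(g, adjacent_only = TRUE)[, c("group1", "group2", "q", "p", "sig01")]
#>   group1 group2     q        p sig01
#> 1    May    Jun  8.64 1.26e-07  TRUE
#> 2    Jun    Jul  9.03 3.11e-08  TRUE
#> 3    Jul    Aug 21.89 3.00e-15  TRUE
#> 4    Aug    Sep  7.75 2.63e-06  TRUE
#> 5    Sep    Oct  7.66 3.55e-06  TRUE
```

The first component is recovered with its exact sequence, its per-bee
score declines from dominance (≈1.0 on the dimensionless score axis) in
May to near absence in October, and every adjacent-month drop is
significant at the 1% family-wise level. The quality filter kept 153 of
180 bees — exactly the bees simulated without noise inflation.

The same analysis is available from a shell:

```sh
Rscript inst/scripts/sangermix-cli.R run --simulate --K 4 --seed 5 --out out/
```

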