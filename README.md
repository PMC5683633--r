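# lymphomiR

Discovery of circulating miRNA biomarkers from plasma small-RNA sequencing
counts, built around the design of lymphoma-surveillance cohorts: healthy
controls versus DLBCL and Hodgkin-lymphoma patients, with optional survival
follow-up. The package is aimed at analysts who have a miRNA-by-sample count
matrix plus a sample sheet and want a tested, seeded, end-to-end pipeline —
and at methodologists who want every stage exercisable on synthetic cohorts
with known ground truth.

## What it computes

* **Detection filter**: keep miRNA *i* iff `#{j : counts[i,j] ≥ 1} / n ≥ 0.25`.
* **Differential abundance, 2-of-3 consensus**: three independent tests per
  comparison — an NB Wald test (log-link GLM at trend-shrunken dispersion
  `φ̃`, `var = μ + φ̃μ²`), an exact conditional NB test (group sum | total is
  beta-binomial `(T, n₁/φ̃, n₂/φ̃)`), and a moderated t on precision-weighted
  log-CPM with empirical-Bayes variance shrinkage
  `s̃² = (d₀s₀² + d s²)/(d₀+d)`. A miRNA is called iff ≥ 2 tests have BH
  `q ≤ 0.05` with agreeing fold-change sign.
* **Composite biomarker score**: per-feature z-scores on the comparison
  cohort, then `score_j = Σ_{i∈up} z_ij − Σ_{i∈down} z_ij`, assessed by
  midrank Mann–Whitney AUC `= P(case > control) + ½P(tie)`.
* **Nearest-centroid classification** with Welch-|t| feature filtering,
  validated by 1000 stratified random 50% splits (median misclassification
  and IQR; per-feature inclusion rates over 200 iterations retaining 80
  miRNAs), LOOCV, and a misclassification-vs-panel-size curve.
* **Survival screen**: counts thinned binomially to common depth, midranked,
  averaged over resamples; per-miRNA Cox score statistics
  `U/√V = Σ_events (x_fail − x̄_risk)/√Σ hypergeometric var` with a joint
  (time, event) permutation null, expected order-statistic Q-Q pairs and
  permutation q-values; confirmation by univariable Cox PH on
  median-dichotomized levels (Breslow ties, Newton–Raphson); Kaplan–Meier
  curves with Greenwood variance and log-scale 95% CIs.
* **Synthetic cohorts**: log-normal plasma-skewed abundances (top-10 species
  > 50% of reads), log-normal library sizes, NB counts with dispersion trend
  `φ(μ) = a0 + a1/μ`, group fold-changes injected compositionally, and
  exponential survival linked to selected miRNAs — with full ground truth
  returned for recovery testing.

## Worked example

```r
library(lymphomiR)
sim <- simulate_cohort(sim_config(seed = 42))   # 20 controls, 14 DLBCL, 11 HL
cm  <- filter_detected(sim$counts)
g   <- as.character(sim$samples$group)
keep <- g %in% c("control", "DLBCL")
sub <- cm[, keep]; g2 <- g[keep]

sf   <- size_factors_median_ratio(sub)
disp <- estimate_dispersions(sub, sf, g2)
tmm  <- norm_factors_tmm(sub)
cons <- consensus_calls(list(
  de_test_nbwald(sub, g2, sf, disp),
  de_test_nbexact(sub, g2, tmm, disp),
  de_test_modt(precision_weights(sub, tmm, groups = g2), g2)))
table(cons$direction)
#> down none   up
#>    8  147    2
```

The consensus recovers exactly the injected DLBCL structure (2 up, 8 down).
Composite scores and classifier validation on those calls:

```
up    panel (2 miRNAs): AUC = 1.000, p = 9.6e-07
down  panel (8 miRNAs): AUC = 1.000, p = 9.6e-07
all   panel (10 miRNAs): AUC = 1.000, p = 9.6e-07
MRV median misclassification: 0.0% (IQR 0.0%-0.0%)
```

(The default simulated effects, |log2FC| 1.2–2.2 at ~10⁶ reads, separate the
groups completely; real plasma cohorts of this size land nearer AUC 0.88–0.99
and ~12% misclassification.)

Survival, at the emulated cohort scale (~25 patients, ~5–6 deaths):

```
5 deaths among 25 patients
     feature     score qvalue
 miR-sim-151  2.903368      0
 miR-sim-112 -2.321811      1
 miR-sim-154 -2.134020      1
miR-sim-151 above median: HR = Inf (p = 0.010)
KM 5-year survival: 79%
true hazard-linked miRNAs: miR-sim-032, miR-sim-034, miR-sim-056
```

With five events the screen's top hit here is a chance association, not one
of the three truly linked miRNAs — a deliberate illustration that at this
cohort size the survival screen is exploratory (the permutation q-values and
Q-Q plot are the guard rails). Power tests at n = 200–300 in the test suite
show the screen and Cox stages recover injected hazards reliably.

Everything can also be run in one seeded call:

```r
bundle <- run_pipeline(pipeline_config(seed = 7, out_dir = "run1"))
bundle$summary$consensus_counts
```

or from a shell via the CLI wrapper:

```sh
Rscript -e 'quit(status = lymphomiR::cli())' all --seed 7 --out run1
```

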