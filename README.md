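# emfkit

Quantifying how land-use disturbance changes **ecosystem multifunctionality
(EMF)** — and which microbial, plant and environmental factors drive the
change. The package targets chronosequence designs such as grassland plots
sampled before a solar facility was built (`Y0`), one year after
installation (`Y1`) and six years into operation (`Y6`), with many ecosystem
functions measured per plot alongside prokaryotic, fungal and plant
communities. It is written for ecologists and microbiome researchers who
need the full analysis chain — indices, screens, attribution, causal paths —
as tested, scriptable functions rather than a one-off analysis.

## What it computes

* **EMF indices** — the averaging index
  `avgFunc = mean_f (x_f - min_f) / (max_f - min_f)` over 23 functions in
  six categories (PP, SNP, C/N/P cycling, redox), and multithreshold counts
  `MF-t% = #{f : x_f >= (t/100) * M_f}` against a top-2 reference maximum
  `M_f`, for t = 20, 40, 60, 80.
* **Annualised effect sizes** —
  `Effect = (mean(Y_i) - mean(Y_j)) / ((i - j) * mean(Y_j))` with percentile
  bootstrap CIs; installation uses (i, j) = (1, 0), running (6, 1).
* **Diversity** — richness, Faith's PD (root-inclusive branch-length sums),
  Gower-distance functional dispersion (FDis), guild richness, Bray–Curtis
  and Euclidean beta distances.
* **Taxa screens** — prevalence/count ASV filtering; indicator species
  analysis `IndVal = max_g sqrt(A_g B_g)` with permutation tests (exact
  enumeration on small designs); co-occurrence networks with
  within-module degree `Zi` and participation coefficient
  `Pi = 1 - sum_s (k_is/k_i)^2`, keystones at Zi > 2.5 or Pi > 0.62;
  abundant (> 0.1%) and rare (< 0.01%) classes.
* **Microbial activity** — metabolic quotient `qCO2 = c_min / MBC`,
  `Cmic/Corg`, and an activity composite (PC1).
* **Attribution battery** — variance partitioning on adjusted R² (exact
  inclusion–exclusion), LMG relative importance (all-orderings R²
  decomposition), partial correlations, Spearman Mantel tests,
  random-forest permutation importance.
* **Piecewise SEM** — per-node OLS path models tested by d-separation,
  combined with Fisher's `C = -2 Σ ln p` on 2k df, with direct / indirect /
  total effects by path enumeration and an installation-vs-running period
  contrast.
* **Synthetic studies** — `generate_study()` builds a complete study
  (functions, metadata, three communities with planted indicator taxa and
  co-occurrence modules, trees, traits, activity, a driver layer drawn from
  a known path model) plus a truth record, so every stage can be validated
  by parameter recovery.

## Worked example

The numbered scripts under `analysis/` run the whole workflow on the default
synthetic study and narrate what they find:

```sh
Rscript analysis/01_simulate.R     # writes results/study/
Rscript analysis/02_emf.R
Rscript analysis/04_screen.R
```

prints, among other lines:

```
Functions: 18 plots x 23 functions
prokaryote  200 taxa, 25 planted indicators
fungus      120 taxa, 25 planted indicators
avgFunc effect: installation 90.6%, running 5.1% per year
prokaryote  184/200 taxa pass filter; 13 indicators, 0 keystones, 94 abundant, 31 rare
fungus      115/120 taxa pass filter; 26 indicators, 0 keystones, 84 abundant, 11 rare
```

Reading this: the installation period raised the average multifunctionality
index by ~91% per year in this simulated study while the running period adds
only ~5% per year — the strong-pulse / weak-drift ordering the generator
plants. The screen recovers planted fungal indicators readily (26 called of
25 planted, BH-controlled), fewer prokaryotic ones (the 200-taxon table
carries a harsher multiplicity burden), and finds no network keystones: at
18 samples the BH-thresholded co-occurrence network is sparse, so hub/
connector nodes are legitimately rare. `analysis/08_report.R` runs the same
chain through the orchestrated `run_pipeline()` and writes a Markdown report
with truth-recovery scores.

Equivalent single calls in R:

```r
library(emfkit)
study <- generate_study(study_design(seed = 1))
prof  <- emf_profile(study$functions, study$category)
annual_effect_size(prof$avgFunc[7:12], prof$avgFunc[1:6], i = 1, j = 0,
                   n_boot = 2000, seed = 1)
```

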