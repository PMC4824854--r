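# calpainqsar

Quantitative structure–activity models of calpain cleavage sites.

The conventional calpains (calpain-1 and calpain-2) are Ca²⁺-dependent
intracellular cysteine proteases that regulate their substrates by limited
proteolysis. They have no crisp recognition motif — cleavability is a graded
property distributed over the P10…P10′ positions flanking the scissile bond —
so useful prediction is quantitative: a cleavage *probability* per bond, and
a catalytic efficiency *k*<sub>cat</sub>/*K*<sub>m</sub> (M⁻¹s⁻¹) per site.
calpainqsar is for protease biochemists and proteomics analysts who want to
model that specificity from oligopeptide digestion data.

The package provides, end to end:

* **Window featurization** — P10–P10′ site windows from peptides or
  proteins, converted to per-position numeric features via amino-acid
  descriptor scales (AAindex flat files, generic TSV tables, per-residue
  secondary-structure sidecars), with descriptor pre-selection by *r*² and
  by joint Pearson/Spearman rank-sum.
* **A Bayes binary-QSAR classifier** of cleavability: z-scored features,
  principal components, binned class-conditional densities with Laplace
  smoothing, naive-Bayes combination —
  *P*(cleaved | **x**) ∝ *P*(cleaved) ∏ⱼ *P*(binⱼ(**x**) | cleaved) —
  with leave-one-out cross-validated accuracy (XA), greedy backward feature
  elimination under an XA floor, confusion-matrix metrics, whole-protein
  scanning and a P2×P1 cooperativity count table.
* **A PLS efficiency model** — NIPALS partial least squares of raw-scale
  *k*<sub>cat</sub>/*K*<sub>m</sub> on position-specific descriptors
  (single or paired positions), component choice by leave-one-out *Xr*²,
  standardized-residual outlier exclusion, per-position Δ*k*<sub>cat</sub>/*K*<sub>m</sub>
  contribution profiles and subsequence scoring.
* **Kinetics** — *k*<sub>cat</sub>/*K*<sub>m</sub> from multiplexed
  isobaric-reporter intensities: v₀ from full-length decay and fragment
  formation, Lineweaver-Burk regression (*k*<sub>cat</sub>/*K*<sub>m</sub> =
  1/(b·[E]ₜ)), optional first-order depletion correction and
  variance-weighted, multi-route combined estimation; Eadie-Hofstee for
  comparison; a seeded digestion simulator for recovery tests.
* **Specificity statistics** — log₁₀ enrichment profiles over a standard
  composition, profile correlations with the t-test for *r*, one- and
  two-proportion Z-tests, binomial absence probabilities, Welch's t-test,
  cleavage-position bias analysis.
* **Decoy-database construction** — C-terminal proteome tails filtered by
  shared 4-mer blocks against a target set (reverse then forward), with
  seeded sampling; plus a fully seeded synthetic-library generator so
  everything above is testable offline.

Everything takes and returns tibbles and pipes; fitted models have
`tidy()`/`glance()` methods and `autoplot()` visualizations. A thin CLI
(`inst/cli/calpainqsar.R`) wraps the main verbs
(`featurize`, `fit-binary`, `fit-pls`, `predict`, `scan`, `kinetics`,
`stats`, `simulate`, `decoydb`).

## Worked example

```r
library(calpainqsar)

# a seeded synthetic oligopeptide library: 87 20-mers, every internal bond
# a window, efficiencies from a planted P2-hydropathy model
lib <- generate_synthetic_library(n_peptides = 87, seed = 42)

# candidate features at three positions; backward elimination under the
# leave-one-out accuracy floor
features <- as_feature_spec(c("P2", "P1", "P3p"),
                            c("KYTJ820101", "SYNTH001", "SYNTH002"))
X <- featurize_spec(lib$windows, features, lib$tables)
traj <- backward_select_binary(X, lib$windows$label, floor = 0.7)
traj
#> Backward selection trajectory (3 steps)
#> Chosen step 3: 1 feature(s), criterion 0.8212
#> Features: P2_KYTJ820101
```

Selection keeps exactly the planted P2 hydropathy feature and discards the
decoys. The cross-validated operating characteristics of the chosen model:

```r
loo <- loo_binary_accuracy(X[, traj$chosen_features, drop = FALSE],
                           lib$windows$label)
round(c(XA = loo$accuracy, sensitivity = loo$sensitivity,
        specificity = loo$specificity), 3)
#>          XA sensitivity specificity
#>       0.821       0.748       0.868
```

XA is the leave-one-out accuracy; sensitivity/specificity are the cleaved
and uncleaved recall at threshold 0.5. Estimating an efficiency from
simulated 8-plex reporter intensities (true value 350 M⁻¹s⁻¹; the
estimate combines both fragment routes and the full-length decay by
inverse variance):

```r
sim <- simulate_digestion(true_kcat_km = 350, noise_cv = 0.1, seed = 42)
estimate_kcat_km(sim)
#> # A tibble: 1 × 5
#>   peptide_id value    se n_routes n_points
#>   <chr>      <dbl> <dbl>    <int>    <int>
#> 1 sim         363.  15.3        3       18
```

The recovered 363 ± 15 M⁻¹s⁻¹ brackets the truth. Finally, which residues
are enriched at P2 among cleaved windows, as log₁₀ ratios over the
standard composition:

```r
prof <- frequency_profile(lib$windows[lib$windows$label, ])
prof |> dplyr::filter(position == "P2") |>
  dplyr::slice_max(log_ratio, n = 3)
#>   position residue count     n proportion log_ratio
#> 1 P2       V          50   305      0.164     0.384
#> 2 P2       L          60   305      0.197     0.297
#> 3 P2       I          36   305      0.118     0.297
```

Hydrophobic β-branched residues dominate P2 — the planted signal, recovered
as an enrichment logo would show it.

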