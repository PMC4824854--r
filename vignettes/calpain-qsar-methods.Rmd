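---
title: "Models and methods behind calpainqsar"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind calpainqsar}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(calpainqsar)
```

calpainqsar models the substrate specificity of the conventional calpains
(calpain-1 and calpain-2), intracellular Ca^2+^-dependent cysteine proteases
that regulate their substrates by limited proteolysis. Unlike caspases,
calpains have no simple sequence motif: cleavability is a graded property
spread over many subsites, so the package treats it quantitatively — as a
cleavage probability and as a catalytic efficiency
$k_\mathrm{cat}/K_\mathrm{m}$ (M^-1^ s^-1^) per peptide bond. This vignette
records the models, the tunable parameters and the design decisions, so a
reader can judge what the computations do and do not establish.

## Cleavage-site windows and featurization

Every analysis unit is a **site window**: the residues occupying positions
P10…P1 (N-terminal to the scissile bond) and P1′…P10′ (C-terminal), written
`P10`…`P1`, `P1p`…`P10p` in code and file headers so labels round-trip
unambiguously. P1 is the residue immediately N-terminal to the cleaved
bond. Positions that fall outside a peptide are *missing*; a 19-mer in a
20-mer library needs no special case because the same missing-data
mechanism covers it.

Windows are turned into numeric features by looking residues up in
**descriptor tables** — one value per amino acid per scale (hydropathy,
accessibility, surface areas, …). Secondary-structure descriptors are
different: they are per-residue probabilities from an external predictor,
so they are supplied as a per-peptide sidecar table and never computed
here. Feature columns are ordered deterministically (positions N→C outer,
descriptor ids lexicographic inner) and all tie-breaks anywhere in the
package are lexicographic, so identical inputs give byte-identical outputs.

Two pre-selection tools reduce a large descriptor library before model
fitting: per position, the scale whose values correlate best (largest
$r^2$) with measured efficiencies; and, given a per-residue activity
profile, a rank-sum ordering of scales by Pearson's $r$ and Spearman's
$\rho$ jointly. Ranking uses absolute correlations because the sign of a
published scale is an arbitrary convention; $\rho$ is included because some
scales have outlier-heavy distributions that distort $r$. Constant scales
are excluded (selection) or assigned the worst rank (ranking), with a
warning.

Model fitting standardizes each scale to zero mean and unit variance over
the 20 residues. The choice is internal — predictions are invariant to
affine rescaling of any input scale — but it keeps principal-component and
latent-variable steps comparable across scales of very different physical
units. Raw values are kept for reporting effect sizes in M^-1^ s^-1^.

## The binary-QSAR cleavability classifier

`fit_binary_qsar()` implements the classical binary-QSAR scheme: z-score
the features, rotate onto principal components, keep the leading components
(default: 98 % cumulative variance, at least one), histogram each retained
component separately per class (default 10 equal-width bins over the
training range, 0.5 pseudo-counts per bin), and combine the per-component
class-conditional densities by Bayes' rule with the training prevalence as
prior:

$$ P(\text{cleaved} \mid x) \propto P(\text{cleaved}) \prod_j
   P(\mathrm{bin}_j(x) \mid \text{cleaved}). $$

The output is a probability in (0, 1); smoothing guarantees it never
saturates. With two bins and one binary feature the model reproduces the
closed-form Bayes posterior up to the smoothing term, which is the unit
test anchoring the implementation. Out-of-range scores at prediction time
are clamped into the edge bins — the sensible extrapolation for binned
densities. Parameters worth knowing:

* `bins` (10) and `smoothing` (0.5 pseudo-counts): histogram resolution
  versus variance; unspecified in the published description of the method,
  so both are explicit arguments.
* `var_explained` (0.98): how many principal components survive.
* classification threshold: 0.5 by default; 0.95 is the deliberate
  high-precision mode used when scanning proteins, trading sensitivity for
  positive predictive value.
* the 0.5 M^-1^ s^-1^ *cut-off* that maps efficiencies to binary training
  labels is a property of the source data coding (cleaved = 1,
  uncleaved = 0), distinct from the classification threshold.

Model quality is measured by leave-one-out cross-validated accuracy (XA):
the classifier is literally refit on $n-1$ rows for every row. A fold whose
training set collapses to one class predicts from the training prior.
Feature sets are chosen by greedy backward elimination: at each step the
feature whose removal maximizes XA is dropped, and the chosen model is the
smallest set with XA above the floor (default 0.7) — the codified version
of a selection that is otherwise done by eye on the trajectory. If no step
clears the floor the best step is returned, flagged, never silently.

Windows restricted to complete P6–P6′ ranges are the default fitting
domain: windows with many missing terminal positions otherwise teach the
classifier to recognize missingness rather than chemistry. The range is a
parameter, not a constant.

`scan_protein()` slides a fitted model along a protein, reports a
probability per bond, leaves bonds whose window is incomplete explicitly
unscorable, and calls sites above the high-precision threshold.
`cooperativity_table()` gives the model-free companion readout: cleaved and
total counts for residue pairs at two positions (classically P2 × P1).

## The PLS efficiency model

`fit_pls_qsar()` regresses raw-scale $k_\mathrm{cat}/K_\mathrm{m}$ on
per-position descriptor values by NIPALS partial least squares. Raw scale
(not log) keeps the model's per-position contributions additive in
M^-1^ s^-1^, which is how effect ranges are reported. Latent components
are chosen by maximizing leave-one-out cross-validated $r^2$ ($Xr^2$), up
to min(8, rank); at full rank PLS coincides with ordinary least squares,
which is asserted against `lm` to 10^-8^ in the tests. Features may span a
*pair* of positions (e.g. P2–P1), evaluated as the descriptor sum over the
two members — the additive convention that lets a pair term marginalize
cleanly: when one member is unknown or out of range it is replaced by the
uniform 20-residue average of the scale.

After a first fit, rows with |standardized residual| > 2.5 are excluded
and the model refit once (`exclude_outliers_and_refit()`); the rule is a
conventional residual cut, the threshold is configurable, and a refit that
would drop more than 20 % of rows is refused rather than performed.
Backward elimination mirrors the classifier's, with $Xr^2$ and floor 0.6.

Interpretation tools are all intercept-free differences of predictions:
`position_contribution()` gives the per-residue effect profile of one
position (partners averaged uniformly), whose sum over positions plus the
intercept exactly recomposes the full prediction for single-position
models; `score_subsequence()` scores a partial window (e.g. a P3–P3′
hexapeptide) with out-of-range features marginalized, so scores are
comparable across subsequences of the same range. Because the model is
additive, the best subsequence over all 20^6^ hexapeptides is found by
per-position argmax — verified against exhaustive enumeration on a
two-position grid in the tests.

## Kinetics: efficiencies from multiplexed intensities

The assay digests an oligopeptide mixture at seven initial concentrations
in one run, one isobaric-label channel per concentration (10, 20, 10, 6.7,
5.0, 4.0 and 3.3 µM; enzyme 2.5 µM in six of them; 900 s at 30 °C), with a
no-enzyme reference channel and a 5 µM fragment-standard channel.
Initial velocities come from the printed formulas

$$ v_0^{\mathrm{full}} = \frac{[S]_{0(n)} - (I_n / I_{113}) \,
   [S]_{0(113)}}{900\ \mathrm{s}}, \qquad
   v_0^{\mathrm{frag}} = \frac{(I_n / I_{121}) \cdot 5 \times
   10^{-6}\ \mathrm{M}}{900\ \mathrm{s}}, $$

and the specificity constant from the double-reciprocal (Lineweaver-Burk)
slope $b$ of $1/v_0$ on $1/[S]_0$ as $1/(b\,[E]_t)$ — exact under
$[S] \ll K_\mathrm{m}$, where $v = (k_\mathrm{cat}/K_\mathrm{m})[E][S]$.
`lineweaver_burk()` returns exactly that by default. Points with
non-positive $v_0$ (possible for the full-length formula under noise) are
dropped and counted. An Eadie-Hofstee variant is provided for comparison;
note that strictly first-order data make its abscissa ($v_0/[S]_0$)
constant, so it is only informative when Michaelis curvature is present,
and degenerate inputs return "not estimable" rather than a number.

The recovery pipeline `estimate_kcat_km()` adds three estimator
refinements, each chosen on statistical grounds and switchable:

1. **First-order depletion correction.** An endpoint assay measures the
   average rate, not the initial rate: with fraction
   $f = k_\mathrm{app}[E]_t t$ consumed, the true constant is
   $k = -\ln(1-f)/([E]_t t)$. At $k = 1000$ M^-1^ s^-1^ under this design
   ~90 % of substrate is consumed and the uncorrected estimate is low by
   ~60 %, deterministically; the corrected chain is exact on noise-free
   first-order data at any rate.
2. **Variance weighting** ($w = v_0^2$) in the double-reciprocal fit:
   reporter-ion noise is multiplicative, so
   $\mathrm{var}(1/v_0) \propto (1/v_0)^2$ and the unweighted fit lets the
   lowest-concentration points dominate. The plain unweighted fit remains
   the `lineweaver_burk()` default.
3. **Route combination.** Each cleavage yields two complementary
   fragments, each quantified against its own standard, plus the
   full-length decay against the reference channel. The three routes have
   complementary precision (full-length is sharp when most substrate is
   consumed, fragments when little is), so the per-route estimates are
   combined by inverse-variance weighting using delta-method standard
   errors propagated from the slope.

`simulate_digestion()` generates reporter intensities under exact
first-order decay $S(t) = S_0 e^{-k[E]t}$ with independent log-normal
noise per measured intensity (mean-one parameterization), deterministic
under its seed. It emulates the channel design and noise scale, not the
things that make real reporter data hard: isotope-impurity cross-talk,
shared-precursor interference, detector saturation, or the excess
variance of full-length quantification observed in practice. Passing
recovery tests therefore demonstrates estimator correctness under the
stated noise model, no more. Under that model, with 10 % intensity noise,
the median recovery error at 50–1000 M^-1^ s^-1^ is 5–8 %, dominated by
the single shared standard-channel intensity — an irreducible feature of
a one-standard design worth knowing when planning a real experiment.

## Specificity statistics

Frequency profiles count residues per window position and standardize by a
background composition (the bundled table is a proteome-wide composition:
Ala 8.67 % … Tyr 3.03 %), reported as
$r = \log_{10}(\text{observed}/\text{background})$. Base 10 is a display
convention only. A residue absent at a position yields $-\infty$, kept as
an explicit sentinel: profile correlations exclude such cells pairwise and
report how many were dropped; the logo export floors them at a display
minimum. Profile agreement uses Pearson correlation with the t-transform
$t = r\sqrt{(n-2)/(1-r^2)}$ for significance.

The proportion machinery is deliberately plain: a pooled two-proportion
Z-test without continuity correction (the published analyses do not state
pooling or correction; pooled/uncorrected is the textbook default and is
cross-checked against the uncorrected chi-squared in tests), a
one-proportion Z-test for cleavage-position bias against the
uniform-cleavage expectation $1/(L-1)$ per bond (library-weighted when
lengths vary; ≈5 % for 20-mers), the closed-form absence probability
$(1-p)^n$, and Welch's t-test via `stats::t.test`. No multiple-testing
correction is applied by default, matching the source analyses; a
Bonferroni adjustment is a one-liner with `p.adjust` on any returned
column.

## Synthetic data and the decoy construction

`generate_synthetic_library()` emulates the oligopeptide study: 87
20-mers drawn from the background composition, every internal bond
enumerated, a planted linear model on per-position descriptors assigning
each window a true efficiency times log-normal noise (CV 0.5 by default —
the within-sequence spread seen in measured efficiency panels), and labels
by thresholding. The default threshold targets a positive prevalence of
0.39, the complete-window prevalence of the study design (314 cleaved of
806). The default planted signal is a single P2 hydropathy term, P2 being
the dominant specificity position; recovery tests ask whether model
selection re-finds it among decoy features. What the generator does *not*
emulate: real windows are correlated (19 windows share one peptide),
composition at fixed positions is biased by library design, and real
cleavability involves several interacting positions — so passing recovery
says the machinery works, not that real data are this easy.

The decoy-database builder reproduces a staged padding construction for
FDR estimation: C-terminal 20-mers of proteome entries, elimination of
tails sharing any 4-residue block with target sequences in reverse, then
in forward orientation, then uniform seeded sampling. "Block" is read
plainly as any contiguous substring of length 4, matching exactly; the
reverse filter reverses the *tail* (the ambiguous alternative — reversing
the full entry — would differ only for entries longer than the tail).
Survivor sets are verified against an exhaustive substring oracle, and
enlarging the target set can only shrink the survivor set (tested).

## Problem sizes and numerical conventions

The test and verification suites run at deliberately moderate sizes chosen
to exercise every code path with clear statistical margins: 100 simulated
digestions per rate constant; 119-row efficiency fits (the size of a
realistic measured panel); 800-window libraries for classifier selection
(10 replicate generations); 1000 null libraries for the type-I-error
check. Degenerate inputs are errors with messages, never silent numbers:
single-class training sets, zero-variance responses, fewer than three
usable kinetic points, regression ranges excluding every model feature.
Random number use is always scoped: generators take explicit seeds and
restore the global RNG state.

## Known limitations

* The classifier is *a* faithful implementation of the published
  binary-QSAR scheme, not a numeric clone of any particular commercial
  implementation; accuracies on identical data should agree to within a
  few points, not to the digit. The same holds for the PLS
  component-selection heuristic and the outlier rule (a 2.5-SD residual
  cut standing in for an unpublished rule).
* Descriptor values are consumed as tables; nothing here computes
  molecular descriptors from 3-D chemistry, and secondary-structure
  probabilities must come from an external predictor.
* The kinetics error model is log-normal and independent per intensity;
  correlated channel effects are handled only by the control-peptide
  standardization hook.
* Paired-position features assume additive descriptor contributions; true
  cooperativity beyond additivity is visible only in the count-based
  cooperativity table, not in the PLS model.
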