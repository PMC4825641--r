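---
title: "Methods: growth kinetics, morphology statistics, and diversity-phenotype association"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: growth kinetics, morphology statistics, and diversity-phenotype association}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(protophen)
```

protophen implements the computational side of a population-phenomics survey
of a yeast strain panel: microplate growth-curve kinetics across many
environments, high-dimensional cell-morphology statistics, hierarchical
clustering of trait profiles, and the association between pairwise genetic
diversity and pairwise phenotype similarity. Because the raw measurements of
such surveys are rarely deposited in machine-readable form, the package
ships a synthetic-data generator with known ground truth; every analysis
stage is validated against that truth, against closed-form cases, and
against independent brute-force reference implementations.

This vignette explains the models and the choices behind them. It states no
empirical result that the test suite or `scripts/acceptance.R` does not
itself compute.

## Growth-curve parameter extraction

Each well yields an OD time series (default design: 48 h sampled every
10 min, 289 points). After background correction — subtraction of the blank
reading when present, otherwise of the minimum of the first five readings,
followed by clamping below at `epsilon = 0.01` so logarithms exist — three
parameters are extracted by `fit_growth_parameters()`:

* **Specific growth rate** (per hour): an ordinary least-squares line of
  ln(OD) on time is fitted in every window of 15 consecutive readings,
  advanced one point at a time; the rate is the maximum slope over all
  windows. Regressing the *logarithm* is what makes the slope a specific
  growth rate with doubling time ln 2 / mu.
* **Lag time** (hours): the intersection of the winning regression line
  with the baseline log-absorbance level, taken as the median of the first
  five corrected readings. Negative intersections are clamped to zero and
  flagged.
* **Yield** (OD units): the maximal corrected OD reached over the whole
  cultivation, without smoothing.

Flags rather than silent edits record quality: `no_growth` when the best
slope falls below `min_rate = 0.01`/h (the rate is then 0 and the lag
undefined), `poor_fit` when the winning window's r-squared falls below
`min_r2 = 0.95`, and `negative_lag_clamped`.

Two readings of "a 15-record window sliding by 10 points" are defensible
for such estimators; the package defaults to stride 1 (every start position)
because the stride-1 maximum dominates any coarser stride's maximum and does
not depend on where the grid happens to start; `stride = 10` is available
for the literal non-overlapping reading. Ties between equal maximal slopes
go to the earliest window, making the estimator deterministic.

The window regression is computed from running sums in O(n) per curve after
centering time and log-OD globally; the test suite checks it against an
exhaustive `lm()` per window on hundreds of curves, so the fast path is
never trusted on its own.

Normalization (`normalize_to_reference()`) averages replicate fits per
strain and condition, then divides by the strain's value in the reference
medium (YPD), so a ratio of 1 means "as in the reference". The same
condition/reference orientation is used for all three parameters. Wells
where no replicate grew contribute a ratio of 0 for rate and yield (no
biomass accumulated) and a missing lag; strains whose *reference* culture
failed are set wholly missing, with a warning, since their ratios are
undefined. Conditions are classified by their median ratio across strains:
below 0.3 low resistance, 0.3 to 0.8 (inclusive) mid, above 0.8 high.
Leave-one-out variance contributions, `(Var_all - Var_without_s)/Var_all`,
identify strains that dominate a condition's variance.

## The synthetic growth-curve generator

The generator's role is to produce curves whose *true* rate, lag and yield
are known exactly, under the default study design (27 strains x 55
conditions x 2 replicates). Two requirements shape it:

1. **The truth must be the estimator's estimand.** The package simulates a
   modified-Gompertz sigmoid in log-OD space — the standard
   parameterization of microbial growth curves in which mu is by definition
   the maximal slope of ln(OD) vs time, the lag is where the tangent at the
   inflection meets the baseline level, and K is the asymptote. The
   double-exponential left tail is renormalized so the curve sits exactly at
   the inoculum level at t = 0 (the raw form only approaches it
   asymptotically, which at slow growth visibly lifts the early baseline).
   Because a finite 15-point window averages a curved log-slope, the
   noiseless estimate still differs from the nominal mu by a small
   deterministic amount; the generator therefore calibrates its (mu, lag)
   parameters by a short fixed-point iteration against the package's own
   noiseless fit, so that the *measured* noiseless values equal the
   configured truths. Calibration is skipped for wells too slow to reach
   their inflection within the cultivation — there the truth is genuinely
   censored, as it would be on a real plate.
2. **Noise must act where it acts on a plate reader.** Gaussian read noise
   (sd 0.005 OD) is added to the OD signal, not its log. A sigmoid whose
   log-slope peaks at mid-OD keeps the maximum-slope window away from the
   near-baseline region where log-scale noise diverges; an inoculum of
   0.05 OD above blank keeps early readings above both the epsilon clamp
   and the noise floor. The generator writes a constant per-well blank
   column, as a plate layout with medium-only wells provides.

True parameters follow a multiplicative (lognormal) model: log rate =
strain + condition + interaction. Reference-medium strain rates are drawn
between 0.18 and 0.72 per hour — one designated slow outlier strain at
0.18, the rest from a truncated normal around 0.48 — so the reference
condition shows a realistic across-strain variance (~0.013) dominated by
one outlier. Yield layers are built proportional to the rate layers with a
configurable correlation (default 0.78) imposed on *every* layer; this
makes the log-scale correlation between true rate and true yield equal the
configured value exactly in expectation. (On the raw scale the Pearson
correlation of lognormals is attenuated by the wide condition layer, which
is why the package states and verifies this parameter on the log scale.)
Lag is drawn from independent layers; its sample correlation with rate or
yield fluctuates around zero with an effective sample size set by the 54
non-reference conditions, so values up to about |0.1| are ordinary.

The interaction layer carries the genotype coupling: each subgroup shares a
condition-response component whose amplitude grows with the subgroup's
divergence from the panel ancestor, scaled by `diversity_effect`. Strains
from divergent subgroups therefore have less correlated growth profiles,
which is what the downstream Kendall association detects; setting
`diversity_effect = 0` removes the coupling. The component scales
(sigma_div = 0.15, sigma0 = 0.17) were chosen so that, at the default
design, the Kendall evidence is of the same order as published surveys of
this kind (tau around -0.2 to -0.35 over 351 strain pairs) rather than
overwhelming, and mean pairwise growth-profile correlations sit in the
0.8-0.9 range.

## Morphology statistics

The morphology table holds 501 trait values per replicate culture (5 per
strain), consumed as numbers — image processing is out of scope.

* `reference_standardize()` applies f(x) = (x - mu_ref)/sigma_ref per
  trait, with moments from the reference strain's replicates. Rank-based
  inference is unaffected; the transform only fixes scales. Zero-SD
  reference traits cannot be standardized and are dropped with a warning.
* `kruskal_wallis_scan()` runs the tie-corrected Kruskal-Wallis test of the
  strain effect per trait (chi-square approximation — group sizes of 5 are
  too small for exact enumeration across 501 traits, and the approximation
  is the field's standard), with Bonferroni correction over the number of
  traits actually tested. Completely tied traits get H = 0, p = 1. The scan
  also reports the one-way sum-of-squares partition (between-strain and
  pooled within-strain), which must add to the total sum of squares — an
  identity the tests verify on random tables.
* `pca_traits()` decomposes the strain-mean matrix (one point per strain,
  as strain-level ordination intends; replicate-level PCA is available via
  a flag), standardizing traits to unit variance by default since
  morphological traits live on incommensurate scales; `scale. = FALSE`
  gives the covariance PCA. Contribution ratios are normalized eigenvalues
  and are checked against an independent eigen-decomposition.
* `trait_variance()` summarizes strain-level dispersion: per trait, each
  strain's deviation from the grand mean is divided by the standard error
  of its mean (pooled residual SD) to give a Z value; the trait's variance
  is the across-strain variance of Z, and the phenotype-level variance is
  the mean over traits. Under no strain effect this sits at 1 (a useful
  null anchor, verified by simulation); strain effects inflate it. This is
  a deliberate simplification of trait-family-specific generalized linear
  models used with some morphology pipelines, whose per-trait error-family
  assignments are not reproducible from published descriptions; only
  orderings and monotonicity of this variance are meaningful here, not its
  absolute value.

The synthetic morphology generator plants strain effects in 384 of the 501
traits (the remainder are pure replicate noise), independent of the
genotype panel — morphological variation in this design is deliberately
*not* structured by genetic divergence, providing the negative control for
the association stage. The strain-effect SD for signal traits is 1.1
replicate-noise units, sized so the Bonferroni scan recovers close to the
planted signal fraction at the default design (per-trait power ~0.93-0.97;
sizing it lower systematically under-recovers the fraction). Effects are
drawn independently per trait, so the synthetic trait space has no
low-rank correlation structure; real morphology traits come in strongly
correlated families, which concentrates their PCA spectrum far more than
this generator does (see Limitations).

For *pairwise strain comparisons* of morphology the package uses Z-value
profiles (`trait_z_matrix()`): per-trait centered strain deviations. Profiles
centered across n strains have expected pairwise correlation -1/(n-1) (about
-0.038 at n = 27) under independent effects, which is the natural "no
structure" reference point for such comparisons; uncentered standardized
means would instead share the reference strain's own deviation and show a
spurious common correlation near 0.5.

## Clustering and origin association

Strain (and condition) profiles are compared with the centered Pearson
distance d = 1 - r, ranging over [0, 2], with pairwise-complete handling of
missing entries; zero-variance profiles are rejected by name since their
correlation is undefined. Clustering is agglomerative with the unweighted
average-linkage (UPGMA) update; items are ordered lexicographically before
linkage so ties resolve deterministically, and the implementation is tested
against a brute-force UPGMA on every matrix of up to six items. Merge-height
monotonicity (guaranteed for average linkage on a metric) is recorded on the
result. Reporting cuts the tree at k = 2 by default; with the default
generator the first split typically isolates the slow-growth outlier strain,
so inspecting k = 3 is often informative.

Whether clusters track strain origin (geography, ecology) is tested by the
chi-square statistic of the cluster-by-origin table with a *permutation*
p-value (labels shuffled across strains, default 10,000 draws) — the
asymptotic chi-square reference would not be trustworthy at 27 strains.

## Diversity-phenotype association

Pairwise genetic diversity is the per-site Hamming fraction over
pairwise-complete sites of the haploid 0/1 genotype matrix. The synthetic
panel is block-structured: all strains descend from one ancestral
haplotype, subgroups carry shared derived alleles with per-subgroup
probabilities laid out on a ladder, and strains add private alleles; the
ladder is solved so the expected maximum pairwise divergence equals the
configured 2.5%. Only pairwise distances feed the analysis, so no
coalescent machinery is warranted.

`diversity_phenotype_association()` computes Kendall's tau-b between
pairwise diversity and pairwise profile correlation, with the
normal-approximation p-value, and additionally the descriptive linear
regression slope. Two caveats are built into the interface: the n(n-1)/2
strain pairs are not independent (each strain occurs in n-1 pairs), so the
analytic p-value is anti-conservative; a strain-label permutation p-value is
available via `n_perm` for honest inference. The tau implementation is
validated against explicit concordant/discordant pair enumeration including
tie corrections.

## Numerical and degenerate-input choices

* Window regressions run on globally centered coordinates; flat windows get
  slope 0 and r-squared 0 by convention.
* `epsilon = 0.01` OD is the floor for logs after background correction; a
  curve clamped everywhere (e.g. a blank exceeding all readings) warns and
  flags rather than erroring.
* Complete ties in the trait scan: H = 0, p = 1.
* Variance contributions where the full variance is 0 are reported missing
  (0/0).
* Singleton subgroups have no within-group correlation entry.
* Seeds: every generator stage derives its own sub-seed from the configured
  seed, so stages are independently reproducible and a configuration is
  bit-identical across runs; all sub-seeds stay far below the 32-bit
  integer ceiling.

## Problem sizes

The default configuration — the design all headline numbers refer to — is
27 strains x 55 conditions x 2 replicate curves (2970 curves, 1485
strain-condition pairs per parameter), 27 x 5 x 501 morphology records
(135 replicate rows), and 10,000 genotyped sites. Ten thousand sites keep a
pairwise-distance standard error near 0.0016, ample for distances up to
0.025, while the full panels of real surveys (hundreds of thousands of
segregating sites) would only shrink error bars that are already
negligible. Stochastic test properties use 10-100 repetitions or 20 seeds,
chosen so that pass/fail margins are several standard errors wide.

## What the tests do and do not establish

Passing tests establish that the estimators do what they claim on data
whose generating process is known: the window fit equals its exhaustive
definition; true parameters are recovered (exactly without noise, within
stated bands with plate-reader-scale noise); family-wise error is
controlled under the null; the clustering and tau implementations match
brute force; the coupled/uncoupled association signs reproduce. They do
*not* establish that real plates satisfy the generator's assumptions:
no spatial plate effects, no evaporation or condensation drift, Gaussian
read noise, a single smooth growth phase (no diauxie or flocculation), and
morphology effects independent across traits. Findings on real data should
be read with those gaps in mind.

## Known limitations

* The Gompertz family cannot represent multi-phasic (diauxic) growth;
  curves with secondary growth phases will yield the dominant phase's
  parameters.
* Yields of slow growers are censored at 48 h by construction — as on a
  real plate — so yield ratios in harsh conditions under-estimate the
  asymptote.
* The phenotype-level variance is a surrogate on the Z scale; compare its
  values only within this package.
* The synthetic PCA spectrum is flat relative to real morphology data
  (independent trait effects), so the number of components needed for a
  cumulative target is larger than published low-rank trait families would
  give.
* The analytic Kendall p-value ignores pair dependence; use the permutation
  option when the inference matters.
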