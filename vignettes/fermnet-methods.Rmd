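---
title: "Linking microbial succession to volatile profiles: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Linking microbial succession to volatile profiles: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fermnet)
```

fermnet analyses the kind of data produced by studies of spontaneous food
fermentations: genus-level microbial abundance tables over a handful of
fermentation stages with a few replicates each, and GC-MS volatile
concentration tables over the same stages. Its goal is the question such
studies ask at the end: *which members of the community are plausibly
driving which aroma compounds?* This vignette explains the statistical
machinery, the choices we made where the methodology is genuinely open,
and what the synthetic-data tests do and do not establish.

## Data model

An abundance table (`abund_tbl`) is a samples-by-taxa tibble with `stage`
and `replicate` metadata; counts or relative abundances (rows summing to
one) are auto-detected on read. A volatile table (`volatile_tbl`) is a
long tibble of concentrations in ug/L; "not detected" is `NA`, which is
distinct from a measured zero — a compound below the detection limit is
treated as 0 only where a numeric value is forced (ordination,
correlation, clustering), and that substitution is a documented
assumption, not a statement that the compound is absent.

The package ships the published 53-compound flat-peach-wine volatile
table as a worked fixture (`load_table1_fixture()`), with stage means and
standard deviations stored separately and odor thresholds that may be
single values, ranges (stored as `[low, high]`), or missing. Two details
of that table are preserved deliberately: compound classes follow the
printed section headings verbatim (one lactone is listed under aldehydes),
and one threshold with an implausible printed value (an extra digit) is
stored as the only reading consistent with its own printed OAV band.

## Alpha diversity

The five per-sample summaries are the classical ones. Chao1 uses the
bias-corrected form $S_{obs} + F_1(F_1-1)/(2(F_2+1))$, appropriate for
small samples and defined even when no doubletons occur. Shannon entropy
defaults to natural log with a base-2 switch. Simpson is reported as
Gini–Simpson $1-\sum p_i^2$ (so that larger = more diverse), with the
dominance form behind a flag. Good's coverage is $1 - F_1/N$.
Richness-type estimators refuse non-integer input: they are defined on
counts, and silently accepting proportions would return nonsense. No
rarefaction is applied by default because the appropriate depth is
context-dependent; a seeded subsampling option exists
(`alpha_diversity(rarefy_to = ...)`).

## Ordination

`pca()` is an exact SVD on the centered (optionally variance-scaled)
matrix. Community snapshots are typically run centered only, on relative
abundances; volatile profiles centered and scaled, because concentrations
span four orders of magnitude and an unscaled PCA would be an ordination
of ethyl acetate alone. Both choices are arguments. Component signs are
fixed by requiring the largest-magnitude loading entry of each component
to be positive; without such a convention PCA results are only defined up
to sign and tests become platform-dependent.

## OAV scoring

The odor activity value is concentration divided by odor threshold; OAV
above 1 marks a compound expected to contribute perceptibly to aroma.
Bands follow the conventional printed form: below 0.1, 0.1–1 (both ends
inclusive — the printed bands do not define closure, so we chose the
middle band closed), above 1. For range thresholds the default policy is
the low end, the aroma-conservative choice; `high` and `midpoint` are
available and the shipped fixture's banded range-threshold compounds agree
under all three. The default scoring stage is the final one: end-of-
fermentation aroma is what such tables summarize, and among the fixture's
stages only the final one reproduces the printed band of every
stage-dependent compound that can be checked. `oav_band_agreement()`
reports computed-versus-printed bands and *flags* mismatches rather than
asserting agreement, because printed tables contain inconsistencies: in
the shipped fixture, ethanol's printed "> 1" cannot be derived from its
final-stage concentration and threshold under any stage or policy we
examined, and is reported as a known mismatch.

## Correlation networks

`correlation_matrix()` returns Pearson (default) or Spearman correlations
with two-sided p-values from the exact t transform
$t = r\sqrt{(n-2)/(1-r^2)}$. The default is Pearson on relative
abundances and concentrations — the screening criterion below is defined
through a *linear* correlation coefficient — with Spearman one flag away.
No multiple-testing correction is applied by default, matching common
practice for these descriptive networks; a Benjamini–Hochberg option
exists for users who want it. Network edges require `|r|` strictly above
the magnitude threshold *and* p strictly below the significance threshold
(defaults 0.7 and 0.01); ties at a threshold are excluded, so shrinking
an edge set by tightening thresholds is a true monotone operation, which
the test suite checks by fuzzing.

Taxon–volatile cross-correlations align samples by replicate when both
tables carry replicates (18 points in the default design) and by stage
means otherwise (6 points, the situation with published per-stage
volatile tables). Replicate-level alignment is preferred whenever
available: with 6 points, chance correlations above 0.6 occur in roughly
a fifth of independent pairs, and any screen built on them would be
mostly noise.

## PLS2 and VIP

The regression engine is NIPALS partial least squares with a multivariate
response, written from scratch: per component, iterate
$w = X'u/\lVert X'u\rVert$, $t = Xw$, $q = Y't/(t't)$, $u = Yq/(q'q)$ to
convergence, then deflate both blocks by the score vector. Both blocks
are autoscaled internally (centering plus unit variance), the common
chemometrics default for mixed-scale blocks. The explained response sum
of squares per component is $(t't)(q'q)$, and variable importance in
projection is
$\mathrm{VIP}_j = \sqrt{p\,\sum_a \mathrm{ssy}_a w_{ja}^2 / \sum_a \mathrm{ssy}_a}$,
whose squares sum to the number of predictors — VIP > 1 therefore marks
an above-average contributor. This identity is checked on every fit and
fuzz-tested across random shapes.

Numerical choices: convergence is declared when the score vector moves
by less than $10^{-10}$; the iteration cap is 5000 because leave-one-out
folds occasionally produce nearly tied latent directions, where the
power iteration rotates very slowly within the tied subspace. If the cap
is reached while the score vector is still drifting by more than a
$10^{-4}$ relative step, the fit errors; below that, the iterate is
accepted, since any basis of a numerically tied subspace yields an
equivalent fit. Y-deflation is performed (symmetric NIPALS); VIP is
insensitive to that choice. Constant columns are dropped with a warning
before autoscaling. Component count can be fixed or chosen by
leave-one-out cross-validation (`select_components_cv()`), keeping
components while the marginal $Q^2$ gain exceeds 0.05 — the usual
chemometrics stopping rule. OPLS variants are deliberately out of scope;
plain PLS2 defines VIP identically and adds no fitting ambiguity.

## The three-criteria core screen

A taxon (or volatile) is "core" when it (i) is stably present — nonzero
in at least half the stages by default, with an optional cap on the
coefficient of variation exposed for stricter readings of "varied
relatively steadily"; (ii) has VIP strictly above 1.0 in the PLS2 model
of volatiles on the top-40 most abundant taxa; and (iii) has at least one
cross-block correlation with absolute value strictly above 0.6. Volatile
VIPs come from a second fit with the blocks swapped — the published
description assigns VIPs to both sides without saying how, and the
swapped fit is the reading that makes the criterion symmetric; a
projection-based alternative from the single forward fit is available.
Strict inequalities match the published "> 1.0" and "> 0.6". The
bipartite network connects each passing taxon–volatile pair whose
correlation clears the same threshold.

## The synthetic-data generator

`simulate_ferment_study()` builds a complete study with known ground
truth: a 6-stage, 3-replicate, 40-genus community and a volatile table
in which 5 planted "core" taxa each drive one compound log-linearly
(effect 3 on the log scale, alternating sign) against measurement noise
of sd 0.05; any compounds beyond the planted ones are baseline noise.

The community model has three variance layers, each with a biological
reading:

* a smooth succession trajectory per taxon (logistic rise/fall, transient
  bloom, or stable), with randomized midpoints, rates, and dynamic ranges
  — planted core taxa get full-range dynamic trajectories, as dominant
  fermentative genera have in practice;
* a per-(taxon, stage) lognormal fluctuation shared by replicates,
  representing irregular biological state;
* Dirichlet-multinomial sampling per replicate at depth $10^4$,
  representing replicate-to-replicate community variation plus counting
  noise. The Dirichlet concentration default is in the tens, the range
  typically fitted to real microbiome replicates, which makes
  within-stage variation a substantial share of each taxon's variance.

That last point is a deliberate identifiability choice, and worth
spelling out. Volatile concentrations respond to the *realized* relative
abundance of their driver taxon, so the planted association transmits
through every variance layer and survives as a near-perfect correlation.
A chance alignment between an unrelated taxon and a compound, by
contrast, can only arise at the stage level (6 points), and is diluted by
the within-stage layers. A generator with smooth, low-noise trajectories
looks cleaner but is a much harder — in the limit, impossible — recovery
problem: with six stages and a handful of trajectory shapes, taxa are so
collinear that *no* correlation-based screen can single out the planted
drivers, and a recovery test would measure collinearity, not correctness.
The generator therefore emulates the noisy, individually fluctuating
series real genus-level data show, which is exactly the regime in which
the screen's criteria are informative.

What passing recovery tests on these data do **not** show: that the
screen recovers causal drivers in real fermentations. Real communities
are compositional, phylogenetically structured, and driven by shared
environmental forcing (ethanol, pH), so correlated non-drivers are
expected; the published screen itself marks more than half of the top-40
genera as core. The synthetic tests establish that the machinery —
correlations, VIP, thresholds, set logic — does what it claims under a
model where the answer is known.

## Problem sizes and determinism

All simulations in the test-suite and in the acceptance script use fixed
seeds and modest sizes (40 taxa, 18 samples, 5–10 compounds; 20-seed
grids for recovery statistics), chosen so the full suite runs in a few
minutes on a single core while the Monte-Carlo acceptance statistics are
stable to well within their tolerances. Every random draw flows from a
single user-supplied seed per run; identical configuration plus seed
reproduces every table byte-for-byte.

## Known limitations

* The screen inherits the published method's limitations: plain Pearson
  correlation on compositional data, no multiple-testing correction, and
  thresholds (VIP 1.0, |r| 0.6) that are conventions rather than
  calibrated error rates.
* Chance correlations at 18 samples put a floor under the screen's
  false-positive rate of roughly one to two taxa per run at the default
  thresholds; this is a property of the criteria at this design size,
  visible in the null-simulation acceptance statistic, not an
  implementation artifact.
* PCA is the only ordination; no PCoA/NMDS/UniFrac.
* No phylogenetic diversity (no tree input exists in this design).
* The volatile generator's log-linear single-taxon effects are a
  convenience, not a fermentation chemistry model.
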