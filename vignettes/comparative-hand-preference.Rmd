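---
title: "Methods: comparative analysis of primate hand preference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparative analysis of primate hand preference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tubetask)
```

This vignette documents the statistical models implemented in `tubetask`,
the assumptions behind them, the tunable parameters and their defaults, the
numerical choices, and what the synthetic-data generator does and does not
emulate. It states no empirical result that the test suite or the acceptance
script does not itself compute.

## Individual-level laterality

Each tested subject contributes counts of left (`L`) and right (`R`)
bimanual insertions. The handedness index

$$\mathrm{HI} = \frac{R - L}{R + L} \in [-1, 1]$$

is descriptive; the binomial z score decides whether the individual bias is
statistically significant:

$$z = \frac{R - n/2}{\sqrt{n/4}}, \qquad n = R + L .$$

**Convention.** We use the normal approximation *without* continuity
correction, and classification is strict at the threshold: `z > 1.96` right,
`z < -1.96` left, everything else (ties included) ambipreferent. Whether the
original tube-task literature applied a continuity correction is rarely
stated; the chosen convention is the common one and is isolated in
`binomial_z()` so it can be swapped in one place. Over the insertion range
enforced by the inclusion filter (30-155), a significant `z` always agrees
in direction with the exact binomial test (verified by enumeration in the
test suite).

**Inclusion filter.** At least 30 insertions in at least 6 bouts, both
boundaries inclusive (`filter_subjects()`). Bout-level indices are not
implemented: insertion- and bout-based preferences are known to be highly
correlated and non-conflicting, and insertions are the finer measurement.

**Group summaries.** MeanHI (direction) and MeanAbsHI (strength) are
unweighted means across subjects. Genus summaries pool subjects rather than
averaging species means, so genus `n` equals the sum of its species' `n`.
By Jensen's inequality MeanAbsHI >= |MeanHI| for every group; this is tested
as a property.

## Population-level tests and the clade baseline

Direction is tested per group with a two-sided one-sample t-test of HI
against 0 (applied to groups with at least `min_n = 15` subjects; smaller
groups can be included explicitly and are flagged). The category
distribution (left / right / ambipreferent) is tested with a Pearson
chi-square (df = 2) against a *clade-specific baseline* rather than a
uniform null: the clade's expected ambipreferent proportion with the
remaining "handed" mass split equally between left and right,

$$p_L = p_R = \frac{1 - p_A}{2}.$$

**Design choice (pooling).** The baseline's `p_A` pools *individuals*
across the clade's species (`weights = "individual"`, the default) rather
than averaging species-level proportions. The wording "mean frequencies per
clade" is ambiguous, but recomputing the published goodness-of-fit p-values
from the packaged category counts settles it: the individual-pooled
baseline reproduces every checkable printed p-value exactly (e.g. 0.288,
0.012, 0.007, 0.031, 0.001 for the spider monkey, golden-headed lion
tamarin, gorilla, squirrel monkey and black lion tamarin rows), while the
species-mean variant does not (e.g. 0.016 instead of 0.012) and changes
which rows survive Bonferroni correction. The species-mean variant remains
available as an option. Humans are always excluded from the hominoid
baseline; their extreme right bias would otherwise contaminate the null.

**Multiple testing.** Bonferroni with family size equal to the number of
groups at the tested level (species or genus), `p_adj = min(1, m p)`.

**Percentages.** Reported percentages are rounded with base R's
round-half-even. Of the two conventions, it reproduces one more printed
cell of the packaged source table (10/32 = 31.25 -> 31.2); ten cells of
that table are internally inconsistent with their own counts either way and
are shipped verbatim for reference, with counts authoritative.

## Phylogenetic signal: Pagel's lambda

For a species-level trait \(y\) on a time-calibrated ultrametric tree with
variance-covariance matrix \(C\) (shared root-to-MRCA path lengths),
`fit_lambda()` maximizes the likelihood of

$$y \sim \mathcal{N}\!\left(\mu \mathbf{1},\; \sigma^2 C_\lambda\right),
\qquad C_\lambda = \lambda C + (1-\lambda)\,\mathrm{diag}(C),$$

profiling \(\mu\) and \(\sigma^2\) in closed form and optimizing
\(\lambda\) on \([0, 1]\).

Numerical choices:

- On an ultrametric tree (all tip depths equal, tolerance 1e-6 relative)
  \(C_\lambda\) shares the eigenvectors of \(C\); a single
  eigendecomposition makes each likelihood evaluation \(O(n)\).
  Non-ultrametric trees fall back to a Cholesky factorization per
  evaluation, with a warning.
- \(\lambda\) is searched by bounded Brent optimization in five
  subintervals plus explicit endpoint evaluation, tolerance 1e-8. Branch
  lengths are used in their native time units: \(\hat\lambda\) and the GLS
  estimates are invariant to global rescaling of \(C\) (tested), so no
  rescaling is performed.
- The likelihood-ratio test against \(\lambda = 0\) uses the \(\chi^2_1\)
  reference. Because \(\lambda = 0\) sits on the boundary of the parameter
  space this is conservative; it is the conventional choice. At
  \(\hat\lambda = 0\) the statistic is 0 and p = 1 exactly.
- On a star phylogeny the likelihood is flat in \(\lambda\); the fit is
  returned with a `flat` flag and a warning rather than an error.
- Constant traits are a degenerate error for `fit_lambda()`; ancestral
  state reconstruction accepts them (all nodes equal the constant).

## Ancestral states under Brownian motion

`asr_bm()` returns the GLS (equivalently, joint maximum-likelihood)
estimates of internal-node states under Brownian motion on the
*untransformed* tree:

$$\hat a = \hat\mu + C_{AY} C^{-1} (y - \hat\mu\mathbf{1}),$$

with \(\hat\mu\) the GLS mean (which is exactly the root estimate) and
\(C_{AY}\) the node-tip shared path lengths. Reported variances are the
conditional variances plus the propagated uncertainty of \(\hat\mu\), scaled
by the ML rate estimate. Estimates agree with brute-force optimization of
the joint BM likelihood over all internal states to 1e-5 (tested), and with
`ape::ace`. Reconstruction under pure BM rather than on the
\(\lambda\)-transformed tree mirrors the default of the standard tooling;
whether published node estimates incorporate a fitted \(\lambda\) is usually
unstated, so this choice is documented rather than assumed.

## PGLS with multi-model inference

`pgls_fit()` estimates, by joint ML, the regression of a species-level
response on subsets of {ecology, tool use, log10 female endocranial volume}
with residual covariance \(\sigma^2 C_\lambda\). For each candidate
\(\lambda\), coefficients and \(\sigma^2\) have closed-form GLS solutions
after whitening by the Cholesky factor (or the eigenbasis on ultrametric
trees); \(\lambda\) is optimized per model. Coding: ecology 0 = arboreal
(reference) / 1 = terrestrial, tool use 0/1, brain size log10 — so
coefficient signs read as "effect of a terrestrial lifestyle", etc.

- **Parameter count.** `k =` number of coefficients (incl. intercept) + 1
  for \(\sigma^2\); \(\lambda\) is *not* counted. This reproduces the
  conventional df column of published AICc tables (null model df = 2,
  one-term models df = 3, full model df = 5).
- **AICc / weights.** \(\mathrm{AICc} = -2\ell + 2k + 2k(k+1)/(n-k-1)\);
  weights \(\propto e^{-\Delta/2}\). All \(2^3 = 8\) subsets including the
  null model are ranked; AICc ties break by fewer terms, then
  lexicographically, for determinism.
- **Conditional averaging.** Each term is averaged only over models
  containing it, with renormalized weights; the adjusted SE uses the
  revised-variance formula
  \(\sqrt{\sum_m w_m (se_m^2 + (\beta_m - \bar\beta)^2)}\), matching the
  defaults of the common multi-model-inference tooling. p-values use a
  normal reference, standard for conditional averages.
- **Diagnostics.** VIFs are computed from the full three-predictor design;
  residual normality is checked with Shapiro-Wilk on the phylogenetically
  whitened (normalized) residuals of the best model.
- At \(\lambda = 0\), PGLS reduces to OLS (tested to 1e-8); the
  implementation is validated against `nlme::gls` with `ape::corPagel` as an
  independent oracle (identical log-likelihoods and SEs to numerical
  tolerance).

`run_model_suite()` performs the three standard analyses: direction on
species with n >= 15, direction excluding humans (their extreme bias
dominates otherwise), and strength on all species.

## Bayesian phylogenetic multilevel models

For individual responses (HI or AbsHI), `sample_posterior()` fits

$$y_i = \beta_0 + \beta_{age}\,\mathrm{subadult}_i +
\beta_{sex}\,\mathrm{male}_i + u_{s(i)} + \varepsilon_i,
\quad u \sim \mathcal{N}(0, \sigma_s^2 A), \quad
\varepsilon_i \sim \mathcal{N}(0, \sigma_e^2),$$

where \(A\) is the tree VCV scaled to unit diagonal (a correlation matrix,
separating tree shape from the \(\sigma_s\) scale). Standard exclusions are
applied by `build_bayes_dataset()`: humans (outlier), chimpanzees
(overrepresented), Tonkean macaques (no age data) and unsexed subjects.
The Gaussian response for the bounded HI/AbsHI follows the original
modelling choice; boundary effects (responses piling up near ±1) are a known
limitation.

**Priors.** Student-t(3, 0, 2.5) on the intercept, implemented as an
inverse-gamma scale mixture so the coefficient update stays conjugate;
improper flat priors on the slopes; half-t(3, 0, 2.5) on both SDs. These
mirror widely used weakly-informative defaults and are configurable in
`mcmc_config()`.

**Sampler.** Coefficients and species effects are drawn *jointly* from
their conditional Gaussian (a single Cholesky solve per iteration; the
cross-products are iteration-constant), which removes the slow mixing that
alternating updates produce between the intercept and the mean of the
random effects. The two SDs use random-walk Metropolis on the log scale.
Defaults are 4 chains x 2000 iterations with 1000 warmup (the published
chain settings live in supplementary material and are not reproduced here);
chain c is seeded `seed + c`, making runs exactly reproducible. Convergence
is summarized by split R-hat (threshold 1.01) and an initial-positive-
sequence ESS; `strict = TRUE` turns non-convergence into an error. An
effect is "notable" when its equal-tailed 95% credible interval excludes
zero.

With the species effect fixed to zero the posterior matches flat-prior
linear regression (tested against OLS), and on a star tree with iid data
the species SD concentrates near zero (tested).

## The synthetic-data generator

`generate_study()` produces a complete study with stored ground truth:

- **Tree.** Pure-birth (Yule), rescaled to height 1, default 38 tips.
- **Direction.** Species values on the *logit* scale of the per-subject
  probability of a right insertion, drawn from
  \(\mathcal{N}(0, \sigma^2 C_\lambda)\); default \(\lambda = 0\),
  \(\sigma = 0.3\). The logit scale keeps probabilities in (0, 1) while the
  species effects stay Gaussian on the tree.
- **Strength.** Species expected |HI|, modeled as
  `strength_base * exp(BM)` (log-scale evolution, default base 0.6,
  \(\sigma = 0.25\), \(\lambda = 0.9\)), clamped to [0.05, 0.98]. Within a
  species, each subject's latent logit SD \(\tau\) is found by numerically
  inverting the map \(\tau \mapsto E|HI|\) (Gaussian quadrature over the
  logit-normal plus a closed-form normal approximation to the binomial
  sampling part, referenced to the mean insertion count). Heritable
  strength with non-heritable direction — the structure seen in real data —
  is therefore the default world, and both \(\lambda\)s are tunable.
- **Defaults as the stated world.** 15-40 subjects per species; insertions
  uniform on 30-155 (only the range and a mean of about 50.7 are reported
  for the real data; a right-skewed shifted negative binomial matching that
  mean is available as `insertion_dist = "nbinom"`). Direction and strength
  spreads were chosen once so that simulated species MeanHI has SD about
  0.15 and MeanAbsHI mean/SD about 0.6/0.17, matching the packaged summary
  table, and are not retuned against test outcomes.
- **Effect injection.** Ecology (Bernoulli 0.5 across species) can shift
  direction (logit scale) and/or strength (|HI| scale); age and sex shift
  individual subjects on the same two scales. Bouts are Poisson around
  insertions/2.46 with a floor of 6, so every generated record passes the
  inclusion filter by construction.

**What a green test does and does not establish.** The generator emulates
binomial insertion noise, within-species heterogeneity, and tree-structured
species effects. It does not emulate bout-sequence autocorrelation,
institution/housing effects, literature-vs-original measurement mixing,
unbalanced clade-specific sampling, or observation error in predictors.
One quantitative consequence is tested and documented rather than hidden:
subject-sampling noise in species MeanAbsHI *attenuates* the recovered
\(\lambda\) (median about 0.7 at 38 species of 15-40 subjects when the
latent \(\lambda\) is 0.9), so end-to-end signal recovery is validated as a
strong strength-vs-direction separation, while calibrated \(\pm 0.15\)
recovery of \(\lambda\) itself is validated on directly simulated traits at
200 tips.

## Known limitations

- The z-score convention (no continuity correction) and the
  individual-pooled baseline are documented choices where the original
  descriptions are ambiguous; both are isolated behind single functions
  with alternatives available.
- LRT p-values at the \(\lambda = 0\) boundary are conservative.
- The Gaussian likelihood for bounded HI/AbsHI ignores edge effects for
  strongly lateralized species.
- Reproducing published headline numbers (e.g. a strength \(\lambda\) of
  0.89 on the real data) requires the external time-calibrated phylogeny,
  the species-level predictor coding and the archived individual-level
  data, which are user-supplied inputs, not package resources.
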