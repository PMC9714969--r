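# tubetask

Comparative analysis of hand preference in anthropoid primates from
bimanual tube-task data.

## The problem

In the tube task, one hand holds a food-filled tube while the other extracts
the contents; the counts of left- and right-hand insertions reveal each
subject's manual lateralization. Multispecies tube-task datasets make it
possible to ask, in an explicitly phylogenetic framework, how the
**direction** (left vs. right bias) and **strength** (degree of bias,
irrespective of side) of hand preference evolved across monkeys, apes and
humans, and whether ecology (arboreal vs. terrestrial lifestyle), habitual
foraging-related tool use, or brain size explain the cross-species patterns.
`tubetask` implements that full analysis chain for researchers in primate
behavioral laterality and phylogenetic comparative methods.

## What it computes

- **Individual laterality.** Handedness index `HI = (R − L)/(R + L)` in
  [−1, 1]; binomial z score `z = (R − n/2) / sqrt(n/4)`; subjects with
  `z > 1.96` are right-handed, `z < −1.96` left-handed, otherwise
  *ambipreferent*. The standard inclusion filter (≥ 30 bimanual insertions
  in ≥ 6 bouts) is applied on import.
- **Group summaries.** Species/genus MeanHI (direction) and MeanAbsHI
  (strength), with category counts; genus summaries pool subjects.
- **Population-level tests.** One-sample t-tests of MeanHI against 0, and a
  chi-square goodness-of-fit test of the left/right/ambipreferent counts
  against a clade-specific baseline: the clade's pooled ambipreferent
  fraction, with the remaining "handed" mass split equally between left and
  right (humans are excluded from the hominoid baseline). Bonferroni
  correction over the number of groups tested.
- **Phylogenetic signal.** ML estimation of Pagel's λ for a continuous
  trait on a time-calibrated tree (μ, σ² profiled in closed form; λ on
  [0, 1] by bounded Brent search), with a likelihood-ratio test against
  λ = 0.
- **Ancestral states.** GLS/ML reconstruction under Brownian motion; the
  root estimate is the GLS mean.
- **PGLS multi-model inference.** PGLS with a Pagel's-λ correlation
  structure (joint ML), all 2³ subsets of {ecology, tool use, log₁₀ brain
  size} ranked by AICc with Akaike weights, conditional model averaging with
  revised-variance standard errors, VIFs, and a Shapiro–Wilk residual check.
  Three analyses: direction (species with n ≥ 15), direction without humans,
  strength (all species).
- **Bayesian multilevel models.** Individual HI or AbsHI on age class and
  sex with a species-level phylogenetic random effect
  `u ~ MVN(0, σ²_species · A)` (A = tree VCV scaled to unit diagonal),
  fitted by a purpose-built Gibbs sampler (joint conjugate draws for
  coefficients and species effects, Metropolis on the log scale for the two
  SDs), with split R-hat and ESS diagnostics and 95% credible intervals.
- **Synthetic studies.** `generate_study()` simulates a pure-birth tree,
  species direction/strength evolving with tunable λ, ecology/tool-use/brain
  predictors, and per-subject binomial insertion counts (30–155), with the
  full ground truth stored for recovery tests.

A packaged transcription of published species-level summaries for 38
anthropoid species (1786 individuals) ships as
`load_species_summaries()`; a handful of percentage cells in the published
table are internally inconsistent with their own counts and are kept
verbatim in the `pct_*` columns (counts are authoritative).

## Worked example

```r
library(tubetask)

summ    <- load_species_summaries()
battery <- gof_battery(summ)             # chi-square vs clade baselines
tab     <- make_table1(summ, battery)
head(tab[order(-tab$n), c("species", "n", "right", "mean_hi", "mean_abs_hi",
                          "p_distribution", "star_distribution")], 3)
#>          species   n      right mean_hi mean_abs_hi p_distribution star
#>  Pan troglodytes 536 266 (49.6)   0.133       0.507          0.000    *
#>     Homo sapiens 127 111 (87.4)   0.761       0.943          0.000    *
#>     Pan paniscus 118  51 (43.2)   0.044       0.529          0.237
```

Humans are the extreme outlier: 87.4% right-handers and MeanHI = 0.761,
against a hominoid baseline (computed excluding humans) of

```r
clade_baseline(summ, "Hominoidea")
#> p_ambi = 0.207, p_left = p_right = 0.396
```

so their category distribution differs from it at p ≪ 0.001 (starred =
still significant after Bonferroni correction over 38 species). The same
run flags chimpanzees, golden snub-nosed monkeys, geladas and black lion
tamarins — and no other species — after correction.

The phylogenetic stages run identically on synthetic data with known truth:

```r
study <- generate_study(sim_config(seed = 42, beta_ecology_strength = -0.15))
sp <- summarize_laterality(subject_laterality(study$subjects), "species")

fit_lambda(setNames(sp$mean_abs_hi, sp$group_id), study$tree)
#> Pagel's lambda (ML)
#>   lambda = 0.6394, sigma2 = 0.02266, mu = 0.5735 (n = 38 tips)
#>   LRT vs lambda = 0: stat = 15.45, p = 8.454e-05

sel <- pgls_model_selection(setNames(sp$mean_abs_hi, sp$group_id),
                            study$predictors, study$tree)
conditional_average(sel)
#>       term estimate    se      z       p n_models
#>    ecology -0.11042 0.032 -3.424 0.00062        4
#>  log_brain -0.06791 0.035 -1.939 0.05250        4
#>   tool_use -0.00055 0.042 -0.013 0.98955        4
```

The injected negative terrestrial effect on strength (−0.15) is recovered
with the right sign and a significant conditional average; the strength
trait, simulated with λ = 0.9, shows a strong and significant phylogenetic
signal (somewhat attenuated by subject-sampling noise in the species means —
see the methods vignette).

`run_all()` chains every stage (filtering → laterality → summaries → tests →
signal → ancestral states → PGLS → optional Bayesian models) and writes CSV
artifacts plus a `manifest.json` with a configuration hash and seed.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

re-runs the pipeline end-to-end against the installed package: the packaged
species summaries through the clade-baseline test battery and formatted
table, then a complete synthetic study through generation, laterality,
population tests, λ fitting, ancestral states, PGLS model averaging and the
Bayesian multilevel models, writing the result JSON to `--out`.
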