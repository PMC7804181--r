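---
title: "Disease ascertainment bias in behavioural-trait GWAS and its correction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Disease ascertainment bias in behavioural-trait GWAS and its correction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Self-reported behavioural phenotypes in biobank cohorts — alcohol
consumption is the canonical case — are contaminated by two related
mechanisms:

* **Misreports**: current users reporting exactly zero consumption
  (underreporting) and participants who answer the frequency questions but
  not the quantity question (selective non-response). Both groups carry a
  measurably higher disease burden than complete responders.
* **Longitudinal changes by disease ascertainment**: people who develop a
  disease reduce the behaviour. Their *reported* current level is lower
  than the level their physiology (and genotype) has been exposed to, and
  the reduction is concentrated in the high-liability tail of the cohort.

Together these induce a spurious negative association between the reported
behaviour and disease. The contamination propagates from the GWAS into
every downstream analysis that consumes its summary statistics: SNP-effect
correlations flip sign, instrumental-variable (Mendelian-randomisation)
estimates of the behaviour's causal effect are dragged negative by spurious
instruments, and binned dose–response curves acquire a J shape that looks
like a protective effect of moderate exposure.

`mlcbias` simulates all of this from first principles and implements the
two-step correction:

1. **Phenotype QC** (`qc_filter()`): remove suspected misreporters —
   never-users, zero-consumption current users, non-responders — and, within
   the group that reduced the behaviour, those who reduced it because of
   illness or a doctor's advice.
2. **Stratified scans + meta-analysis** (`stratified_gwas()`,
   `ivw_meta()`): partition by the self-reported longitudinal-change group
   (LESS / SAME / MORE), standardise the phenotype to mean 0, variance 1
   *within* each group (and within sex), scan each group separately, and
   recombine per-SNP effects by fixed-effect inverse-variance weighting.

`mlc_correct()` composes the two steps and clumps the meta-analysis into
independent loci.

## The generative model

`simulate_scenario()` builds a cohort under one of four architectures for
behaviour Y and disease liability D (both unit variance):

* **I** — D independent of Y; only Y is genetic (`n_causal_y` SNPs,
  heritability `h2_y`).
* **II** — Y causally affects D with effect `b_yd` per SD (liability
  scale); D is genetic only through Y. True SNP-effect correlation is 1.
* **III** — independent traits; only D is genetic.
* **IV** — II plus a disjoint set of direct D SNPs (`n_causal_d`, `h2_d`).
  With `b_yd = 0` this is the two-trait null: both traits genetic, true
  SNP-effect correlation 0.

Genotypes are binomial(2, MAF) under Hardy–Weinberg equilibrium, MAF
uniform on `maf_range`, linkage equilibrium by default; an optional
block-AR(1) Gaussian-copula generator induces LD for clumping tests.
Positions sit at 100 kb spacing on one synthetic chromosome. Disease status
is liability above the empirical `(1 - prevalence)` quantile.

Ascertainment (`apply_ascertainment()`) takes the top `q` fraction of
liability (ties broken by index), subtracts `c` SDs of the true behaviour
from their *reported* value, and labels them LESS. Misreporting
(`apply_misreport()`) is Bernoulli with logistic dependence on liability,
the intercept calibrated by root-finding so the marginal rate is exact.

**Default study conditions.** The simulation grids are q in
{0.10, 0.20, 0.30, 0.40} and c in {1, ..., 5}; causal sets hold 100 SNPs.
The remaining parameters are not fixed by the design we emulate, so the
package picks biobank-plausible defaults once and exposes them as
configuration: n = 10,000, m = 1,000, `h2_y = h2_d = 0.3`, `b_yd = 0.3`,
prevalence 0.15, MAF in (0.01, 0.5). Replicate counts in the shipped tests
(5–10 per grid point for surfaces, 50 for locus and curve rates, 100 for
the sign-flip property) were chosen so that Monte-Carlo error is small
against the effect sizes being asserted.

## Why the correction works

Within the ascertained (LESS) group the shift is a group constant, so
within-group standardisation removes it exactly; what remains is selection
on liability, which attenuates within-group effects slightly (range
restriction) but cannot flip their sign. The meta-analysis then restores
full-sample precision. Hence: spurious disease-SNP effects on the reported
behaviour vanish, true-SNP power recovers, and the SNP-effect correlation
returns to its true sign with at most a small downward bias.

In the simulations the default correction is stratification-only
(`qc_rules(drop_illness_reducers = FALSE)`): removing all ascertained
individuals by their recorded reason would trivialise the demonstration,
and the partition itself is the mechanism being studied. On data with
recorded reasons the full rule set applies.

## Two mechanisms, two scenarios

A point that only becomes clear once you derive it: the *direction* of the
bias in the IVW causal estimate depends on the genetic architecture.

* **Scenario II** (everything mediated): the shift multiplies every true
  instrument's reported-behaviour effect by
  `1 - c * b_yd * phi(threshold)` — attenuation, not reversal (a sign flip
  would need `c > 8` at the default `b_yd`). Attenuated exposure betas
  *inflate* Wald ratios, so the uncorrected IVW estimate drifts upward.
  This scenario cleanly exhibits the SNP-effect-correlation story (true
  value 1, estimate driven towards 0 and below).
* **Scenario IV** (direct disease SNPs exist): the biased exposure scan
  hands the instrument-selection step spurious instruments — disease SNPs
  with strong *negative* effects on the reported behaviour and positive
  effects on the outcome. Their Wald ratios are negative and their weights
  large, so the uncorrected IVW estimate falls with ascertainment strength
  and crosses zero at the strongest grid corner (about 0.32 at q = 0.1,
  c = 1 down to about -1.2 at q = 0.4, c = 5 under the defaults), while
  the corrected estimate stays at the true 0.3. This is the
  spurious-locus mechanism, and it is why the package's acceptance checks
  assert the r_b surface on scenario II and the IVW surface on scenario IV.

Similarly, the literal scenario I cannot support an r_b estimate at all:
the disease scan has zero true effect variance, so the error-corrected
moment estimator is undefined there and raises
`mlcbias_unstable_rb_error` by design. The two-trait null used throughout
(scenario IV with `b_yd = 0`) keeps the defining feature — orthogonal true
effects — while giving both scans identifiable effect variance.

## The r_b estimator

For aligned summary sets, with per-SNP estimates `b_k` and standard errors
`se_k` (k = 1, 2):

* `var_true_k = var(b_k) - mean(se_k^2)`,
* `cov_true = cov(b_1, b_2) - r_p * mean(se_1 * se_2)`, where the error
  correlation `r_p` is the mean product of z-scores at null SNPs (|z| < 2
  in both scans) when the samples overlap, 0 otherwise,
* `rb = cov_true / sqrt(var_true_1 * var_true_2)`, clamped to [-1, 1] with
  the raw value retained, SE by delete-one-SNP jackknife.

When an error variance exceeds the corresponding effect-size variance the
estimate is refused with diagnostics rather than returned as noise. In
simulations the estimation SNP set defaults to the union of true causal
sets; on real summary statistics use the clumped significant SNPs.

## The down-sampling excess test

Losing individuals costs loci, so "the correction removed 16 loci" is only
evidence of bias if 16 exceeds what the sample-size loss explains.
`downsample_excess()` removes `n_remove` individuals uniformly at random,
rescans, reclumps, and counts full-scan loci with no down-sampled lead
within the clump window (reciprocal matching; the locus-matching convention
is ours, as no standard exists). The default statistic is
`z = (observed - mean) / sem` with a normal reference — the right test when
the observed count is a fixed quantity compared against the down-sampling
*expectation*. When the observed count is itself one draw of the same
process, that statistic is over-dispersed by construction; the
`observed_is_draw = TRUE` mode therefore tests against the predictive
distribution (`sd * sqrt(1 + 1/reps)` scale, t with `reps - 1` df), which
is the version that is uniform under resampling — the package's
calibration test exercises exactly this.

## The J shape

With risk increasing in the true behaviour, ascertained individuals are
high-risk and their reported values land in the low bins — including the
lowest ("moderate") bin conventionally used as the odds-ratio reference.
The contaminated reference inflates the baseline odds, pushing
mid-range bins below 1 and creating an interior minimum. `risk_curve()`
reports per-bin odds ratios (Woolf intervals), the change-group composition
of every bin, and supports excluding the LESS group *from the reference
side only* — after which the curve is monotone increasing again.
`pgs_curve()` shows the complementary fact: a polygenic predictor of the
exposure, trained on a disjoint split (enforced, seeded), inherits a true
J-shaped dose–response but shows no protective dip when the true relation
is monotone. The shipped J-shape experiment uses n = 8,000, a 0.3-prevalence
disease with `b_yd = 0.6`, ascertainment (q = 0.15, c = 3), and four bins at
the 0/30/55/80/100 percentiles of the reported behaviour, the lowest bin
being the reference.

## Numerical choices and edge cases

* Scans use the Frisch–Waugh–Lovell decomposition; betas and SEs match the
  full normal-equations fit to 1e-8 (tested against `lm()`). P-values are
  two-sided normal by default (`exact_t = TRUE` for the t reference);
  monomorphic SNPs are flagged, never estimated.
* Clumping is greedy on p with ties broken by position then id; the lead
  kills candidates within the window *or* above the r² threshold, so the
  surviving leads form an antichain under both rules.
* Group-wise standardisation screens raw values outside mean ± 7 SD, then
  |z| > 5 after covariate adjustment, then re-standardises so retained
  group moments are exactly (0, 1). The ±7 SD screen applies to the
  transformed consumption scale by default (`outlier_screen_stage`), a
  convention made explicit because either order is defensible.
* Percentages in accounting tables are half-up rounded at one decimal,
  matching the presentation convention of cohort descriptor tables.
* All randomness flows from one root seed through labelled sub-streams
  (`derive_seed()`), so any stage reruns bit-identically in isolation.

## Limitations

The generator omits realistic LD structure, relatedness, imputation error
and chip artefacts; individuals are unrelated, so per-SNP OLS replaces the
mixed-model scans used at biobank scale, and odds-ratio transforms for
binary traits are out of scope. Passing tests therefore demonstrate the
*logic* of the bias and its correction under the stated generative model,
not the magnitude of either in any particular real cohort. Misreport
mechanisms are memoryless Bernoulli; real selective recall is likely more
structured. The LESS/SAME partition in simulation is two-group; the
three-group mode exists for pipeline generality but is not the default.
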