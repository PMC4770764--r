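---
title: "Methods: models, conventions and design choices in myelomiR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, conventions and design choices in myelomiR}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
library(myelomiR)
options(myelomiR.verbose = FALSE)
```

myelomiR re-implements, as reusable and tested components, the complete
statistical workflow of an array-based miRNA/mRNA profiling study of
plasma-cell dyscrasias. This vignette explains the models behind each
stage, the tunable parameters and their defaults, what the synthetic
cohorts do and do not emulate, and the design decisions taken where the
methodology was genuinely open.

## Preprocessing

Raw array signal is made positive by adding a constant c chosen so the
global minimum becomes exactly 1 (`scaled_log2()`, `offset = "auto"`
gives c = 1 − min), then log2-transformed; the log2 minimum is therefore
exactly 0. The constant is data-dependent and stored, never hard-coded:
for the miChip data this package models, the study-scale value was 114,
but every data set computes its own. We read the constant as *additive*:
a multiplicative constant cannot in general make the minimum equal 1.

Normalization is rank-invariant (`fit_invariant_normalization()`,
`apply_normalization()`). The frozen model consists of a per-probe
reference profile — by default the probe-wise median pseudo-sample of
the training cohort, chosen because it is symmetric, reproducible and
storable — plus the selection settings. Each sample is then processed
independently:

1. iterated selection of approximately rank-invariant probes: keep
   probes with |rank in sample − rank in reference| / n below
   `threshold` (default 0.05), re-rank, repeat to convergence
   (`max_iter` 10);
2. a monotone piecewise-linear mapping through matched quantiles
   (`n_knots` 30) of the invariant probes on each side. Because knot
   ordinates are quantiles of each side separately, monotonicity holds
   by construction; tails extrapolate with the end-segment slopes.

Within-sample rank order is preserved exactly (monotone mapping), a
sample identical to the reference maps to itself, and a global affine
distortion — which leaves ranks unchanged — is removed essentially
exactly. If the invariant set falls below `floor_size` (default 20) the
model refuses with advice to relax the threshold, rather than fitting a
mapping through too few points. The 5% proportional window presumes
array-scale probe counts, so the default widens to `max(0.05, 25/n)`
(with a correspondingly reduced floor) on small matrices — at the
559-probe study scale both defaults are unchanged; the adaptation
matters only for toy fixtures.

## Differential expression

Two-group probe-wise linear models (`fit_probe_models()`) reduce to the
difference of group means with the pooled within-group variance; the
first-named group of the contrast is the baseline for sign conventions
(positive = up in that group). Average expression is computed over the
contrasted samples only — whether it should instead span all samples is
not decidable from the source methodology, so the choice is explicit
here and surfaced in the output.

`ebayes_moderate()` implements moderated t-statistics: variances are
modelled as draws around a scaled inverse-chi-square prior (d₀, s₀²),
estimated by the method of moments on log s² (matching the first two
moments of the log of a scaled F distribution). The posterior variance
is the convex combination (d₀s₀² + ds²)/(d₀ + d) and the statistic gains
d₀ degrees of freedom. When the observed log-variance dispersion does
not exceed its sampling component, d₀ = ∞ and the arithmetic mean of
the variances is used — the same convention as the standard reference
implementation, with which the suite cross-checks numerically. Probes
with numerically zero residual variance are excluded from estimation and
flagged. `prior_df = 0` recovers the ordinary t exactly (used as a
limiting-case test).

Multiplicity control is Benjamini–Hochberg at level 0.05 throughout
(`bh_adjust()`), and p-values are two-sided. The signed fold change is
FC = 2^logFC for logFC ≥ 0 and −2^(−logFC) otherwise; printed tables
round **half away from zero** to one decimal — this convention
reproduces all 67 (logFC, FC) pairs of the bundled reference table,
which the acceptance suite asserts exactly. Reported percentages use the
same rounding on 100·k/n.

## Survival analysis

`cox_fit()` wraps the partial-likelihood Newton solver of the survival
package with Efron tie handling (better small-sample behaviour than
Breslow; the choice was not specified in the source methodology and is
configurable). Rank-deficient designs and monotone likelihoods raise
errors instead of returning runaway coefficients. An independent
brute-force oracle (direct Efron partial log-likelihood, grid/golden
maximization) pins the coefficients in the test suite.

`maxstat_cutpoint()` evaluates the standardized two-group log-rank
statistic at every distinct threshold whose left-tail proportion lies in
the quantile window (default 0.1–0.9; common practice, logged), taking
`x ≤ c` as the low group. The maximum is reported with the
Lausen–Schumacher improved-Bonferroni approximation

P(sup |Z| > b) ≈ φ(b)(b − 1/b)·log[(1−ε₁)ε₂ / ((1−ε₂)ε₁)] + 4φ(b)/b,

which the null-calibration tests show holds its level (empirical
rejection ≈ 0.04–0.06 at nominal 0.05 for n ≈ 60–200). A permutation
p-value (`pmethod = "permutation"`) is available as a small-n reference.
`dichotomize_and_compare()` additionally reports the log-rank p at the
selected cutoff with an explicit logged caveat that this p is optimistic
because the cutoff was optimized; the adjusted maxstat p is the honest
quantity.

## The risk signature

`build_signature()` implements the four-step supervised-PCA score on a
small panel of survival-relevant features:

1. center features; first two principal axes of the centered
   feature-by-sample matrix (unscaled covariance PCA — all features
   share the log2 scale; a correlation variant was considered and
   rejected as it would silently reweight features); per-sample
   projections (w₁, w₂);
2. bivariate Cox fits of (w₁, w₂), separately for EFS and OS;
3. β̄ = element-wise mean of the two coefficient pairs; the per-sample
   score is the **inner product** β̄·(w₁, w₂) — the only reading of a
   "vector product" of a coefficient pair with a projection pair that
   yields a scalar score;
4. maxstat cutoff on the training scores. The cutoff search needs one
   endpoint; EFS (the primary endpoint) drives it by default,
   configurable via `cutoff_outcome`.

Axis signs are fixed (largest-magnitude loading positive) for
reproducibility; scores are provably invariant to that convention and to
feature order, and both invariances are tested. If the second singular
value is numerically zero (e.g. duplicated features) the signature
degrades to the first axis with zero second loadings, flagged.

Whether a *low* or *high* score marks the adverse group is
data-dependent (the Cox coefficients can take either sign); the package
reports the direction rather than assuming one.

**Documentation-by-value.** The signature freezes feature ids, centers,
loadings, β̄, the cutoff, and optionally the normalization model, and
serializes losslessly to JSON. `apply_signature()` re-scores any cohort
through exactly these constants — the frozen reference profile first
(per-sample invariant mapping), then frozen centers and loadings — with
no refitting, and `use_documentation = FALSE` provides the deliberately
naive ablation used to demonstrate that the frozen preprocessing is what
makes transfer work. Signature training must run on the same normalized
scale that transfer will use; the pipeline therefore normalizes the
training cohort with the same frozen model. Group assignment uses a
relative tolerance of 1e-9 at the cutoff so that a sample lying exactly
on the cutoff (the cutoff is itself a training score) classifies stably
across serialization round-trips.

`build_target_score()` applies the identical construction to the
expression of one miRNA's consensus-predicted target genes.

## Targets, correlations, associations

`consensus_targets()` keeps genes called by at least `min_tools`
(default 6) of the 7 prediction algorithms. `variance_filter()` keeps
the ⌈fraction·n⌉ most variable probes (ties broken by probe id);
dropping the "80% least variable" of 559 probes retains 112. Note the
filter is *not* idempotent under re-application at the same fraction
(⌈0.2·112⌉ = 23 ≠ 112); the intended usage is a single pass on the full
matrix, and the tests pin the count, determinism and subset property
instead. On the mRNA side the same filter is applied; published probe-set
counts for that side imply an additional upstream filter that is not
recoverable, so no count is asserted for real mRNA data.

`correlation_screen()` computes all miRNA×mRNA Pearson correlations over
shared samples, BH-adjusts over the full tested family, and retains
|r| ≥ 0.6 with adjusted p ≤ 0.05. Manual plausibility curation of hits
is replaced by a reproducible surrogate: a leave-one-out influence flag,
set when removing any single sample drops |r| below the retention
threshold. This is an explicit stand-in, not a reconstruction of the
original subjective review.

`global_association()` is a score-type set test: with centered feature
matrix X (samples × p) and null-model residuals r (intercept-only
residuals for continuous/binary outcomes; martingale residuals from a
null Cox model for survival), Q = rᵀ(XXᵀ/p)r, with significance by
permutation of the residuals (default 10⁴; tests use fewer). Permutation
was chosen over the asymptotic distribution as assumption-light and
directly testable for calibration.

## Clustering

`pearson_dissimilarity()` is 1 − r between samples with the standard
mean-centered Pearson r (the "centered" qualifier distinguishes it from
the uncentered cosine variant in the clustering-software vocabulary).
`average_linkage()` is a from-scratch UPGMA with a deterministic
lexicographic tie-break, returning a standard `hclust` object; the suite
checks it against `stats::hclust` on random instances. All probes are
used by default (no pre-filtering was described for the unsupervised
analysis); a variance filter can be applied upstream if desired.
`cluster_purity_report()` reports, per diagnostic group, the smallest
containing clade and whether the group forms a pure sub-branch.

## The synthetic cohorts

`generate_cohort()` emulates the data structure the analysis assumes, at
the study's scale: 559 miRNA probes; 62 myeloma, 7 MGUS, 3 pooled-normal
and 20 cell-line samples; 53 myeloma samples with EFS/OS; an independent
345-sample validation cohort. Defaults mirror the observed magnitudes:
planted |log2FC| in [0.44, 2.2] (|FC| ≈ 1.4–4.6), planted miRNA→mRNA
links at |r| = 0.7, five prognostic probes at log-hazard 0.7 per SD.
Where the stated world fixes no value we chose once, on field
plausibility, and did not revisit:

* probe-level baselines N(9, 1.2²) (published per-probe averages span
  ≈ 8–13 on the log2 scale) with probe variances from a scaled
  inverse-chi-square (d₀ = 4, s₀² = noise_sd²), so the empirical-Bayes
  hyperparameters have a true value to recover;
* MGUS samples receive 60% of the myeloma effect on a random 30% of the
  differential probes (premalignant samples resemble myeloma more than
  normal);
* cell lines get large global shifts (±1–3 log2 units on 40% of probes),
  which is what makes them segregate into their own cluster branch;
* the five prognostic probes share a latent per-sample factor carrying
  half their variance: survival-relevant miRNAs in real cohorts co-vary
  through a common biological axis (family members, proliferation), and
  that shared axis is precisely what a principal-component summary can
  capture. Survival is exponential proportional hazards on the
  standardized-probe linear predictor, with uniform censoring calibrated
  by root-finding to the target censor fraction (default 0.35, a typical
  transplant-cohort figure);
* aberration prevalences (t(4;14) 15%, t(11;14) 20%, del17p 10%,
  gain1q21 35%, del13q 45%, hyperdiploid 50%) are plausible myeloma
  frequencies used only as defaults;
* the validation cohort is distorted by a global affine map
  (shift 1.5, slope 0.9) so that frozen-parameter transfer is exercised
  nontrivially — rank-based normalization must undo it, naive transfer
  must not;
* risk indices (GPI/UAMS/IFM-type) are noisy linear combinations of
  designated probes, giving the association tests planted signal.

What the generator does **not** emulate: spot-level array artifacts,
probe cross-hybridization, batch effects, non-proportional hazards,
competing risks, or the correlation structure of a real transcriptome
(null genes are independent). A green recovery test therefore
establishes that the estimators recover the stated generative structure
at the stated scale — not that they would behave identically on any
real cohort.

All randomness flows from one master seed through named substreams, so
every stage is independently reproducible and fixture files are
byte-identical across runs.

## Numerical conventions and degenerate inputs

* Printed rounding is half-away-from-zero (base R rounds half to even).
* Expression TSVs carry a `#scale=` sidecar line; values print with 15
  significant digits so decimal representations round-trip exactly.
* Cox convergence is Newton to ε = 1e-9 with singularity and
  perfect-separation detection; maxstat requires ≥ 2 in-bounds candidate
  cutoffs and ≥ 10 samples; constant markers are rejected.
* Zero-variance probes are excluded (with a warning) from correlation
  screening and (with an error naming the sample) from Pearson
  dissimilarity.
* BH adjustment validates p ∈ (0, 1] and is permutation-equivariant.

## Known limitations

* Only two-group (and implicitly paired, via differencing upstream)
  contrasts; no multi-factor designs or array weights.
* No time-dependent covariates, stratified Cox, or competing risks; no
  recalibration of transferred cutoffs (deliberately, as the transfer
  design forbids it).
* The invariant-normalization reading (rank-invariant selection +
  monotone quantile mapping) is one standard interpretation of a method
  the source literature cites but does not specify; its contracts
  (identity, shift removal, distortion correction, rank preservation)
  are what the tests enforce.
* The consensus filter consumes prediction tables as data; the seven
  prediction algorithms themselves are out of scope, as are the gene
  memberships of published risk scores (consumed as per-sample values).
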