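---
title: "Methods: censoring-aware normalization and paired comparison of multiplex cytokine panels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: censoring-aware normalization and paired comparison of multiplex cytokine panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(xplexnorm)
```

## The data model

A bead-immunoassay run reports, for each patient and analyte, either a
concentration in pg/mL or the fact that the signal fell outside the standard
curve. `xplexnorm` keeps both: every cell of an `xplex_panel` carries a
status — `measured` (within `[LLOD, ULOD]`), `extrapolated` (a value the
instrument software extrapolated below the lowest standard), `below_range`
or `above_range` (no value at all). Out-of-range cells are *initially
missing*, not absent: a missing row is a data error, not a censored value,
and the readers enforce that distinction.

Plasma is assayed after 1:1 dilution with assay buffer, so its panel carries
`dilution_factor = 2`; neat conditioned medium carries 1. The dilution
factor enters only where the substitution and interval rules need it (below),
never as a blanket rescaling of reported values: what the instrument
software reports is treated as final.

## Censoring: substitution and intervals

Two encodings serve the two statistical branches:

* **Point substitution** (`impute_points`) for the quantitative branch:
  below-range cells become `llod * dilution_factor / 2` — LLOD/2 in neat
  medium, LLOD in 1:1-diluted plasma — and above-range cells
  `ulod * dilution_factor` (ULOD, respectively 2·ULOD). One formula
  reproduces both specimen-specific rule sets; measured and extrapolated
  values pass through untouched.
* **Intervals** (`build_intervals`) for the qualitative branch: observed
  values become point intervals `[v, v]`; censored cells become
  `[0, llod * d]` or `[ulod * d, Inf]`. Every substituted point lies inside
  its cell's interval, a property the test suite asserts across seeds.

**The 40% routing rule.** An analyte whose pooled missing-or-extrapolated
fraction is below 0.40 is compared quantitatively, otherwise qualitatively.
Two details are genuinely underdetermined and were fixed as follows:

* *Denominator*: pooled over both panels (2 × n patients). The comparison is
  paired across specimen types, so the pooled denominator is the only
  symmetric choice.
* *Exactly 40%*: routed to the qualitative branch. Substitution-imputed
  values are least trustworthy exactly when censoring is heavy, so the
  interval branch — which makes no numeric claim for censored cells — is the
  conservative side of the boundary.

## Reference selection

Candidates are the *complete* analytes: measured in every cell of both
panels. Stability is GeNorm on linear concentrations, pooling the plasma and
medium samples into one set (2 × 23 = 46 samples in the emulated design):
the ranking should describe stability across the whole material the
normalization factor will be applied to, and the published analysis ranks
one set spanning both materials. Conventions: log base 2, sample (n−1)
standard deviation, arithmetic-mean `M`, classic stepwise exclusion with
recomputation after each removal, max-`M` ties broken by input order with a
recorded note (determinism over elegance).

The NF series uses per-sample geometric means — the correct average for a
multiplicative sample-scale model, and invariant in ratio terms to
per-sample scaling. `V(n/n+1)` decides how many references are worth
carrying; the Spearman matrix over {top-pair singles, NF2..NFK} shows the
same information as correlation.

**The screen.** A reference that itself differs between specimen types after
normalization would bias everything downstream. Starting from the V-optimal
member set, each member is normalized by the current NF and tested (paired
Wilcoxon, BH across the round's members); if any fail, the *least stable*
differential member is dropped and the screen repeats. Dropping one member
per round, least stable first, matters: dropping all differential members at
once can overshoot, because a single unstable member (e.g. a third-ranked
cytokine) can drag an otherwise valid reference into apparent
differentiality — removing the cause rescues the victim on the re-screen.
An empty surviving set raises an error advising a manual choice; the
automatic selection can always be overridden by pinning
`analyze_study(..., references = c(...))`, e.g. when external evidence
(mRNA expression of a candidate) informs the choice.

## The two branches

* **Quantitative** — paired two-sided Wilcoxon signed-rank on normalized
  values, zero differences dropped, exact small-sample null when untied
  (`stats::wilcox.test` semantics). Direction is the sign of the median
  paired difference.
* **Qualitative** — per pair, the two (normalized) intervals either
  intersect — a tie, with touching endpoints counted inclusively as
  intersection — or one lies wholly above, scoring for that specimen. Ties
  are excluded and the exact two-sided binomial sign test is applied:
  `p = min(1, 2·min(P(X ≤ min), P(X ≥ max)))`, `X ~ Bin(n⁺ + n⁻, ½)`.
  The whole construction is invariant to monotone rescaling applied to both
  members of a pair, which is what makes it robust to the censoring.

Interval endpoints are divided by the per-sample NF before comparison: the
qualitative branch compares *normalized* levels, like the quantitative one,
and since each specimen's sample has its own factor, this is not a no-op.

BH adjustment is applied once, jointly across the non-reference analytes of
both branches: the published account describes a single correction over
"multiple comparisons of cytokines", and one family of 39 is the
conservative single-family reading. Classification at α = 0.05: adjusted
p ≤ α in the plasma direction ⇒ `elevated_in_plasma`, in the medium
direction ⇒ `elevated_in_medium`, otherwise `not_differential`. References
are appended as non-differential rows (they passed the screen; they are not
re-tested against themselves).

## Co-regulation clustering

Candidate references that rise and fall together may be co-regulated, which
inflates apparent stability. Ward-linkage agglomeration
(`stats::hclust(method = "ward.D2")`, verified against a brute-force
minimum-ESS oracle) runs per specimen type on the quantitatively analysable
analytes, *unnormalized* to avoid circularity. Two open choices:

* **Input scale**: log2 by default. Euclidean distance on raw pg/mL would be
  dominated by the most abundant analytes; log2 makes distances comparable
  fold-change distances. `scale = "raw"` is exposed for sensitivity checks.
* **Flat cut**: at the largest gap between consecutive merge heights
  (overridable by `k`). The gap criterion separates the cheap, tight merges
  from the expensive late ones without a tuned constant.

A positive flag (`references co-cluster`) is a caveat, not an error: the
analysis proceeds, as the published workflow did, but the caveat is printed.

## qPCR verification

Relative expression is ΔCt-based: `2^−(Ct_target − Ct_ref)` against a
reference gene (UBC by default), assuming ~100% amplification efficiency
(efficiency modelling is out of scope). Undetected targets receive a floor
(default 1e-4) flagged `detect = FALSE`; the floor is validated to sit at
least two-fold below the smallest detected value, warning otherwise. Because
published accounts alternate between ΔCt and ΔΔCt displays, both are
exposed: `relative_expression()` for 2^−ΔCt and `calibrate_expression()`
for ΔΔCt against a chosen calibrator population. Comparisons between
populations are paired Wilcoxon tests on the relative values, floored
values included.

## The synthetic world

`generate_study()` draws latent log2 concentrations
`baseline + scale_s + effect·[medium] + N(0, residual_sd)`, exponentiates,
and censors at the analyte's limits; a sub-LLOD cell is emitted as an
extrapolated value (carrying its latent concentration) with probability 0.3,
else as `below_range`. The per-sample scale factor `scale_s ~ N(0, 0.5²)`
(≈1.4-fold typical swing, a realistic sample-to-sample loading variation for
bead assays) is shared by *all* analytes of a sample. That choice is what
makes the generator a meaningful test of the pipeline: a shared
multiplicative sample factor is exactly the distortion geometric-mean
reference normalization is built to remove, so parameter recovery tests the
method, not the generator.

`study_preset()` mirrors the emulated study's structure: 23 pairs,
41 analytes; five analytes uncensorable by construction (the candidate
pool), of which two (zero effect, residual sd 0.15) are the designated
stable pair; six analytes planted higher in plasma and twenty-two higher in
medium (|effects| of 2–5 log2 units); heavy plasma censoring for the
low-abundance analytes so that roughly nine non-reference analytes route to
the quantitative branch. Defaults were chosen once from the emulated
design's stated regime and are not tuning knobs.

What a green synthetic test does *not* establish: the generator is
log-normal with symmetric noise and an exactly shared scale factor — real
panels have analyte-specific assay noise, correlated biology (co-regulation
beyond the planted scale), plate effects, and a censoring mechanism coupled
to the standard curve, none of which are modelled. Recovery on the preset
shows the pipeline is correct under its own assumptions, not that those
assumptions hold for any particular dataset.

## Numerical and testing choices

* Exact tests are enumerated, not approximated: the test suite checks the
  Wilcoxon branch against full 2^n enumeration (n ≤ 10) and the sign test
  against the binomial pmf directly; GeNorm and Ward are checked against
  naive brute-force reimplementations.
* The stochastic recovery suite fixes its replicate counts (200 for the
  stability ranking, 500 for the null false-discovery rate, 100 for
  planted-effect recovery, 200 per effect level for power monotonicity) and
  its tolerance for Monte-Carlo noise in the power curve (0.1 between
  consecutive effect levels, ≈2 binomial standard errors of a difference of
  proportions at 200 replicates) a priori.
* Degenerate inputs are defined, not accidental: all-zero paired differences
  give p = 1 with direction `none`; an all-tie sign test likewise; constant
  vectors make Spearman correlations `NA` with a warning; max-`M` ties break
  by input order with a recorded note.

## Known limitations

* Substitution imputation and interval substitution follow the published
  rules; no censored-likelihood (Tobit-style) modelling is attempted.
* The screen's one-at-a-time drop order is a deterministic refinement of a
  judgment-laden published procedure; other defensible orders exist and can
  be bypassed by pinning references.
* With fewer than three complete analytes the GeNorm step is undefined and
  references must be pinned manually.
* qPCR quantification ignores amplification-efficiency differences between
  targets and reference.
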