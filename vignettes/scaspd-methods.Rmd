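---
title: "Methods: scoring, agreement statistics and synthetic cohorts in scaspd"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: scoring, agreement statistics and synthetic cohorts in scaspd}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scaspd)
```

## The scoring model

SCAS-PD observes twelve clinical signs of impaired swallowing over three
food offerings (20 ml thin liquid, 10 ml paste, one solid cracker). The
package models the raw data as a binary 12 × 3 *observation grid*: a sign
either occurred during an offering or it did not. This binary-per-offering
convention is a deliberate modelling choice: the instrument's published
per-sign maxima equal exactly three times the per-offering weight, which is
only consistent with at most one scored occurrence per offering; counting
repeated events within an offering would break that bound.

Scoring is then a weighted sum. Each flagged cell contributes the item's
weight; phase subscores sum the cells of the oral (max 18), pharyngeal
(max 66) and penetration/aspiration (max 270) items, and the total ranges
0–354. Two invariants follow directly and are enforced by property tests:
flipping any flag from 0 to 1 never decreases any subscore, and the total
equals the sum of the three per-offering scores.

Weights are carried as doubles (they are printed with decimals), so
non-integer weightings load cleanly from the JSON instrument configuration;
with the canonical weights all attainable totals are integers.

**Offerings that cannot be administered.** A patient too impaired to ingest
one consistency is handled by `impute_offering()`: all flags of that
offering are set to 1 (the offering scores at its maximum) and the record is
marked. This mirrors how such cases are handled in practice — the inability
to swallow a consistency is itself maximal evidence of impairment at that
consistency. The alternative (scoring a refused offering 0) is available by
simply not imputing; imputation is the default the readers honour because
scoring an unadministrable offering as unremarkable would bias severity
downward.

**Item naming.** Items use snake_case identifiers derived from their tabular
labels. The first oral item appears in the literature both as "prehension of
food" and as "altered lip closure"; the package treats these as one item
(`lip_closure`) and resolves the alias on input, along with other common
spelling variants.

## Severity bands

A severity scheme is an ordered list of bands tiling [0, 354] with
inclusive upper bounds and exclusive lower bounds — both published schemes
are phrased that way ("functional >3 ≤ 19"), so a score sitting exactly on a
cutoff belongs to the band below. `classify_severity()` enumerably
satisfies: every integer 0–354 receives exactly one label, and labels are
non-decreasing in the score. Two canonical schemes ship:

| scheme | bands |
|---|---|
| preliminary | normal ≤2, functional ≤15, mild ≤35, moderate ≤60, severe ≤354 |
| revised | normal ≤3, functional ≤19, mild ≤35, moderate_severe ≤354 |

The revised scheme merges moderate and severe; when agreement statistics
compare it against the five-level VFSS scale, the deeper VFSS levels
collapse into the scheme's last band (rank 3) so the cross-table stays
square on one ordinal scale.

## Agreement statistics

All statistics are implemented from their definitions; installed packages
(`pROC`, base `aov`) serve only as independent cross-checks in the test
suite.

**ICC.** The intraclass correlation of the ordinally encoded severity
ratings (index test vs gold standard, ranks 0..k−1) is computed from the
two-way ANOVA mean squares. The default form is two-way random effects,
absolute agreement, single measures — ICC(2,1) — because the two "raters"
are different measurement instruments whose systematic offset should count
as disagreement, and because it is the common default of clinical
statistics software. One-way and consistency forms, and average-measures
units, are selectable. Confidence intervals use the exact F distributions
of the mean-square ratios; ICC(2,1) uses the Satterthwaite approximation
for the denominator degrees of freedom. The p-value tests ICC = 0 via
F = MSR/MSE (or MSR/MSW for the one-way model).

**Weighted kappa.** Disagreement weights are `|i−j|/(k−1)` (linear,
default) or its square (quadratic). Unqualified "weighted kappa" most often
means linear weights in the clinical agreement literature, hence the
default; both are exposed because the choice is consequential (quadratic
weights forgive near-misses more). Standard errors follow the
Fleiss–Cohen–Everitt large-sample formulas, both under the null (for the
p-value) and around the estimate (used by the parameter-recovery tests; the
formula was verified against Monte-Carlo dispersion during development). A
table with all mass in one cell has zero expected disagreement; kappa is
defined as 1 there and flagged with a warning rather than erroring, since
perfect one-category agreement is a legitimate degenerate cohort.

**Per-level kappa.** Published per-severity agreement rows do not specify
their construction; the package uses one-vs-rest binarization at each level
with unweighted Cohen's kappa — the simplest construction that yields one
coefficient per level and reduces to the 2 × 2 closed form
`2(ad−bc)/((a+b)(b+d)+(a+c)(c+d))`. Levels absent from a cohort are
reported as not estimable instead of failing the run.

**ROC analysis.** The positivity convention is *score > threshold*, so a
reported cutoff is the largest score still classified negative — matching
the band phrasing (19 is the last non-dysphagic score under the revised
scheme). The trapezoidal AUC of the empirical curve equals the Mann–Whitney
concordance probability with ties counted ½ (a property test checks this on
1000 random tied instances). Confidence intervals: DeLong placement-value
variance by default (deterministic), or a seeded percentile bootstrap that
redraws degenerate single-class resamples with a hard cap. The
Youden-optimal cutoff maximizes sensitivity + specificity − 1 over the
distinct observed scores; ties prefer higher sensitivity (a screening
instrument must not miss dysphagia), then the lower cutoff. Tie detection
uses an absolute tolerance of 1e-9 on J, because mathematically equal J
values computed from different sensitivity/specificity pairs can differ by
machine epsilon.

**Cronbach's alpha** runs on the patients × 12 matrix of per-item scores
(weight × number of offerings flagged), in total and per phase domain. The
variance-denominator convention cancels in the ratio provided it is uniform
(asserted by test); sample variances are used. Alpha below 0 is reported
unclamped with a warning. Zero total variance or a single item are errors —
the statistic is undefined, and silently returning a number would mask a
degenerate cohort.

## The synthetic cohort generator

`generate_cohort()` emulates a paired validation study: a latent severity
level per patient drawn from a configurable five-level distribution, an
assessment record whose total lands inside the corresponding band, and a
VFSS label drawn from a confusion kernel applied to the latent level.

Defaults are the package's fixed study conditions: n = 31 and severity
probabilities 7/5/6/6/4 (renormalized — the published cohort's count
columns are internally inconsistent with its stated n, so the clinical
column is taken as the shape and rescaled to a proper distribution). The
default concordance is 0.8: the kernel `K = c·I + (1−c)·U` (U's rows equal
the severity distribution) has population linear weighted kappa exactly
equal to c, and 0.8 places the simulated agreement in the "good concordance"
range reported for instruments of this type while leaving visible
off-diagonal mass. That analytic identity is what the recovery tests
exploit: at n = 5000 the estimated kappa must fall within 3 standard errors
of c.

Profile sampling is rejection sampling: a target total is drawn uniformly
from the band's attainable integers, all 36 flags are drawn Bernoulli with
probability target/354 (making the expected total equal the target), and
the grid is accepted if it classifies into the band. After 1000 rejections
a deterministic greedy construction takes over: cells are walked in
decreasing weight order and flagged whenever they still fit the target.
With cell weights {1×6, 2×9, 10×9, 15×6, 20×3, 30×3} this greedy walk
reaches *every* integer in 0–354 exactly — once the large denominations are
exhausted the remainder is at most 24, which the 2- and 1-point cells cover
contiguously — so termination and band membership are guaranteed, and the
round-trip invariant (sample, score, classify ⇒ target band) holds
unconditionally.

A coherence preference (on by default) rejects grids in which a
penetration/aspiration sign appears in an offering with no pharyngeal sign,
reflecting that airway compromise rarely presents without pharyngeal-phase
abnormality; the greedy fallback orders pharyngeal cells before PA cells at
equal weight but may relax the preference, which is why it is documented as
a preference rather than an invariant.

**What the generator does not emulate.** Item-level prevalence within a
band is uniform (no published per-sign frequencies exist to calibrate it);
there are no within-patient correlations across offerings beyond the
coherence toggle, no covariate structure (age, disease stage) linked to
severity, and no disease progression. Passing validation on these cohorts
therefore demonstrates the correctness of the statistical pipeline, not
clinical performance on real patients.

## Determinism and problem sizes

Every stochastic routine takes an explicit seed, and seeded runs are pure
functions of their inputs: the same spec yields byte-identical CSVs, and
`simulate → validate → report` yields byte-identical JSON and markdown
(numeric output is serialized at 6 significant digits for stable diffs).
RNG state is saved and restored around seeded code, so library calls never
perturb a caller's stream.

The test suite sizes its simulations for tight feedback while keeping
estimates meaningful: 1000 random instances per oracle-equivalence check at
tolerance 1e-10, n = 5000 with 3 seeds for kappa recovery, and n ≈ 30–60
cohorts elsewhere. Bootstrap defaults to 2000 replicates in the API and is
reduced in tests where only determinism, not interval width, is under test.

## Known limitations

* The ICC p-value for the absolute-agreement form reuses the consistency
  F statistic (the standard practice); its interval, not its p-value,
  accounts for the rater variance component.
* The asymptotic kappa standard errors are large-sample; at n ≈ 31 they
  are indicative only, which is one reason the acceptance checks that
  compare against analytic values run at n = 5000.
* Per-level kappa's one-vs-rest construction is one of several defensible
  readings of per-severity agreement tables; with a published joint table
  it could be adjudicated, without one it is a documented convention.
* The generator's uniform-within-band profiles make domain alphas
  (particularly the 3-item pharyngeal domain) noisier than a real cohort
  with correlated signs would be.
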