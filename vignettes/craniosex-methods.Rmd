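---
title: "Methods: virtual morphoscopic sex estimation and observer agreement"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: virtual morphoscopic sex estimation and observer agreement}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(craniosex)
```

## The problem

Morphoscopic sex estimation scores visually assessed cranial traits on
an ordinal 1–5 robusticity scale and converts the scores to a sex call
with a published discriminant function. When the scoring happens on
virtual 3D cranial models rather than dry bone, two measurable
questions decide whether the approach is usable: how strongly do
independent observers agree on the ordinal scores, and how accurately
do their scores classify sex against recorded ground truth. This
package implements that full evaluation pipeline — estimation,
agreement, accuracy — together with the embedded eight-observer,
twenty-crania study tables it was built around and a simulator for
stress-testing the statistics.

## The discriminant

The built-in classifier is the two-trait logistic discriminant

$$Y = -1.568\,g - 1.459\,m + 7.434,$$

where $g$ and $m$ are the glabella and mastoid-process scores. Both
coefficients are negative: robust (high-scoring, typically male)
crania drive $Y$ negative, and the cut-off is 0 — male if $Y < 0$,
female if $Y > 0$. Any coefficient set over the three supported traits
can be supplied through `discriminant_spec()`; only this equation
ships because it is the only one applicable when just these two traits
are observable. Coefficients are inputs, never re-fitted.

The sex probabilities reported alongside each call are the logistic
transform $p_\text{female} = 1/(1+e^{-Y})$, $p_\text{male} =
1-p_\text{female}$. The source tables print probabilities without
stating the formula; the logistic transform is adopted because it
reproduces the printed whole-percent pairs across both embedded tables
(155 of 158 estimable cells; the other three are flagged
inconsistencies discussed below). Three conventions follow the tables:
displayed percentages are rounded half away from zero (0.9566 → 96);
$Y$ exactly at the cut-off is labelled `indeterminate` rather than
guessing a side (no such case occurs in the embedded data); and a
cranium missing any required trait score yields the label `missing` —
a value, not an error, so downstream policies can decide how to treat
it.

## Agreement statistics

**Kendall's W (tie-corrected).** For $m$ raters scoring $n$ items,
each rater's values are converted to mid-ranks (ties receive the mean
of the ranks they span), item rank sums $R_i$ are compared with their
null expectation $m(n+1)/2$ through $S=\sum_i (R_i - m(n+1)/2)^2$, and

$$W = \frac{12\,S}{m^2(n^3-n) - m\sum_j T_j}, \qquad
T_j = \sum_{\text{tie groups of rater } j} (t^3 - t).$$

The tie correction matters here: five-point ordinal scores over twenty
items are heavily tied, and without it W is biased downward. If every
rater assigns a single constant value, the denominator reaches zero
and the statistic is undefined (an error with an explanatory message).
W requires a complete matrix, so `complete_ratings()` applies listwise
deletion — every cranium with any missing score for the trait is
dropped and reported. That is the only missing-data policy offered for
the agreement statistics, because rank-based concordance is simply not
defined on ragged matrices; missing-tolerant policies are confined to
the accuracy module, where "missing counts against" is well defined.

**Fleiss' kappa.** For nominal sex calls by more than two raters, with
$n_{ij}$ raters placing item $i$ in category $j$:
$P_i = (\sum_j n_{ij}^2 - m)/(m(m-1))$, $\bar P$ their mean,
$p_j = \sum_i n_{ij}/(nm)$, $P_e = \sum_j p_j^2$, and
$\kappa = (\bar P - P_e)/(1 - P_e)$. When all calls land in one
category $P_e = 1$ and kappa is undefined (error, not NaN). Crania
where any rater's call is `missing` or `indeterminate` are excluded
before the computation; the recorded sex can optionally join the panel
as one further "rater" to measure agreement with the ground truth.

**Landis–Koch bands.** Values are interpreted on the conventional
scale: below 0 poor, 0–0.20 slight, 0.21–0.40 fair, 0.41–0.60
moderate, 0.61–0.80 substantial, 0.81–1.00 almost perfect. The raw,
unrounded value is compared with the band edges and an edge value such
as 0.80 belongs to the lower band; this resolves the ambiguity in the
conventional two-decimal interval notation without double-rounding.

## Accuracy

An estimate is correct iff its label equals the recorded sex.
`missing` and `indeterminate` estimates are never correct but stay in
the denominator: an unscorable cranium is a failed estimation, not an
excluded one. This policy is forced by the embedded data themselves —
the observer with one unscorable cranium is published at 13/20 = 65%,
which only holds with the full denominator. Whole-percent figures are
rounded half away from zero, with raw fractions retained alongside.
Per-sex accuracies use per-sex denominators, and pooled rows aggregate
counts (not percentages) across observers.

## The embedded study tables and the reproduction report

The raw inputs of the embedded study are transcribed cell-for-cell:
two panels of four observers each scoring the same twenty crania (ten
of each recorded sex) for three traits — one panel scoring 3D models
directly, the other scoring 360° screen recordings — including the two
cells one observer left unscored. `reproduce_study()` reruns the whole
pipeline on these tables and compares every published quantity with
its recomputed value.

Quantities the published tables support are asserted; a mismatch there
would indicate a defect in this package. Quantities that are
*internally inconsistent in the published tables* are flagged with a
note instead — reported side by side, never silently corrected and
never asserted:

* the direct-observer panel's W for mastoid process and supra-orbital
  margin (published 0.68 and 0.78; listwise-deleted tie-corrected
  recomputation gives 0.74 and 0.81, and no documented handling of the
  one incomplete cranium reproduces the published pair);
* one observer's percent-correct row (published 65 although the same
  published table marks eight of their twenty estimates as errors,
  i.e. 60);
* three per-cranium probability cells whose published values are
  inconsistent with the published raw scores (including one pair that
  does not sum to 100, presumed typographical);
* the overall Fleiss' kappa values (published 0.50 for inter-observer
  and 0.56 versus recorded sex without a stated rater set; the report
  computes kappa for each documented rater-set choice — first panel,
  second panel, all eight, each with and without the recorded sex as
  an extra rater — and none reproduces the published pair);
* the published per-sex accuracy averages, which are not recoverable
  from the published per-observer tables.

## The simulator

`synthetic_config()`/`simulate_ratings()` implement a latent-threshold
(cumulative) model of multi-observer ordinal scoring. Each cranium
draws a sex (Bernoulli with `sex_ratio`) and a shared robusticity
effect $\mathcal N(0, \sigma_c^2)$; each (observer, cranium, trait)
cell draws a latent value

$$\ell = \mu_{\text{trait},\text{sex}} + c_\text{cranium}
  + b_\text{observer} + \mathcal N(0, \sigma_o^2)$$

and scores it as 1 plus the number of thresholds below $\ell$; cells
go missing independently with `missing_rate`. This model was chosen
because it reproduces the qualitative phenomena of real morphoscopic
data with few parameters: an observer's systematic bias $b$ shifts
their whole score distribution (score avoidance at the extremes),
while large scoring noise $\sigma_o$ piles scores into the middle
categories.

Defaults mirror the embedded study's structure and were fixed once:
20 crania, balanced sexes, four unbiased observers, thresholds
$(-1.5,-0.5,0.5,1.5)$ symmetric about zero, latent sex means $\mp 1$
for every trait (female low), $\sigma_c = \sigma_o = 0.7$, no missing
cells. The sex separation of two latent threshold units with
comparable cranium- and observer-level spread represents a realistically
overlapping population — some robust females and gracile males — and
puts the default dataset's discriminant accuracy inside the 65–95%
band the study observed, rather than at a ceiling. All randomness
flows from the single seed in the configuration; equal configurations
generate byte-identical datasets.

`recovery_experiment()` runs generate → agreement → accuracy over a
configuration grid and returns Monte-Carlo means with standard errors.
Replicate seeds are derived deterministically from the master seed;
replicates where a statistic is undefined (e.g. kappa when every call
lands in one category) drop out of that statistic's mean.

**What passing simulator-based tests do and do not show.** The
generator emulates the *structure* of multi-observer ordinal data —
not CT imaging, surface-reconstruction error, trait-specific scoring
difficulty, or correlated observer training. Tests built on it verify
internal statistical behaviour (perfect agreement at zero noise,
monotone degradation of W and kappa with observer noise, collapse of
accuracy to the majority rate when the sexes are unseparated,
invariance properties of the statistics); they do not validate the
discriminant's accuracy on any real population.

## Numerical choices and problem sizes

* Mid-ranks everywhere in W; ties counted per rater via run lengths of
  the sorted values.
* Percentages compared as whole numbers and W/kappa after rounding to
  two decimals when auditing against the published values — the
  published precision; internal computations keep full precision.
* Degenerate inputs error with explanatory messages rather than
  returning NaN: fewer than two raters or items, all-constant raters
  (W), single-category panels (kappa), fewer than two complete items
  after listwise deletion.
* Test-suite simulations use 10–500 crania and 25 Monte-Carlo
  replicates per grid point — sizes at which the checked expectations
  are stable while the whole suite stays interactive (about half a
  minute).

## Known limitations

* Only the three supported traits are accepted; other morphoscopic
  traits (e.g. nuchal crest, mental eminence) would need the type
  list and discriminant extended.
* No significance tests accompany W or kappa, and no alternative
  agreement coefficients (Cohen's or weighted kappa, ICC,
  Krippendorff's alpha) are provided.
* The discriminant is applied, never re-fitted; populations for which
  the shipped coefficients are miscalibrated will show systematic
  bias, which this package measures (per-sex accuracy) but does not
  correct.
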