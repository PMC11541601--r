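---
title: "Measurement invariance and screening accuracy: models and methods"
author: "screendif"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measurement invariance and screening accuracy: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(screendif)
```

## The problem

Large psychiatric epidemiological surveys administer their diagnostic
interviews behind *gate questions*: a short screening section whose nine
dichotomous rules decide which full diagnostic modules a respondent
receives. A respondent who screens out of every rule is assigned a
negative diagnosis without further questioning, so everything downstream
— prevalence estimates and especially *comparisons of prevalence between
subgroups* — rests on the assumption that the screening rules measure
the same underlying construct, the same way, in every subgroup.

`screendif` implements the full analysis chain for interrogating that
assumption: a unidimensionality check, a two-parameter logistic (2PL)
item response model, detection of differential item functioning (DIF)
across a binary grouping with a purified-anchor likelihood-ratio
procedure, and a quantification of what the detected DIF does to the
screening decision itself — sensitivity, specificity and classification
rate at the "screen in on one or more rules" cut-point.

Because the motivating survey data are access-restricted, the package
ships a synthetic-data generator whose default truth is the published
item-parameter table for the nine rules, so every stage can be exercised
end to end with known ground truth.

## The measurement model

Each rule *j* is modelled as a 2PL item: given the latent internalising
liability $\theta$,

$$P_j(\theta) = \frac{1}{1 + e^{-a_j(\theta - b_j)}},$$

with discrimination $a_j > 0$ and difficulty $b_j$ (the location where
endorsement probability is 0.5). The factor-analytic summaries follow
from the logistic-to-normal-ogive bridge

$$\lambda_j = \frac{a_j / D}{\sqrt{1 + (a_j/D)^2}}, \qquad h^2_j = \lambda_j^2 ,$$

with $D = 1.702$. The package uses 1.702 — not the rounded 1.7 — because
only the higher-precision constant reproduces the published loading and
communality columns exactly from the published discriminations; `D` is
an argument wherever the conversion appears.

### Estimation

`fit2pl()` maximises the marginal likelihood by the Bock–Aitkin EM
scheme: a fixed grid of 61 equally spaced nodes on $[-6, 6]$ carrying
renormalised standard-normal weights, an E-step that computes each
observed response pattern's posterior over the nodes, and an M-step that
refits each item's logistic curve to the expected success/trial counts
by damped Newton steps. Because every accepted Newton step increases the
expected complete-data log-likelihood, the observed-data log-likelihood
is non-decreasing across cycles (the trace is stored in the fit summary
and asserted in the tests). Convergence is declared when the largest
absolute parameter change falls below `tol` (default `1e-4`, cap 500
cycles); both are `control` options. Slopes are bounded at 50 and a fit
that reaches the bound or the cycle cap is flagged rather than silently
returned — perfectly Guttman-ordered data, whose maximum-likelihood
slopes diverge, are the canonical case. A mild ridge penalty on the
slopes (`control$ridge`, default 0) is available for unstable data but
off by default so that likelihood oracles hold exactly. Response
patterns are collapsed to unique patterns with counts, so the cost per
cycle is bounded by the number of distinct patterns ($\le 2^9 = 512$),
not the sample size. Missing responses simply drop out of that item's
likelihood term.

Factor scores are expected a posteriori (EAP) means: defined for every
pattern, including all-zero and all-one, and identical for identical
patterns. The summed-score distribution conditional on $\theta$ comes
from the Lord–Wingersky recursion (`lordWingersky()`), which the tests
pin against exhaustive 512-pattern enumeration at $10^{-12}$.

## Unidimensionality check

`fitOneFactor()` fits a one-factor model to the matrix of tetrachoric
correlations. The tetrachoric for each pair is the maximum-likelihood
correlation of an underlying bivariate normal with thresholds fixed at
the margins; the bivariate normal rectangle probabilities are computed
by reducing to a univariate integral of the conditional normal CDF.
Degenerate tables are handled explicitly: a single empty cell gets a
flagged 0.5 continuity correction on all cells; an empty diagonal or
anti-diagonal pair (perfect concordance/discordance) is clamped at
$\pm(1 - 10^{-6})$ and flagged, since the MLE diverges. Non-PSD
correlation matrices are repaired by flooring eigenvalues at $10^{-6}$
and rescaling to unit diagonal (or rejected when `smooth = FALSE`).

Loadings minimise unweighted least squares on the off-diagonal elements
(a user-supplied weight matrix gives DWLS). The global indices — RMSEA,
CFI, TLI from a sample-size-scaled discrepancy against the independence
baseline, SRMSR as the root-mean-square off-diagonal residual — are
conventions of this estimator: comparable across models fit by this
function, not across software packages. The per-item RMSEA applies the
same scaling to a single item's residual row (df = J − 2); it is a
documented convention, not an attempt to match any particular program's
"item RMSEA". Conventional good-fit annotations (RMSEA and SRMSR at or
below 0.05, CFI/TLI at or above 0.95) are attached to the JSON report as
annotations only.

One mismatch is worth knowing about when simulating: the generator uses
logistic ICCs (that *is* the 2PL model), while the tetrachoric assumes a
normal ogive. For mid-range difficulties the two coincide almost
exactly, but for the most extreme rules (difficulty above roughly 1.5)
the population tetrachoric falls a few hundredths short of
$\lambda_j\lambda_k$. The test suite therefore requires CFA loadings to
recover the generating values within 0.02 only for items with
$|b| \le 1.2$, and within 0.06 overall. This is a property of the model
families, not an estimation error.

## DIF detection

`fitMultigroup()` estimates the two-group 2PL jointly: *anchored* items
share one $(a_j, b_j)$ across groups, *free* items get group-specific
parameters. The reference group's latent distribution is fixed standard
normal; the focal group's mean and variance are estimated by the EM
moment update whenever at least one anchor identifies the common metric
(freeing them with no anchors is refused as an identification error).
Partial constraints — slope-only or location-only equality — support the
one-parameter follow-up tests.

The two-stage procedure:

1. **Purification sweep** (`purifyAnchors()`). For each item in turn,
   the fully anchored model is compared with the model freeing that
   item's $(a, b)$ — all other items acting as the temporary anchor set
   — by a likelihood-ratio test with 2 df. Items significant at an
   *unadjusted* $\alpha = 0.05$ become DIF candidates; the rest form the
   purified anchor set. The sweep is deliberately liberal: its job is to
   keep contaminated items out of the anchors, not to control error
   rates. If every item flags, or fewer than three survive, items are
   ranked by the BIC improvement gained by freeing them and the three
   with the smallest improvement (ties broken by item order, a stable
   sort) are taken as anchors. The focal latent moments are re-estimated
   inside every sweep model, so a true latent-mean difference (impact)
   is not mistaken for DIF.
2. **Formal tests** (`testDif()`). With the anchors constrained equal
   and every other item free, each non-anchor item is tested for joint
   $(a, b)$ equality by a likelihood-ratio test (2 df) against the model
   that additionally constrains it, and the p-values are
   Benjamini–Hochberg adjusted across the tested items of the grouping
   variable. The joint 2-df test is the flagging criterion; slope-only
   and location-only follow-ups (`difFollowUp()`, 1 df each) are for
   interpretation.

Two statistical honesty notes, both verified by simulation in the test
suite. First, with nine unadjusted sweep tests at $\alpha = 0.05$, the
probability that *no* item flags under the null is about
$0.95^9 \approx 0.63$ — an occasional spurious sweep flag is expected
behaviour, which is why the sweep is followed by adjusted formal tests.
Second, the BH guarantee of the formal stage applies to testing a
*given* anchor set: under the null, the familywise any-flag rate of
`testDif()` with a valid fixed anchor set is at the nominal level
(measured $\le 0.07$ at $\alpha = 0.05$ over 200 replicates). The full
sweep-then-test pipeline does not control that rate — items reach the
formal stage *because* they flagged in the liberal sweep — and this
selection effect is inherent to purified-anchor procedures, which buy
robustness of the anchor set at the price of nominal error calibration.

## Screening impact

The screening decision is "meet at least one rule", a cut of $c = 1$ on
the sum score $X$. The test characteristic curve
$TCC(\theta) = \sum_j P_j(\theta)$ is strictly increasing, so the cut
maps to a unique latent cut-point $\theta^*$ solving
$TCC(\theta^*) = t$, found by bisection to $10^{-10}$. The default
*midpoint* convention sets $t = c - 0.5$: an expected score above 0.5
rounds to "screens in", which avoids the pathology of the *strict*
convention ($t = c$) where respondents whose expected score is just
below 1 are counted as screen-outs however close they sit. Both
conventions are exposed and every report names the one used. $\theta^*$
is computed once, from the DIF-free pooled parameters, and reused for
both model variants, so reported differences isolate measurement-model
effects rather than cut-point drift.

`classificationIndices()` then classifies each group against
$\theta^*$ under two measurement models — a DIF-free model (all items
anchored; for a standard-normal prior in both groups, fit with
`estimateMoments = FALSE`) and a DIF model (flagged items free, focal
moments estimated) — and `compareModels()` reports ignoring-minus-
accounting differences per index and group. Two computational modes and
two decision variants are available:

* **empirical** (default): every respondent gets an EAP score under
  their group's parameters and prior; sensitivity is the share of
  respondents at or above $\theta^*$ whose expected observed score
  $TCC_g(\hat\theta)$ reaches $t$, specificity the share below
  $\theta^*$ falling short, classification rate the overall concordance.
* **integration**: the EAP distribution is replaced by the group's
  latent normal density (closed-form normal tail ratios under the
  expected-score variant).
* the **expected** variant uses the indicator $TCC_g(\theta) \ge t$;
  the **probabilistic** variant replaces it with the exact summed-score
  probability $P(X \ge c \mid \theta)$ from the Lord–Wingersky
  recursion.

Their interplay deserves explicit documentation. Under the expected
variant the DIF-free model is trivially perfect —
$TCC(\hat\theta) \ge t \iff \hat\theta \ge \theta^*$ because the same
monotone curve defines both sides — so all of the reported difference is
carried by the DIF model's group-specific curves. The probabilistic
variant is the one that produces the familiar non-degenerate magnitudes
(sensitivities near 0.9, specificities near 0.75 for this item set),
because it retains the Bernoulli noise of the screening decision itself;
it is the variant to use when the goal is a realistic accuracy figure
rather than an isolation of DIF effects. Under either variant,
classification rate decomposes exactly as
$\text{sens}\cdot\pi + \text{spec}\cdot(1-\pi)$ with
$\pi = P(\theta \ge \theta^*)$.

One caveat on the empirical mode: EAP scores are discrete over the 512
response patterns, with atoms of several percent sitting near the cut,
so empirical indices can differ from the integration ones by a few
hundredths — that is a property of factor scores, not a bug. The
quadrature itself is cross-validated by a third mode, `montecarlo`,
which estimates the integration-mode indices from random latent draws
and agrees within Monte-Carlo error (within 0.005 at $10^6$ draws in the
acceptance suite).

## The synthetic-data generator

`simulateResponses()` draws each respondent's $\theta$ from their
group's normal distribution and each rule outcome as a Bernoulli with
the group's 2PL probability. The defaults are the study conditions the
package is built around: the published total-sample $(a, b)$ table as
reference truth, an even two-group split, equal standard-normal latent
distributions and no injected DIF; `groupItemParameters()` supplies the
published group-specific truth (sex, age, employment, location,
substance use), in which items without DIF share the reference
parameters. DIF is injected as additive offsets on the focal group's
$a$ or $b$. Seeds are explicit arguments everywhere; the generator
saves and restores the global RNG state.

`simulateRawGateResponses()` additionally emits a categorical
gate-question table (including "Don't know"/"Refused" answers sprinkled
among the negatives) that compiles back to its generating rule matrix
through `encodeScreeningRules()` — the rule compiler treats any non-Yes
answer as negative and implements screen-out as the logical complement
of each screen-in clause, which resolves the ambiguous "or" phrasing of
the compound rules' screen-out descriptions.

What the generator deliberately does **not** emulate: the survey's
stratified area sampling, oversampling of younger respondents and survey
weights (the analysis ignores weights by design); item-level
missingness; local dependence between rules beyond the single factor;
and any non-normal latent distribution. Passing tests therefore
demonstrate that the algorithms recover the truth of this idealised
process at realistic sizes — not that the substantive published
estimates are correct.

## Problem sizes and numerical choices

The test suite exercises the package at the sizes the analysis is meant
for, chosen once: single-group recovery at n = 15,893 (the survey's n);
multigroup recovery and pipeline recovery at 10,000 per group; the null
error-rate study at 200 replicates of 5,000 per group; the power study
(difficulty offset 0.8) at 50 replicates; unbiasedness over 50
replicates at n = 5,000. Remaining numerics: quadrature 61 nodes on
$[-6, 6]$ (401–10,001 nodes where an integrand must be resolved more
finely); bisection to $10^{-10}$ on the TCC; tetrachoric optimisation on
$\pm(1 - 10^{-6})$ with boundary clamping flagged; BIC ties broken by
item order; focal latent variance floored at $10^{-3}$ during EM.

## Limitations

* Two groups per contrast; several groupings are independent runs.
* Binary items only — no polytomous or 3PL extensions, no MCMC.
* Fit indices are estimator-specific conventions (see above).
* The two-stage DIF procedure's familywise error is nominal only with
  respect to a fixed anchor set.
* No survey-design corrections: estimates assume simple random
  sampling.
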