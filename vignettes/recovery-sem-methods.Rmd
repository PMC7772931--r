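---
title: "Modeling addiction recovery and relapse from forum text: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling addiction recovery and relapse from forum text: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(recoverysem)
```

## The problem

People discussing drug use and recovery on community forums leave two kinds
of observable traces: the language of their posts and the communities they
post in. Constructs that plausibly drive recovery and relapse — emotional
distress, physical pain, social ties, self-development effort — are latent.
This package implements a pipeline that (1) turns post text into bounded
psycholinguistic category proportions with dictionary word counting,
(2) turns posting timelines across recreational-drug-use (RDU) and
drug-addiction-recovery (DAR) communities into recovery and relapse labels,
and (3) estimates the effect of the latent constructs on those outcomes with
structural equation models (SEM) fitted by maximum-likelihood covariance
analysis, evaluated with CFI, TLI, RMSEA and SRMR.

Because platform data cannot be redistributed, the package ships a seeded
synthetic-data module that generates every input with known ground truth.
All quantitative claims in the test suite are made against that ground
truth or against closed-form/enumeration oracles.

## Lexicon scoring

A lexicon maps category names to term patterns: exact lowercase tokens or
prefix wildcards (`pray*`), the publicly documented dictionary convention.
Tokenization lowercases and keeps maximal runs of alphanumerics plus
apostrophes. A category's score for a token list is the fraction of tokens
matching any of its patterns. Choices worth making explicit:

* **Scale.** Scores are proportions in $[0,1]$, not percentages in
  $[0,100]$. The negation transformation $x \mapsto 1-x$ (which turns
  "friends" into "friends$'$", the absence of the signal) only makes sense
  on that scale, and it is the scale on which reported category means of
  about $0.1$–$0.4$ live. `negate_category()` treats values outside
  $[0,1]$ as a scale mismatch and refuses them.
* **Non-exclusive categories.** A token may count toward several
  categories, without down-weighting; dictionaries overlap by design
  (expletives are both "swear" and "anger" material).
* **Aggregation across a user's posts.** Two modes are provided because the
  choice is not dictated by the scoring definition: `"pooled"` (default)
  concatenates all of a user's tokens and scores once, weighting posts by
  length; `"per_post_mean"` scores each nonempty post and averages,
  weighting posts equally. They coincide exactly when posts have equal
  token counts. For a user with a 10-token post containing 2 matches and a
  30-token post containing 3, pooled gives $5/40 = 0.125$ and per-post-mean
  gives $(0.2 + 0.1)/2 = 0.15$.
* **The "authentic" summary score.** Some dictionary suites ship summary
  scores computed by proprietary algorithms rather than term lists. Such
  variables are accepted as externally supplied per-user columns
  (`extra_columns` in the pipeline), never recomputed.
* **Relapse-model transformations.** For relapse analyses each post's raw
  category value is first divided by the number of whole days between the
  post and the user's relapse day (floored at one day, so same-day posts
  are kept rather than dropped or divided by zero), then negated for the
  prime indicators, then averaged over the user's posts. Scaling before
  negation keeps the value inside $[0,1]$, where the negation is defined.
  Continued-recovery users have no relapse day; their final observed post
  is used as the anchor, on the reasoning that the scaling is meant to
  up-weight language near the end of the observed journey.

## Cohort rules

Users are retained with at least five nonempty posts in RDU $\cup$ DAR
forums. Recovery is the binary indicator of ever posting in a DAR forum.
Relapse labeling works on the user's subsequence of RDU/DAR posts in
timestamp order (stable sort, so ties keep input order):

* *relapsed*: some RDU post follows a DAR post, and at least five DAR posts
  precede the first such RDU post. Because no earlier RDU post may follow a
  DAR post, the prefix has the shape RDU\*DAR\*, so those DAR posts are
  automatically consecutive. The relapse time is that first returning RDU
  post's timestamp.
* *continued*: never posts in RDU after DAR and has at least five DAR
  posts.
* *excluded*: everything else (stray DAR postings, short runs).

"Posts in succession" is read *within the drug-related subsequence*: posts
to unrelated forums do not break a run, since the intent of the filter is
sustained recovery-forum engagement and users post widely elsewhere. The
run threshold is configurable (`min_consecutive_dar`); with threshold 1 the
rule degenerates to "any DAR followed later by RDU", which the tests verify
against exhaustive enumeration of all short sequences.

Forum-activity features for the activity-based recovery model are per-user
post counts in each target forum divided by the user's total retrieved
posts; with on the order of a thousand posts per user this produces the
small magnitudes (around $10^{-3}$) typical of normalized activity tables.

## The SEM engine

Models are written in a small text syntax (`latent =~ ind1 + ind2`,
`outcome ~ predictor`, `a ~~ b`). The engine uses a reticular (RAM)
parameterization over the combined observed + latent variable set: a
directed-path matrix $A$ (loadings and regressions), a symmetric matrix
$S_0$ (variances and covariances, including residual and latent ones) and a
filter $F$ selecting observed rows. The implied covariance is

$$\Sigma(\theta) = F (I - A)^{-1} S_0 (I - A)^{-\top} F^\top.$$

This single-matrix form is algebraically equivalent, for recursive models,
to the two-block endogenous/exogenous formulation, and avoids having to
commit to a labeling of indicators as "exogenous" — a point on which
textbook presentations are not always internally consistent. Estimation
minimizes the ML discrepancy

$$F_{ML} = \log|\Sigma(\theta)| + \mathrm{tr}(S\,\Sigma(\theta)^{-1})
  - \log|S| - p,$$

with $p$ the number of observed variables and $S$ the sample covariance
with divisor $N$ (the ML convention; the test statistic is
$\chi^2 = (N-1)\,F_{ML}$, so cross-checks against other software should
reconcile the divisor first). Each latent variable is given the scale of
its first listed indicator by fixing that loading to 1 — the convention
behind the "1.000, no standard error" rows of published loading tables —
rather than by fixing latent variances.

Numerical choices:

* **Scaling.** The optimizer works on the unit-diagonal rescaling of $S$
  ($F_{ML}$ is scale invariant); estimates map back by ratios of the scale
  factors. This keeps the problem well conditioned when indicators differ
  in scale by orders of magnitude, as day-scaled relapse features do.
* **Positivity.** Variance parameters are optimized on the log scale.
  Estimates pinned at the positivity boundary (below $10^{-5}$ on the
  standardized scale) are flagged as Heywood-type solutions with a warning,
  never silently accepted.
* **Optimization.** Start values: free loadings at the indicator/anchor SD
  ratio, paths and covariances at 0, variances at half the observed
  variance. BFGS with the analytic gradient of $F_{ML}$ (a few matrix
  products per evaluation in the RAM form), followed by Newton polishing
  until the gradient infinity-norm falls below $10^{-8}$ (maximum 500
  optimizer iterations). Fits are deterministic given $S$, the model and
  these documented starts.
* **Inference.** The asymptotic covariance of the free parameters is
  $\frac{2}{N-1} H^{-1}$ with $H$ the Hessian of $F_{ML}$ at the solution
  (finite differences of the analytic gradient); $z$ is estimate over SE
  and $p$ is two-sided normal — the usual large-sample reporting
  convention, chosen over a $t$ reference.
* **Binary outcomes.** Recovery/relapse indicators are treated as
  continuous endogenous variables under normal-theory ML, mirroring common
  practice in this literature; the fit logs a note. The thresholding
  attenuates path magnitudes (and its implied covariances with Gaussian
  indicators stay proportional to the latent ones), so sign and ordering of
  structural paths are the meaningful targets, not their raw magnitudes.
* **Standardization.** Loadings and paths are rescaled by implied predictor
  over outcome standard deviations; covariances become implied
  correlations. Standardized solutions are invariant to rescaling the
  observed variables, which the tests verify by refitting.

## Model evaluation

The baseline model frees every variance and fixes all covariances to zero
(degrees of freedom $p(p-1)/2$); it is refitted by the same optimizer, with
its closed form (variances equal to $\mathrm{diag}(S)$,
$F_{ML} = -\log|R|$ for the sample correlation matrix $R$) used as a test
oracle. Indices:

* CFI $= 1 - \max(\chi^2_I - d_I, 0)/\max(\chi^2_I - d_I,\ \chi^2_B - d_B,
  0)$, with the $0/0$ case defined as 1; always in $[0,1]$.
* TLI $= (\chi^2_B/d_B - \chi^2_I/d_I)/(\chi^2_B/d_B - 1)$, not clamped —
  values slightly above 1 are reported as such.
* RMSEA $= \sqrt{\max(\chi^2_I - d_I, 0)/(d_I (n-1))}$, negative radicand
  clamped to zero.
* SRMR: root mean square of residuals over the lower triangle including
  the diagonal. The default standardizes residuals on the correlation
  scale, dividing by $\sqrt{C_{ii} C_{jj}}$ — the reading under which the
  quantity is the "average standardized residual" — while
  `srmr(..., rooted = FALSE)` divides by the unrooted product $C_{ii}
  C_{jj}$; the two coincide for unit-diagonal $C$. The rooted reading is
  the default because only it is invariant to rescaling the variables.

Just-identified models reproduce $S$ exactly; for them $d_I = 0$ and the
report uses the perfect-fit conventions TLI $= 1$, RMSEA $= 0$. Threshold
labels use strict inequalities: RMSEA excellent/good/mediocre below
0.01/0.05/0.08 else poor; CFI and TLI high-quality strictly above 0.90;
SRMR adequate strictly below 0.08 (so an index of exactly 0.90 or 0.08
does not earn the better label).

## Group statistics

Group comparisons use the Mann–Whitney U test, two-sided, with $U$ from
midrank summation. The `"exact"` method enumerates the permutation null
over all assignments of the pooled values (used automatically up to 16
pooled observations; correct with ties); `"normal"` uses the tie-corrected
normal approximation with a continuity correction. At 8-vs-8 the normal
approximation tracks the exact p to about a percentage point at worst,
converging quickly with size. Comparison tables report group means, sample
SDs (divisor $n-1$), $U$, the exact/approximate p, and the coarsest
satisfied display bound ("$p < 0.005$"-style), with no multiple-testing
correction by default — mirroring how such tables are usually printed — and
an optional `p.adjust` method for analysts who want one.

## The synthetic-data generator

The generator defines the study conditions under which everything is
tested:

* **Feature structure.** Latent scores are multivariate normal; indicators
  are loading $\times$ latent $+$ Gaussian residual, affinely squashed into
  $[0,1]$ (centered at 0.5, scaled to SD 0.1, clipped at the boundaries
  with the clipping rate recorded — under the defaults clipping is a
  five-sigma event). Default residual variances make the loadings the
  standardized loadings. Keeping features bounded keeps the negation
  transformation meaningful on synthetic data.
* **Outcome.** Binary, by thresholding the structural linear predictor plus
  Gaussian noise at the quantile giving prevalence 0.38 — the observed
  share of drug-forum users who also post in recovery forums. The
  latent-threshold link produces the point-biserial covariance structure
  that normal-theory ML treats linearly, which is why the recovery targets
  are the signs and significance of the structural paths rather than their
  raw magnitudes.
* **Text.** Post tokens are drawn from a mixture of per-category
  vocabularies (restricted to tokens unique to their category, so the
  planted signal is not smeared across categories by dictionary overlap)
  plus neutral filler, with mixture weights increasing linearly in the
  user's latent score. Scoring and aggregating this text approximately
  recovers the factor structure.
* **Timelines.** Relapsing users get a qualifying DAR run followed by an
  RDU return; continued users a run with no return; a 20% decoy fraction
  violates the filter and must come out excluded. The relapsed fraction
  defaults to 0.62, the share of relapsers among event-labelable users in
  comparable cohorts. Unrelated-forum posts are interleaved to exercise the
  "runs are counted within the drug-related subsequence" rule.

What the generator does **not** emulate: realistic lexical and topical
variety, post-length and activity burstiness, censoring and account churn,
cross-posting, or dictionary miscoverage. Passing tests therefore
demonstrate that the pipeline's machinery is correct under its own
statistical assumptions — not that those assumptions hold for any
particular platform's data.

## Problem sizes used by the checks

Parameter recovery runs all five bundled topologies at $n = 5000$ with 50
replicates each, asking for mean absolute error of standardized loadings
below 0.03; standard errors are calibrated on a one-factor model with 200
replicates at $n = 2000$ (empirical SD within 15% of the mean reported SE).
The end-to-end experiment generates a 2000-user corpus and requires the
recovered structural paths to be positive at $p < 0.05$ with CFI and TLI
above 0.90 and SRMR below 0.08 for the correctly specified model. Implied
covariances are checked against a $10^6$-draw Monte-Carlo simulation of the
structural equations; the discrepancy function and SRMR against
independent direct evaluations on hundreds of random positive-definite
pairs; exact Mann–Whitney p values against full enumeration of every split
of up to eight pooled observations.

## Known limitations

One estimator (normal-theory ML); no mean structures, missing-data
handling, multi-group models or robust corrections. Binary outcomes are
modeled linearly rather than with a probit link, so structural path
magnitudes are attenuated relative to a latent-response formulation. The
bundled lexicon is a miniature stand-in with the right interface, not a
validated dictionary, and analyses on real text should supply a real one.
Exact Mann–Whitney enumeration is limited to small groups by design.
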