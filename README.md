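# recoverysem

Structural equation models of addiction recovery and relapse from
social-media text.

People discussing drug use and recovery on community forums leave two
observable traces: the language of their posts and the communities they
post in. The constructs that plausibly drive recovery and relapse —
emotional distress, physical pain, social ties, self-development — are
latent. `recoverysem` is an analysis pipeline for estimating the effect of
such latent constructs on recovery and relapse outcomes, aimed at
computational-epidemiology and text-as-data researchers:

1. **Lexicon scoring** — posts are tokenized and scored against
   psycholinguistic category dictionaries (exact terms and stem wildcards,
   LIWC-style `.dic` files supported); scores are proportions of matching
   tokens. Relapse analyses use negated ("prime") indicators
   `x' = 1 - x` and per-post day-scaling toward the relapse event.
2. **Cohort construction** — users active in recreational-drug-use (RDU)
   and drug-addiction-recovery (DAR) forums are filtered (≥ 5 nonempty
   drug-forum posts), labeled for recovery (ever posted in DAR) and for
   relapse (an RDU post after a qualifying run of ≥ 5 consecutive DAR
   posts), and featurized by normalized forum activity.
3. **A native SEM engine** — models written in a small text syntax
   (`latent =~ ind1 + ind2`, `outcome ~ predictor`, `a ~~ b`) are fitted by
   minimizing the maximum-likelihood discrepancy

   F_ML = log|Σ(θ)| + tr(S Σ(θ)⁻¹) − log|S| − p,

   over a RAM parameterization Σ(θ) = F(I−A)⁻¹S₀(I−A)⁻ᵀFᵀ, with analytic
   gradients, asymptotic standard errors, standardized solutions, and the
   fit indices CFI, TLI, RMSEA and SRMR with conventional threshold labels
   (χ² = (N−1)·F_ML against an independence baseline).
4. **Descriptive statistics** — indicator correlation matrices and
   Mann–Whitney U comparisons (exact enumeration for small groups,
   tie-corrected normal approximation otherwise) between outcome groups.
5. **Synthetic data with ground truth** — seeded generators for
   factor-structured features, category-bearing post text, and
   event-structured timelines, so every stage is testable without platform
   data (which cannot be redistributed).

The methods vignette (`vignettes/recovery-sem-methods.Rmd`) documents the
model, the estimation details, and every interpretation decision.

## Worked example

Generate a 500-user synthetic corpus whose text carries a two-factor
structure with positive distress → recovery paths, then run the withdrawal
analysis end to end:

```r
library(recoverysem)

cfg <- generator_config(n_users = 500, seed = 42)
corpus <- generate_synthetic_posts(cfg, mini_lexicon())

model <- parse_model("
  emotional_distress =~ negative_emotion + sad + anger + anxiety
  physical_pain =~ health + body + pain
  recovery ~ emotional_distress + physical_pain
  emotional_distress ~~ physical_pain
")
res <- run_pipeline(run_config("withdrawal_liwc", posts = corpus$posts,
                               model = model, seed = 42))

ptab <- res$parameter_table
ptab[ptab$op == "~", c("lhs", "rhs", "estimate", "standardized", "z", "p")]
#>        lhs                rhs estimate standardized    z        p
#> 8 recovery emotional_distress    11.86        0.390 9.29 1.49e-20
#> 9 recovery      physical_pain     9.45        0.274 6.50 8.15e-11

res$indices
#> chi^2 = 20.294 (df 18), baseline chi^2 = 3033.220 (df 28)
#> CFI = 0.9992  TLI = 0.9988  RMSEA = 0.0160  SRMR = 0.0151  (n = 500)

assess_fit(res$indices)
#>      rmsea        cfi        tli       srmr
#>     "good"     "high"     "high" "adequate"
```

Both structural paths come back positive and strongly significant
(standardized 0.39 and 0.27 — the generating paths were 0.5 and 0.3 before
the binary outcome's attenuation), and the correctly specified model earns
the high-quality fit labels. Five ready-made model topologies
(withdrawal via two lexicon families, activity-based recovery, and two
relapse models over negated indicators) ship as text fixtures; see
`bundled_model()` and `run_pipeline()`.

## The analysis workflow

Numbered drivers under `analysis/` rerun the study on synthetic data and
write their tables under `results/`:

- `01_simulate.R` — generate the 2000-user corpus and 1000 event timelines.
- `02_features_cohort.R` — feature matrix, cohort labels, indicator
  correlation matrix, Mann–Whitney group-comparison table.
- `03_fit_models.R` — the withdrawal SEM end to end and the relapse SEM on
  negated day-scaled indicators, with parameter tables and fit reports.
- `04_parameter_recovery.R` — all five bundled topologies simulated from
  known parameters and refitted; standardized loadings recovered to within
  about 0.01 on average.

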