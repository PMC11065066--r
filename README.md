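# lifetraj

Life-course epidemiology tools for retrospective **life-calendar data**:
yearly categorical employment state sequences, timing-sensitive sequence
dissimilarity, trajectory typologies by k-medoids clustering, and
covariate-adjusted association of trajectory membership with a binary health
outcome (e.g. ever-diagnosed cancer).

The package targets the common study design in which a cohort of older
adults reconstructs its working life retrospectively — one labour-market
state per year between ages 16 and 65, coded on an 8-category alphabet
(1 employed full-time, 2 employed part-time, 3 self-employed, 4 unemployed,
5 home/family, 6 retired, 7 full-time education, 8 other) — and the analyst
asks two questions: *what typical employment trajectories exist in this
cohort?* and *is trajectory membership associated with the outcome after
adjustment for baseline covariates?*

## The method

**Sequences and dissimilarity.** Each subject is an aligned state sequence
`x = (x_16, ..., x_64)` of length 49 (ages in the half-open span `[16, 65)`).
Pairwise dissimilarity is the Hamming distance

```
d(x, y) = Σ_a 1[x_a ≠ y_a],
```

the count of ages at which two subjects hold different states. Because no
shifting or insertions are allowed, the same spell occurring at different
ages counts as mismatch — the distance is sensitive to *timing*, which is the
point: being unemployed at 25 is not the same exposure as being unemployed
at 55.

**Typology.** Sequences are grouped by partitioning around medoids (PAM):
choose `k` actual subjects (medoids) minimising the total distance of every
subject to its nearest medoid, via deterministic greedy BUILD seeding
followed by best-improvement SWAP exchanges. The number of trajectory types
is chosen by the average silhouette width `ASW = mean_i (b_i − a_i) /
max(a_i, b_i)` over a range of `k` (default 2–10). Each cluster is described
by its chronogram (the state distribution at every age) and a composition
table (n, %, modal state path, medoid).

**Association.** With trajectory membership as indicator variables
(reference type omitted), a logistic regression

```
logit P(Y = 1) = β0 + Σ_c β_c 1[cluster = c] + γ' z
```

adjusts for baseline covariates `z` (age, birth cohort coded by historical
crisis periods, BMI, smoking, ≥2 chronic conditions, low physical activity,
attrition category) and reports per-trajectory odds ratios `exp(β_c)` with
95% Wald confidence intervals.

A synthetic-cohort generator (templates → noisy sequences → covariates →
logistic outcomes) makes every stage testable without access-restricted
survey data.

## Worked example

```r
library(lifetraj)

cfg <- synthetic_config(
  templates     = builtin_templates("female"),   # 8 trajectory shapes
  n_per_cluster = 75,
  noise_rate    = 0.05,                          # per-age corruption probability
  outcome_model = list(log_or_cluster = c(
    "Mainly full-time" = log(1.7), "Mainly home/family" = 0,
    "Mainly full-time to home/family" = log(1.5),
    "Mainly self-employment" = log(0.8),
    "Full-time or home/family to part time" = log(2.3),
    "Home/family to full-time" = log(1.2),
    "Mainly unemployment" = 0, "Other" = log(1.5))),
  seed = 2024)
cohort <- generate_cohort(cfg)
cohort$panel
#> sequence_panel: 600 sequences x 49 states (ages 16-64), 8-state alphabet

d   <- hamming_matrix(cohort$panel)
sel <- select_k(d, k_min = 2, k_max = 10)
sel$best
#> cluster_solution: k = 8, n = 600, total cost = 1472, ASW = 0.827
```

The ASW profile peaks at the planted number of types (`k = 8`, ASW 0.83
against 0.81 at `k = 7` and 0.79 at `k = 9`), and the modal state paths in
`typology_summary(cohort$panel, sel$best$cluster, d = d)` read off the
planted shapes, e.g. `7-7-7-1-...-1-5-...-5` for the full-time to
home/family type. The association stage recovers the configured effects
(simulation noise aside):

```r
fit <- fit_trajectory_outcome_model(cohort$outcome, cohort$labels,
                                    cohort$covariates,
                                    reference = "Mainly home/family")
fit
#> association_result: n = 600 (0 excluded), reference = Mainly home/family
#>                             trajectory            or_ci
#>                     Mainly home/family             Ref.
#>  Full-time or home/family to part time 3.36 (1.22–9.20)
#>               Home/family to full-time 1.04 (0.31–3.42)
#>                       Mainly full-time 2.19 (0.76–6.32)
#>        Mainly full-time to home/family 2.18 (0.76–6.27)
#>                 Mainly self-employment 0.82 (0.24–2.86)
#>                    Mainly unemployment 1.46 (0.47–4.50)
#>                                  Other 1.64 (0.55–4.91)
```

Each row is the odds ratio of the outcome for that trajectory versus the
reference "Mainly home/family" type, with its 95% CI; at n = 600 the
intervals are wide, and they tighten as expected at realistic cohort sizes
(see the replicate experiments run by the acceptance script).

The same analysis runs config-driven from the shell via
`inst/cli/lifetraj.R` with subcommands `simulate`, `cluster`, `associate`,
`report`, writing plain CSV/JSON outputs per stage.

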