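---
title: "Employment trajectory typologies and outcome association: models and choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Employment trajectory typologies and outcome association: models and choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette explains the statistical procedure `lifetraj` implements, the
assumptions behind it, the numerical and design choices that were genuinely
open, and what the synthetic-data experiments do and do not demonstrate.

## The data model

The unit of analysis is a **life-calendar sequence**: one categorical
labour-market state per year of a subject's life, on the 8-state alphabet
(1 employed full-time, 2 employed part-time, 3 self-employed, 4 unemployed,
5 home/family, 6 retired, 7 full-time education, 8 other — the last bundling
illness or disability, voluntary work, military service and travelling). A
`sequence_panel` stores these as an integer matrix with one row per subject
and one column per age, with `NA` marking years for which the respondent gave
no information. The alphabet is configurable, but all defaults assume the
8-category coding.

**Alignment span.** Working lives are compared over ages 16 to 65. A yearly
calendar with one state per *completed* year of age gives the half-open span
`[16, 65)` — ages 16 through 64 — and therefore sequences of exactly 49
states, which is the convention `align()` uses by default. An inclusive
50-state variant is one argument away (`end_age = 66`). The half-open
convention was chosen because a 49-state sequence is what a 16-to-65 calendar
yields when each year of age contributes one cell; all package defaults,
templates and tests use it consistently.

**Completeness.** Any missing year inside the span excludes the subject
(`filter_complete()`), mirroring the complete-case inclusion rule of
retrospective life-history studies. No imputation is attempted: a
life-calendar gap usually reflects a refused or failed recall, and imputing a
49-length categorical path from its neighbours would manufacture exactly the
timing information the downstream distance is designed to measure.

## Dissimilarity: plain Hamming, deliberately

`hamming_matrix()` computes the positionwise mismatch count between every
pair of aligned sequences. Hamming distance is used *because* it is rigid:
with no shifting or insertions allowed, two identical employment spells
occurring at different ages count as mismatches, so the distance is sensitive
to the timing of states, not only their duration. Optimal-matching / edit
distances with indel costs are intentionally **not** implemented — they trade
away precisely that timing sensitivity, and the package takes a position
rather than offering a distance menu. The matrix is stored dense
(`n × n` doubles), which is comfortable to roughly 10^4 sequences (about
800 MB at n = 10^4); larger cohorts need either subsampling or a different
storage strategy and are outside the package's design envelope.

Normalization by sequence length (`normalize_dissimilarity(d, "length")`)
maps distances into [0, 1] for reporting; clustering and silhouettes operate
on the raw counts, since dividing every entry by the same constant changes
neither medoids nor silhouette values.

## Clustering: deterministic PAM with ASW selection

`pam_cluster()` implements classical partitioning around medoids:

* **BUILD** seeds greedily — the first medoid minimises the total distance to
  all subjects; each subsequent medoid is the point whose addition most
  reduces the total cost.
* **SWAP** repeatedly evaluates every (medoid, non-medoid) exchange and
  applies the single best one, as long as it *strictly* reduces the total
  cost.

Strict improvement plus lowest-index tie-breaking (for both equal swap gains
and equidistant medoids) makes the procedure fully deterministic: no random
restarts, no seeds, identical output on identical input. The cost strictly
decreases at every swap, so termination is guaranteed.

Best-improvement SWAP is a local search, and that should be understood
honestly: on *unstructured* dissimilarity matrices it can terminate at a
local optimum a few percent above the exhaustive k-medoid optimum (the test
suite contains one such instance, verified by enumerating all single
exchanges — no improving swap exists from the returned solution). On panels
with actual cluster structure — the data this method is for — the suite's
small-instance oracle (exhaustive enumeration over all medoid subsets,
n ≤ 12) finds PAM at the global optimum throughout, and a well-known
reference implementation (`cluster::pam`) agrees with our costs on the same
instances.

**Silhouettes.** For subject *i*, `a(i)` is the mean dissimilarity to its own
cluster (excluding itself) and `b(i)` the smallest mean dissimilarity to any
other cluster; `s(i) = (b − a) / max(a, b)`. Two conventions cover the
degenerate corners: members of singleton clusters score 0 (they provide no
evidence either way), and so do points with `a = b = 0` (exact duplicates
split across clusters). The **average silhouette width** is the mean of
`s(i)`, computed on the same unnormalized distances used for clustering.

**Choosing k.** `select_k()` runs PAM for every `k` in a range (default
2–10, a span that covers typologies reported across the life-course
literature with room above) and returns the solution maximising ASW, ties
going to the smaller `k` — parsimony as the tie-break. The full `k → ASW`
profile is always returned so the analyst can see whether the maximum is a
peak or a plateau.

## Typology description

`chronogram()` turns each cluster into its age-by-state distribution: entry
(state, age) is the fraction of the cluster in that state at that age, so
every age column of a complete panel sums to 1. `typology_summary()` reports
each cluster's size, percentage, medoid subject and modal state path.
Percentages are rounded half *away from zero* to one decimal — the convention
of printed cohort tables — rather than R's default round-half-even.

Cluster *naming* is user input. Names like "Mainly full-time to home/family"
are qualitative judgements; the package supplies modal paths and chronograms
to support them and never auto-names.

## Covariate coding and the association model

`code_birth_cohort()` maps birth years onto three historical-crisis bands:
*war* (1914–1918 or 1939–1945), *great_depression* (1929–1938), *no_crisis*
otherwise. `code_covariates()` applies the usual baseline dichotomisations:
two-or-more chronic conditions; *low* physical activity when neither the
vigorous nor the moderate item is answered "more than once a week"; BMI from
self-reported weight and height. Subjects missing any field are flagged for
complete-case exclusion.

`fit_trajectory_outcome_model()` fits, by maximum likelihood (`stats::glm`,
binomial), the logistic model with trajectory indicators (reference omitted)
plus whichever adjustment covariates are supplied. Choices worth stating:

* **Confidence intervals** are Wald on the log-odds scale,
  `exp(coef ± 1.96 · SE)` — the standard reporting convention; profile
  likelihood intervals would differ only in small or sparse strata.
* **Reference category** is user-specified, defaulting to the largest
  trajectory (a stable, well-populated baseline).
* **Age at baseline and birth cohort both enter** the model when supplied.
  They are partially collinear by construction; rather than silently dropping
  one, the fit warns when the design-matrix condition number exceeds 1e6 and
  leaves the specification to the analyst.
* **Separation** is detected by diverging coefficients (|coef| > 15 on the
  log-odds scale) and *flagged*, never silently penalised: the result carries
  `converged = FALSE` with an explanatory message. Transparency over
  automatic bias correction.
* Outcomes can be restricted to one self-reported cancer site with
  `filter_outcome_site()`. Site-specific analyses of sex-specific cancers
  (e.g. breast) should be run on the corresponding gender's panel; the
  package leaves that restriction to the caller since the panel is already
  split by gender upstream.

## The synthetic-cohort generator

`generate_cohort()` emulates the *structure* of a retrospective ageing-survey
cohort so every pipeline stage is testable without restricted data:

* **Sequences** come from `trajectory_template`s — contiguous age segments
  tiling the span. The built-in shapes (8 women's, 2 men's, each starting
  with a short full-time education segment) echo typologies described for
  mid-20th-century European cohorts; their transition ages (e.g. full-time →
  home/family at 32) are fixed module constants, configuration rather than
  estimates. Each year is corrupted independently with probability
  `noise_rate` (default 0.05) to a uniformly drawn *other* state — the
  simplest corruption consistent with clustered structure. Markov-switching
  noise would be the natural extension.
* **Covariates** are drawn from simple parametric distributions (uniform
  birth years 1914–1945, normal age ~ N(70, 7) and BMI ~ N(26.5, 4.5),
  Bernoulli smoking and low activity, Poisson(1.5) chronic-condition counts,
  multinomial attrition 0.45/0.31/0.24), generated as raw survey fields and
  passed through `code_covariates()` so the coding rules are exercised on
  every cohort.
* **Outcomes** are Bernoulli draws from the exact logistic model: intercept
  (default −2.2, giving a realistic ~10–15% lifetime prevalence), one log-OR
  per cluster (reference fixed at 0), and optional covariate effects with age
  and BMI centred at their configured means.
* **Reproducibility**: one integer seed drives everything, split
  deterministically across stages — the panel uses `seed`, covariates
  `seed + 1`, outcomes `seed + 2`. Identical configs give bit-identical
  cohorts.

**What passing tests do and do not show.** Synthetic panels are far cleaner
than real life-calendar data: noise is independent across years and subjects,
clusters are equally sized and perfectly templated, covariates are
independent of cluster membership, and attrition is independent of both. ASW
values near 0.8–0.9 on synthetic panels therefore say nothing about the
0.3–0.7 range typical of real cohorts, and perfect cluster recovery (ARI = 1
at noise 0.05) demonstrates that the machinery — distance, PAM, ASW
selection — is correct, not that real panels have recoverable structure.
Likewise the generator makes no attempt to reproduce any particular survey's
cluster sizes, silhouette values or adjusted odds ratios.

## Validation experiment sizes

The package's own validation experiments (test suite and
`scripts/acceptance.R`) use problem sizes chosen to make the statistical
checks sharp while staying comfortably interactive:

* cluster-count recovery: 100 sequences per template (n = 800 women's-like,
  n = 200 men's-like), noise 0.05, `k` searched over 2–10;
* odds-ratio recovery and CI coverage: 200 replicate cohorts of n = 5,000
  (625 per cluster), configured cluster ORs spanning 0.76–2.28, recovery
  judged within ±3 Monte-Carlo standard errors and null coverage against the
  93–97% band. These replicates generate labels, covariates and outcomes
  directly — the association stage is the quantity under test, so
  re-clustering each replicate would only add noise around true labels;
* oracle suites: brute-force Hamming at n ≤ 20, exhaustive medoid
  enumeration at n ≤ 12, naive-loop silhouettes to 1e−12, and the 2×2
  cross-product identity for the crude logistic OR to 1e−6.

## Known limitations

Dense distance storage bounds practical cohort size (~10^4 sequences);
no survey weights; no multichannel (parallel-domain) sequence analysis; no
optimal-matching distances; no imputation of calendar gaps; logistic
ever-diagnosed outcomes only (no time-to-event); no country fixed effects or
policy moderation. The typology depends on the state coding and the distance
choice — a different alphabet or an indel-tolerant distance can yield a
different cluster count — which is inherent to sequence analysis, not a
removable defect.
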