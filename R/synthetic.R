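#' Trajectory templates
#'
#' A template describes one idealised employment trajectory as contiguous
#' age segments `[age_from, age_to)` that tile the panel span. Synthetic
#' sequences are drawn by copying a template and corrupting each year
#' independently with a small probability.
#'
#' @param label template name.
#' @param segments data frame with columns `age_from`, `age_to`, `state`
#'   (alphabet code); segments must be contiguous, non-overlapping, and cover
#'   `[start_age, end_age)`.
#' @param start_age,end_age the span the segments must tile (default 16-65,
#'   half-open).
#' @return An object of class `trajectory_template`.
#' @export
trajectory_template <- function(label, segments, start_age = 16L, end_age = 65L) {
  segments <- as.data.frame(segments)
  segments <- segments[order(segments$age_from), ]
  if (segments$age_from[1L] != start_age ||
      segments$age_to[nrow(segments)] != end_age ||
      (nrow(segments) > 1L &&
       any(segments$age_from[-1L] != segments$age_to[-nrow(segments)])))
    stop("segments must tile [", start_age, ", ", end_age, ") contiguously")
  if (any(segments$age_to <= segments$age_from)) stop("empty segment")
  structure(list(label = label, segments = segments,
                 start_age = as.integer(start_age),
                 end_age = as.integer(end_age)),
            class = "trajectory_template")
}

seg <- function(from, to, state) data.frame(age_from = from, age_to = to, state = state)

#' @rdname trajectory_template
#' @param template a `trajectory_template`.
#' @return `template_states`: the integer state vector the template encodes
#'   (one entry per age in the span).
#' @export
template_states <- function(template) {
  out <- integer(template$end_age - template$start_age)
  for (i in seq_len(nrow(template$segments))) {
    sg <- template$segments[i, ]
    out[(sg$age_from:(sg$age_to - 1L)) - template$start_age + 1L] <- sg$state
  }
  out
}

#' Built-in gendered trajectory templates
#'
#' Eight women's and two men's trajectory shapes, echoing the typologies
#' reported for mid-20th-century European cohorts: every shape starts with a
#' short full-time education segment; women's shapes then diverge into
#' full-time work, home/family, transitions between the two, self-employment,
#' part-time work, unemployment or other states, while men's shapes are
#' dominated by full-time employment or self-employment. The transition ages
#' are fixed module constants (configuration, not estimates): e.g. the
#' full-time to home/family shape switches at age 32.
#'
#' State codes follow [employment_alphabet()]: 1 full-time, 2 part-time,
#' 3 self-employed, 4 unemployed, 5 home/family, 6 retired, 7 education,
#' 8 other.
#'
#' @param gender `"female"` or `"male"`.
#' @return A list of [trajectory_template()] objects (8 for female, 2 for
#'   male) tiling ages 16-64.
#' @export
builtin_templates <- function(gender = c("female", "male")) {
  gender <- match.arg(gender)
  if (gender == "female") {
    list(
      trajectory_template("Mainly full-time",
        rbind(seg(16, 20, 7), seg(20, 61, 1), seg(61, 65, 6))),
      trajectory_template("Mainly home/family",
        rbind(seg(16, 18, 7), seg(18, 65, 5))),
      trajectory_template("Mainly full-time to home/family",
        rbind(seg(16, 19, 7), seg(19, 32, 1), seg(32, 65, 5))),
      trajectory_template("Mainly self-employment",
        rbind(seg(16, 19, 7), seg(19, 62, 3), seg(62, 65, 6))),
      trajectory_template("Full-time or home/family to part time",
        rbind(seg(16, 18, 7), seg(18, 26, 1), seg(26, 34, 5),
              seg(34, 62, 2), seg(62, 65, 6))),
      trajectory_template("Home/family to full-time",
        rbind(seg(16, 18, 7), seg(18, 40, 5), seg(40, 62, 1), seg(62, 65, 6))),
      trajectory_template("Mainly unemployment",
        rbind(seg(16, 18, 7), seg(18, 65, 4))),
      trajectory_template("Other",
        rbind(seg(16, 18, 7), seg(18, 65, 8)))
    )
  } else {
    list(
      trajectory_template("Mainly full-time",
        rbind(seg(16, 20, 7), seg(20, 62, 1), seg(62, 65, 6))),
      trajectory_template("Mainly self-employment",
        rbind(seg(16, 19, 7), seg(19, 65, 3)))
    )
  }
}

#' Configuration of the synthetic-cohort generator
#'
#' Bundles everything the generator needs: trajectory templates, per-cluster
#' sizes, the per-age state noise rate, baseline covariate distributions, the
#' logistic outcome model, and a single integer seed. The seed is split
#' deterministically across stages: the sequence panel uses `seed`, the
#' covariates `seed + 1`, the outcomes `seed + 2`.
#'
#' @param templates list of [trajectory_template()]s.
#' @param n_per_cluster integer count(s) of sequences per template, recycled.
#' @param noise_rate probability, per age, of replacing the template state by
#'   a uniformly chosen *other* alphabet state; must be in `[0, 1)`.
#' @param gender gender tag stored on generated subjects.
#' @param covariate_model list of distribution parameters: `birth_year_range`
#'   (uniform), `age_mean`/`age_sd` (baseline age, normal), `bmi_mean`/
#'   `bmi_sd`, `height_mean`/`height_sd` (m), `p_smoker`, `chronic_lambda`
#'   (Poisson mean of the chronic-condition count), `p_low_activity`,
#'   `attrition_probs` (named, no_dropout/dropout/deceased).
#' @param outcome_model list with `intercept` (log-odds), `log_or_cluster`
#'   (named per template label; exactly one entry — the reference — must be
#'   0), `log_or_covariates` (named among `age_baseline`, `bmi`, `smoker`,
#'   `chronic_2plus`, `low_activity`; age and BMI enter centred at
#'   `age_mean`/`bmi_mean`).
#' @param seed integer master seed.
#' @param alphabet a [state_alphabet()].
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(templates = builtin_templates("female"),
                             n_per_cluster = 100L,
                             noise_rate = 0.05,
                             gender = "female",
                             covariate_model = list(),
                             outcome_model = list(),
                             seed = 1L,
                             alphabet = employment_alphabet()) {
  if (noise_rate < 0 || noise_rate >= 1) stop("noise_rate must be in [0, 1)")
  labels <- vapply(templates, `[[`, character(1), "label")
  if (anyDuplicated(labels)) stop("template labels must be unique")
  n_per_cluster <- rep_len(as.integer(n_per_cluster), length(templates))
  cm <- utils::modifyList(list(
    birth_year_range = c(1914L, 1945L),
    age_mean = 70, age_sd = 7,
    bmi_mean = 26.5, bmi_sd = 4.5,
    height_mean = 1.65, height_sd = 0.07,
    p_smoker = 0.10,
    chronic_lambda = 1.5,
    p_low_activity = 0.32,
    attrition_probs = c(no_dropout = 0.45, dropout = 0.31, deceased = 0.24)
  ), covariate_model)
  om <- utils::modifyList(list(
    intercept = -2.2,
    log_or_cluster = stats::setNames(rep(0, length(labels)), labels),
    log_or_covariates = c(smoker = log(1.3), chronic_2plus = log(1.25),
                          low_activity = log(1.1))
  ), outcome_model)
  if (is.null(names(om$log_or_cluster)) ||
      !setequal(names(om$log_or_cluster), labels))
    stop("outcome_model$log_or_cluster must be named by template label")
  om$log_or_cluster <- om$log_or_cluster[labels]
  if (sum(om$log_or_cluster == 0) < 1L)
    stop("one cluster log-OR must be 0 (the reference)")
  structure(list(templates = templates, labels = labels,
                 n_per_cluster = n_per_cluster, noise_rate = noise_rate,
                 gender = gender, covariate_model = cm, outcome_model = om,
                 seed = as.integer(seed), alphabet = alphabet),
            class = "synthetic_config")
}

#' Generate a synthetic sequence panel from templates
#'
#' Each sequence copies its cluster's template, then every age is corrupted
#' independently with probability `noise_rate` to a uniformly drawn *other*
#' state. Reproducible: seeded with `config$seed`.
#'
#' @param config a [synthetic_config()].
#' @return A list with `panel` (a [sequence_panel()]) and `labels` (the true
#'   template label of every subject).
#' @export
generate_panel <- function(config) {
  set.seed(config$seed)
  K <- n_states(config$alphabet)
  tmpl <- lapply(config$templates, template_states)
  L <- length(tmpl[[1L]])
  n <- sum(config$n_per_cluster)
  labels <- rep(config$labels, config$n_per_cluster)
  m <- do.call(rbind, lapply(seq_along(tmpl), function(i)
    matrix(tmpl[[i]], config$n_per_cluster[i], L, byrow = TRUE)))
  corrupt <- matrix(stats::runif(n * L) < config$noise_rate, n, L)
  nc <- sum(corrupt)
  if (nc > 0L) {
    # uniform over the K-1 other states: shift by 1..K-1 modulo K
    shift <- sample.int(K - 1L, nc, replace = TRUE)
    m[corrupt] <- ((m[corrupt] - 1L + shift) %% K) + 1L
  }
  byr <- config$covariate_model$birth_year_range
  birth_year <- sample(seq.int(byr[1L], byr[2L]), n, replace = TRUE)
  panel <- sequence_panel(m,
                          subject_id = sprintf("s%05d", seq_len(n)),
                          gender = config$gender, birth_year = birth_year,
                          start_age = config$templates[[1L]]$start_age,
                          alphabet = config$alphabet)
  list(panel = panel, labels = labels)
}

#' Generate baseline covariates for a synthetic cohort
#'
#' Raw survey-style fields (weight, height, activity items, ...) are drawn
#' from the configured distributions and passed through [code_covariates()],
#' so the covariate-coding rules are exercised on every synthetic cohort.
#' Seeded with `config$seed + 1`.
#'
#' @param true_labels cluster label per subject (defines the cohort size).
#' @param config a [synthetic_config()].
#' @param birth_year optional birth years to reuse (e.g. from the panel
#'   generated alongside); drawn uniformly from the configured range when
#'   `NULL`.
#' @param subject_id optional ids; defaults to `s00001`, ...
#' @return Coded covariate data frame as returned by [code_covariates()].
#' @export
generate_covariates <- function(true_labels, config, birth_year = NULL,
                                subject_id = NULL) {
  set.seed(config$seed + 1L)
  n <- length(true_labels)
  cm <- config$covariate_model
  if (is.null(birth_year)) {
    byr <- cm$birth_year_range
    birth_year <- sample(seq.int(byr[1L], byr[2L]), n, replace = TRUE)
  }
  if (is.null(subject_id)) subject_id <- sprintf("s%05d", seq_len(n))
  height <- stats::rnorm(n, cm$height_mean, cm$height_sd)
  bmi <- stats::rnorm(n, cm$bmi_mean, cm$bmi_sd)
  low <- stats::rbinom(n, 1L, cm$p_low_activity)
  # the 4-point activity items (1 = more than once a week); a low-activity
  # subject answers neither item with 1
  vig <- ifelse(low == 1L, sample(2:4, n, replace = TRUE), 1L)
  mod <- sample(1:4, n, replace = TRUE)
  mod[low == 1L] <- sample(2:4, sum(low == 1L), replace = TRUE)
  raw <- data.frame(
    subject_id = subject_id,
    birth_year = birth_year,
    age_baseline = pmax(50, stats::rnorm(n, cm$age_mean, cm$age_sd)),
    weight_kg = bmi * height^2,
    height_m = height,
    smoker = stats::rbinom(n, 1L, cm$p_smoker),
    chronic_count = stats::rpois(n, cm$chronic_lambda),
    activity_vigorous = vig,
    activity_moderate = mod,
    attrition = sample(names(cm$attrition_probs), n, replace = TRUE,
                       prob = cm$attrition_probs),
    stringsAsFactors = FALSE
  )
  code_covariates(raw)
}

#' Generate binary outcomes from the configured logistic model
#'
#' `P(outcome = 1) = plogis(intercept + log_or_cluster[label] + covariate
#' terms)`, with independent Bernoulli draws. Age and BMI contribute centred
#' at their configured means so the intercept keeps its interpretation as the
#' reference-subject log-odds. Seeded with `config$seed + 2`.
#'
#' @param true_labels cluster label per subject.
#' @param covariates coded covariate table (from [generate_covariates()]), or
#'   `NULL` for a trajectory-only model.
#' @param config a [synthetic_config()].
#' @return Integer 0/1 outcome vector.
#' @export
generate_outcomes <- function(true_labels, covariates, config) {
  set.seed(config$seed + 2L)
  om <- config$outcome_model
  lp <- om$intercept + unname(om$log_or_cluster[true_labels])
  if (!is.null(covariates) && length(om$log_or_covariates)) {
    cm <- config$covariate_model
    for (v in names(om$log_or_covariates)) {
      x <- covariates[[v]]
      if (is.null(x)) next
      x <- as.numeric(x)
      if (v == "age_baseline") x <- x - cm$age_mean
      if (v == "bmi") x <- x - cm$bmi_mean
      lp <- lp + om$log_or_covariates[[v]] * x
    }
  }
  stats::rbinom(length(lp), 1L, stats::plogis(lp))
}

#' Generate a full synthetic cohort
#'
#' Convenience wrapper running [generate_panel()], [generate_covariates()]
#' (reusing the panel's birth years and ids) and [generate_outcomes()].
#'
#' @param config a [synthetic_config()].
#' @return List with `panel`, `labels`, `covariates`, `outcome`.
#' @export
generate_cohort <- function(config) {
  gp <- generate_panel(config)
  cov <- generate_covariates(gp$labels, config,
                             birth_year = gp$panel$meta$birth_year,
                             subject_id = gp$panel$meta$subject_id)
  y <- generate_outcomes(gp$labels, cov, config)
  list(panel = gp$panel, labels = gp$labels, covariates = cov, outcome = y)
}
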