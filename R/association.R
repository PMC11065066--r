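#' Code birth year into historical-crisis cohorts
#'
#' Cohorts: `war` for births 1914-1918 or 1939-1945, `great_depression` for
#' 1929-1938, `no_crisis` otherwise (before 1914, 1919-1928, after 1945).
#'
#' @param birth_year integer vector of birth years.
#' @return Factor with levels `no_crisis`, `war`, `great_depression`.
#' @export
#' @examples
#' code_birth_cohort(c(1925, 1940, 1930))
code_birth_cohort <- function(birth_year) {
  birth_year <- as.integer(birth_year)
  out <- rep("no_crisis", length(birth_year))
  out[(birth_year >= 1914 & birth_year <= 1918) |
        (birth_year >= 1939 & birth_year <= 1945)] <- "war"
  out[birth_year >= 1929 & birth_year <= 1938] <- "great_depression"
  out[is.na(birth_year)] <- NA
  factor(out, levels = c("no_crisis", "war", "great_depression"))
}

#' Code raw baseline survey fields into the adjustment covariate set
#'
#' Dichotomisations follow the usual baseline conventions of ageing cohorts:
#' two or more chronic conditions; *low* physical activity when neither the
#' vigorous nor the moderate activity item is answered "more than once a week"
#' (code 1 on the 4-point scale 1 = more than once a week ... 4 = hardly ever
#' or never); BMI from self-reported weight (kg) and height (m). Subjects with
#' any missing field are flagged for complete-case exclusion, never imputed.
#'
#' @param raw data frame with columns `subject_id`, `birth_year`,
#'   `age_baseline`, `weight_kg`, `height_m`, `smoker` (0/1),
#'   `chronic_count` (integer), `activity_vigorous`, `activity_moderate`
#'   (1-4 scales), `attrition` (`no_dropout`/`dropout`/`deceased`).
#' @return Data frame with columns `subject_id`, `age_baseline`,
#'   `birth_cohort`, `bmi`, `smoker`, `chronic_2plus`, `low_activity`,
#'   `attrition`, and `exclude` (TRUE when any source field is missing).
#' @export
code_covariates <- function(raw) {
  need <- c("subject_id", "birth_year", "age_baseline", "weight_kg", "height_m",
            "smoker", "chronic_count", "activity_vigorous", "activity_moderate",
            "attrition")
  miss <- setdiff(need, names(raw))
  if (length(miss)) stop("raw covariates missing columns: ",
                         paste(miss, collapse = ", "))
  out <- data.frame(
    subject_id = as.character(raw$subject_id),
    age_baseline = as.numeric(raw$age_baseline),
    birth_cohort = code_birth_cohort(raw$birth_year),
    bmi = as.numeric(raw$weight_kg) / as.numeric(raw$height_m)^2,
    smoker = as.integer(raw$smoker),
    chronic_2plus = as.integer(as.numeric(raw$chronic_count) >= 2),
    low_activity = as.integer(!(raw$activity_vigorous %in% 1L |
                                  raw$activity_moderate %in% 1L)),
    attrition = factor(as.character(raw$attrition),
                       levels = c("no_dropout", "dropout", "deceased")),
    stringsAsFactors = FALSE
  )
  out$low_activity[is.na(raw$activity_vigorous) | is.na(raw$activity_moderate)] <- NA
  out$exclude <- Reduce(`|`, lapply(out[setdiff(names(out), "subject_id")], is.na))
  out
}

#' Logistic association between trajectory membership and a binary outcome
#'
#' Fits a maximum-likelihood logistic regression of the outcome on trajectory
#' indicator variables (the reference trajectory omitted) plus any adjustment
#' covariates supplied, and reports per-trajectory odds ratios with 95% Wald
#' confidence intervals, `exp(coef +/- 1.96 SE)`. Analysis is complete-case.
#' Quasi-complete separation is flagged (any |coefficient| above 15 on the
#' log-odds scale) rather than silently penalised, and a warning is emitted
#' when the design matrix condition number exceeds 1e6 (e.g. age and birth
#' cohort are partially collinear).
#'
#' @param outcome binary (0/1) outcome vector.
#' @param trajectory trajectory assignment vector (one label per subject).
#' @param covariates optional data frame of adjustment covariates; any of
#'   `age_baseline`, `birth_cohort`, `bmi`, `smoker`, `chronic_2plus`,
#'   `low_activity`, `attrition` present are used.
#' @param reference reference trajectory label; defaults to the largest
#'   trajectory.
#' @return An object of class `association_result`: `reference`, `table`
#'   (per non-reference trajectory: `or`, `ci_low`, `ci_high`, `log_or`,
#'   `se`, `p`), `n`, `n_excluded`, `covariates_used`, `converged`,
#'   `message`, and the full `coefficients`/`se` vectors.
#' @export
fit_trajectory_outcome_model <- function(outcome, trajectory,
                                         covariates = NULL, reference = NULL) {
  trajectory <- as.character(trajectory)
  outcome <- as.integer(outcome)
  if (length(outcome) != length(trajectory))
    stop("outcome and trajectory lengths differ")
  if (!all(outcome %in% c(0L, 1L, NA)))
    stop("outcome must be binary 0/1")
  if (is.null(reference))
    reference <- names(which.max(table(trajectory)))
  reference <- as.character(reference)
  if (!reference %in% trajectory)
    stop("reference trajectory '", reference, "' is empty")
  dat <- data.frame(.y = outcome,
                    .traj = stats::relevel(factor(trajectory), ref = reference))
  cov_used <- character()
  if (!is.null(covariates)) {
    allowed <- c("age_baseline", "birth_cohort", "bmi", "smoker",
                 "chronic_2plus", "low_activity", "attrition")
    cov_used <- intersect(allowed, names(covariates))
    for (v in cov_used) dat[[v]] <- covariates[[v]]
  }
  cc <- stats::complete.cases(dat)
  n_excluded <- sum(!cc)
  dat <- dat[cc, , drop = FALSE]
  if (length(unique(dat$.y[dat$.traj == reference])) < 2L)
    warning("reference trajectory has a single outcome value; ",
            "odds ratios may be unstable")
  rhs <- paste(c(".traj", cov_used), collapse = " + ")
  form <- stats::as.formula(paste(".y ~", rhs))
  X <- stats::model.matrix(form, dat)
  if (kappa(X, exact = FALSE) > 1e6)
    warning("design matrix condition number exceeds 1e6; ",
            "covariates may be nearly collinear")
  fit <- stats::glm(form, family = stats::binomial(), data = dat)
  co <- stats::coef(fit)
  se <- sqrt(diag(stats::vcov(fit)))
  separated <- any(abs(co) > 15, na.rm = TRUE)
  converged <- isTRUE(fit$converged) && !separated && !anyNA(co)
  msg <- if (separated)
    "possible quasi-complete separation: |coefficient| > 15 on the log-odds scale"
  else if (!isTRUE(fit$converged)) "IWLS did not converge"
  else if (anyNA(co)) "aliased coefficients dropped by the fit"
  else "ok"
  tr_levels <- setdiff(levels(dat$.traj), reference)
  nm <- paste0(".traj", tr_levels)
  lo <- co[nm]; lse <- se[nm]
  tab <- data.frame(
    trajectory = tr_levels,
    or = exp(lo),
    ci_low = exp(lo - 1.96 * lse),
    ci_high = exp(lo + 1.96 * lse),
    log_or = lo,
    se = lse,
    p = 2 * stats::pnorm(-abs(lo / lse)),
    row.names = NULL, stringsAsFactors = FALSE
  )
  structure(
    list(reference = reference, table = tab, n = nrow(dat),
         n_excluded = n_excluded, covariates_used = cov_used,
         converged = converged, message = msg,
         coefficients = co, se = se),
    class = "association_result"
  )
}

#' @export
print.association_result <- function(x, ...) {
  cat(sprintf("association_result: n = %d (%d excluded), reference = %s%s\n",
              x$n, x$n_excluded, x$reference,
              if (x$converged) "" else paste0(" [NOT CONVERGED: ", x$message, "]")))
  print(make_association_table(x), row.names = FALSE)
  invisible(x)
}

#' Format an association result as a printed odds-ratio table
#'
#' One row per trajectory, `"OR (lo-hi)"` with two decimals and an en dash,
#' the reference trajectory marked `"Ref."`.
#'
#' @param result an `association_result`.
#' @return Data frame with columns `trajectory` and `or_ci`.
#' @export
make_association_table <- function(result) {
  fmt <- sprintf("%.2f (%.2f–%.2f)", result$table$or,
                 result$table$ci_low, result$table$ci_high)
  data.frame(trajectory = c(result$reference, result$table$trajectory),
             or_ci = c("Ref.", fmt),
             stringsAsFactors = FALSE)
}

#' Restrict a cancer outcome to one self-reported site
#'
#' @param outcome_table data frame with columns `subject_id`, `cancer` (0/1)
#'   and `site` (text; empty or `NA` when no site reported).
#' @param site site to select, or `NULL` for overall (any-site) cancer.
#' @param known_sites vocabulary of valid sites.
#' @return Integer 0/1 vector: 1 only for subjects reporting cancer of that
#'   site.
#' @export
filter_outcome_site <- function(outcome_table, site = NULL,
                                known_sites = c("lung", "colon", "skin",
                                                "breast", "cervix", "stomach",
                                                "ovarian", "other")) {
  cancer <- as.integer(outcome_table$cancer)
  if (is.null(site)) return(cancer)
  if (!site %in% known_sites) stop("unknown cancer site: ", site)
  s <- as.character(outcome_table$site)
  as.integer(cancer == 1L & !is.na(s) & s == site)
}
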