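test_that("birth cohorts follow the crisis-period year bands", {
  expect_equal(as.character(code_birth_cohort(c(1925, 1940, 1930))),
               c("no_crisis", "war", "great_depression"))
  # boundaries of every band
  years <- c(1913, 1914, 1918, 1919, 1928, 1929, 1938, 1939, 1945, 1946)
  expect_equal(as.character(code_birth_cohort(years)),
               c("no_crisis", "war", "war", "no_crisis", "no_crisis",
                 "great_depression", "great_depression", "war", "war",
                 "no_crisis"))
  expect_true(is.na(code_birth_cohort(NA)))
})

raw_row <- function(...) {
  base <- list(subject_id = "s1", birth_year = 1935L, age_baseline = 70,
               weight_kg = 70, height_m = 1.7, smoker = 0L, chronic_count = 1L,
               activity_vigorous = 1L, activity_moderate = 3L,
               attrition = "no_dropout")
  do.call(data.frame, utils::modifyList(base, list(...)))
}

test_that("covariate coding dichotomises chronic conditions and activity", {
  expect_equal(code_covariates(raw_row(chronic_count = 1L))$chronic_2plus, 0L)
  expect_equal(code_covariates(raw_row(chronic_count = 2L))$chronic_2plus, 1L)
  # vigorous "once a week" (2), moderate "hardly ever" (4): neither is
  # "more than once a week" -> low activity
  expect_equal(code_covariates(raw_row(activity_vigorous = 2L,
                                       activity_moderate = 4L))$low_activity, 1L)
  expect_equal(code_covariates(raw_row(activity_vigorous = 3L,
                                       activity_moderate = 1L))$low_activity, 0L)
  cc <- code_covariates(raw_row(weight_kg = 68, height_m = 1.6))
  expect_equal(cc$bmi, 68 / 1.6^2)
  expect_equal(as.character(cc$birth_cohort), "great_depression")
  expect_false(cc$exclude)
})

test_that("missing covariate fields flag the subject for exclusion", {
  expect_true(code_covariates(raw_row(weight_kg = NA))$exclude)
  expect_true(code_covariates(raw_row(activity_moderate = NA))$exclude)
  expect_true(code_covariates(raw_row(attrition = NA))$exclude)
  expect_error(code_covariates(raw_row()[-2]), "missing columns")
})

expand_2x2 <- function(n11, n10, n01, n00, lvl = c("A", "B")) {
  # n11: exposed cases, n10: exposed non-cases, n01/n00 reference
  list(outcome = c(rep(1, n11), rep(0, n10), rep(1, n01), rep(0, n00)),
       traj = c(rep(lvl[1], n11 + n10), rep(lvl[2], n01 + n00)))
}

test_that("the crude logistic OR on a 2x2 equals the cross-product ratio", {
  tab <- expand_2x2(120, 905, 707, 3984, c("self", "fulltime"))
  res <- fit_trajectory_outcome_model(tab$outcome, tab$traj,
                                      reference = "fulltime")
  expect_equal(res$table$or, (120 * 3984) / (905 * 707), tolerance = 1e-6)
  expect_true(res$converged)
  expect_true(res$table$ci_low <= res$table$or &&
                res$table$or <= res$table$ci_high)
})

test_that("an irrelevant covariate leaves the OR essentially unchanged", {
  set.seed(41)
  n <- 4000
  traj <- sample(c("A", "B"), n, replace = TRUE)
  y <- rbinom(n, 1, plogis(-1 + 0.5 * (traj == "B")))
  base <- fit_trajectory_outcome_model(y, traj, reference = "A")
  noise <- data.frame(bmi = rnorm(n, 26.5, 4))
  adj <- fit_trajectory_outcome_model(y, traj, noise, reference = "A")
  expect_equal(adj$table$or, base$table$or, tolerance = 0.01)
  expect_equal(adj$covariates_used, "bmi")
})

test_that("switching the reference maps ORs by the ratio rule", {
  set.seed(42)
  n <- 1500
  traj <- sample(c("A", "B", "C"), n, replace = TRUE)
  y <- rbinom(n, 1, plogis(-1 + 0.4 * (traj == "B") - 0.3 * (traj == "C")))
  ra <- fit_trajectory_outcome_model(y, traj, reference = "A")
  rb <- fit_trajectory_outcome_model(y, traj, reference = "B")
  or_b_vs_a <- ra$table$or[ra$table$trajectory == "B"]
  or_c_vs_a <- ra$table$or[ra$table$trajectory == "C"]
  expect_equal(rb$table$or[rb$table$trajectory == "C"],
               or_c_vs_a / or_b_vs_a, tolerance = 1e-6)
  expect_equal(rb$table$or[rb$table$trajectory == "A"],
               1 / or_b_vs_a, tolerance = 1e-6)
})

test_that("degenerate designs are reported, not silently fitted", {
  expect_error(fit_trajectory_outcome_model(c(0, 1), c("A", "A"),
                                            reference = "B"), "empty")
  # quasi-complete separation: outcome determined by trajectory
  traj <- rep(c("A", "B"), each = 40)
  y <- as.integer(traj == "B")
  res <- suppressWarnings(fit_trajectory_outcome_model(y, traj, reference = "A"))
  expect_false(res$converged)
  expect_match(res$message, "separation")
})

test_that("nearly collinear covariates trigger a condition-number warning", {
  set.seed(43)
  n <- 400
  traj <- sample(c("A", "B"), n, replace = TRUE)
  cov <- data.frame(age_baseline = rnorm(n, 70, 7))
  cov$bmi <- cov$age_baseline * 1e4 + rnorm(n, 0, 1e-4)
  y <- rbinom(n, 1, 0.3)
  expect_warning(fit_trajectory_outcome_model(y, traj, cov, reference = "A"),
                 "condition number")
})

test_that("association tables print OR (low-high) with a Ref. row", {
  res <- structure(list(reference = "Mainly home/family",
                        table = data.frame(trajectory = c("Mainly full-time", "x"),
                                           or = c(1.7321, 0.999),
                                           ci_low = c(1.401, 0.95),
                                           ci_high = c(2.158, 1.049))),
                   class = "association_result")
  tab <- make_association_table(res)
  expect_equal(tab$or_ci[tab$trajectory == "Mainly home/family"], "Ref.")
  expect_equal(tab$or_ci[tab$trajectory == "Mainly full-time"],
               "1.73 (1.40–2.16)")
  expect_equal(tab$or_ci[tab$trajectory == "x"], "1.00 (0.95–1.05)")
})

test_that("site filtering selects only the requested cancer site", {
  toy <- data.frame(subject_id = c("a", "b", "c"),
                    cancer = c(1L, 1L, 0L),
                    site = c("breast", "colon", NA))
  expect_equal(filter_outcome_site(toy, "breast"), c(1L, 0L, 0L))
  expect_equal(filter_outcome_site(toy, NULL), c(1L, 1L, 0L))
  expect_error(filter_outcome_site(toy, "prostate"), "unknown cancer site")
  none <- data.frame(subject_id = "a", cancer = 0L, site = NA)
  expect_equal(filter_outcome_site(none, "breast"), 0L)
  # any site filter is a subset of the overall outcome
  set.seed(44)
  big <- data.frame(subject_id = seq_len(200),
                    cancer = rbinom(200, 1, 0.3),
                    site = sample(c("breast", "colon", "skin", NA), 200,
                                  replace = TRUE))
  overall <- filter_outcome_site(big, NULL)
  for (s in c("breast", "colon", "skin"))
    expect_true(all(filter_outcome_site(big, s) <= overall))
})
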