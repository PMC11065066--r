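#' Construct a panel of aligned state sequences
#'
#' A `sequence_panel` holds one categorical state sequence per subject, all
#' aligned on the same yearly age axis. States are stored as an integer matrix
#' (rows = subjects, columns = ages); `NA` marks years with no information.
#'
#' @param states integer matrix of alphabet codes, one row per subject, one
#'   column per age. `NA` entries are missing years.
#' @param subject_id character vector of unique subject identifiers.
#' @param gender character vector (`"female"`/`"male"`), recycled if length 1.
#' @param birth_year integer vector of birth years, recycled if length 1.
#' @param start_age age (in years) of the first column.
#' @param alphabet a [state_alphabet()]; defaults to [employment_alphabet()].
#' @return An object of class `sequence_panel` with elements `states`, `meta`
#'   (data frame of subject_id, gender, birth_year), `start_age`, `alphabet`.
#' @export
#' @examples
#' m <- rbind(c(7, 1, 1), c(7, 5, 5))
#' sequence_panel(m, subject_id = c("a", "b"), gender = "female",
#'                birth_year = 1940, start_age = 16)
sequence_panel <- function(states, subject_id, gender = NA_character_,
                           birth_year = NA_integer_, start_age = 16L,
                           alphabet = employment_alphabet()) {
  check_alphabet(alphabet)
  states <- as.matrix(states)
  storage.mode(states) <- "integer"
  n <- nrow(states)
  subject_id <- as.character(subject_id)
  if (length(subject_id) != n) stop("subject_id length must match rows of states")
  if (anyDuplicated(subject_id)) {
    dup <- subject_id[duplicated(subject_id)][1L]
    stop("duplicate subject_id: ", dup)
  }
  gender <- rep_len(as.character(gender), n)
  birth_year <- rep_len(as.integer(birth_year), n)
  bad <- states[!is.na(states)]
  if (length(bad) && (any(bad < 1L) || any(bad > n_states(alphabet))))
    stop("state codes outside the alphabet")
  start_age <- as.integer(start_age)
  dimnames(states) <- list(subject_id,
                           paste0("age_", seq_len(ncol(states)) + start_age - 1L))
  structure(
    list(states = states,
         meta = data.frame(subject_id = subject_id, gender = gender,
                           birth_year = birth_year, stringsAsFactors = FALSE),
         start_age = start_age,
         alphabet = alphabet),
    class = "sequence_panel"
  )
}

#' @export
print.sequence_panel <- function(x, ...) {
  cat(sprintf("sequence_panel: %d sequences x %d states (ages %d-%d), %d-state alphabet\n",
              nrow(x$states), ncol(x$states), x$start_age,
              x$start_age + ncol(x$states) - 1L, n_states(x$alphabet)))
  invisible(x)
}

#' Panel dimensions
#'
#' @param panel a `sequence_panel`.
#' @return `n_sequences`: number of subjects; `panel_ages`: integer vector of
#'   the ages covered (one per column).
#' @export
n_sequences <- function(panel) nrow(panel$states)

#' @rdname n_sequences
#' @export
panel_ages <- function(panel) seq_len(ncol(panel$states)) + panel$start_age - 1L

as_table <- function(x) {
  if (is.character(x) && length(x) == 1L)
    x <- utils::read.csv(x, stringsAsFactors = FALSE)
  as.data.frame(x)
}

#' Read life-calendar data in long format
#'
#' Long format has one row per subject-year: columns `subject_id`, `gender`,
#' `birth_year`, `age`, `state`. Years absent from the table (within the
#' panel's span) are recorded as missing; a missing/empty `state` value is
#' also treated as missing.
#'
#' @param x a data frame or path to a CSV file.
#' @param alphabet a [state_alphabet()].
#' @param start_age,end_age optional span; the panel covers ages in
#'   `[start_age, end_age)`. Defaults to the range of ages observed.
#' @return A [sequence_panel()].
#' @export
read_long <- function(x, alphabet = employment_alphabet(),
                      start_age = NULL, end_age = NULL) {
  tab <- as_table(x)
  need <- c("subject_id", "gender", "birth_year", "age", "state")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop("long table missing columns: ", paste(miss, collapse = ", "))
  tab$subject_id <- as.character(tab$subject_id)
  tab$age <- as.integer(tab$age)
  if (nrow(tab) == 0L) {
    sa <- if (is.null(start_age)) 16L else as.integer(start_age)
    ea <- if (is.null(end_age)) sa + 49L else as.integer(end_age)
    return(sequence_panel(matrix(NA_integer_, 0L, ea - sa),
                          subject_id = character(), start_age = sa,
                          alphabet = alphabet))
  }
  dup <- duplicated(tab[c("subject_id", "age")])
  if (any(dup)) {
    d <- tab$subject_id[dup][1L]
    stop("duplicate (subject, age) rows for subject ", d)
  }
  st <- tab$state
  if (is.character(st)) st[!nzchar(trimws(st))] <- NA
  st <- suppressWarnings(as.integer(st))
  ok <- is.na(st) | (st >= 1L & st <= n_states(alphabet))
  if (!all(ok)) stop("unknown state code: ", tab$state[!ok][1L])
  if (is.null(start_age)) start_age <- min(tab$age)
  if (is.null(end_age)) end_age <- max(tab$age) + 1L
  start_age <- as.integer(start_age); end_age <- as.integer(end_age)
  if (start_age >= end_age) stop("start_age must be below end_age")
  L <- end_age - start_age
  ids <- unique(tab$subject_id)
  m <- matrix(NA_integer_, length(ids), L)
  keep <- tab$age >= start_age & tab$age < end_age
  ri <- match(tab$subject_id[keep], ids)
  ci <- tab$age[keep] - start_age + 1L
  m[cbind(ri, ci)] <- st[keep]
  first <- match(ids, tab$subject_id)
  sequence_panel(m, subject_id = ids, gender = tab$gender[first],
                 birth_year = tab$birth_year[first], start_age = start_age,
                 alphabet = alphabet)
}

#' Write a panel in long format
#'
#' @param panel a `sequence_panel`.
#' @param file optional path; when `NULL` the long-format data frame is
#'   returned instead of written.
#' @return The long-format data frame, invisibly when written to file.
#' @export
write_long <- function(panel, file = NULL) {
  ages <- panel_ages(panel)
  n <- n_sequences(panel)
  out <- data.frame(
    subject_id = rep(panel$meta$subject_id, each = length(ages)),
    gender = rep(panel$meta$gender, each = length(ages)),
    birth_year = rep(panel$meta$birth_year, each = length(ages)),
    age = rep(ages, times = n),
    state = as.integer(t(panel$states)),
    stringsAsFactors = FALSE
  )
  if (is.null(file)) return(out)
  utils::write.csv(out, file, row.names = FALSE, na = "")
  invisible(out)
}

#' Read life-calendar data in wide format
#'
#' Wide format has one row per subject with columns `subject_id`, `gender`,
#' `birth_year` and one column per age named `age_16`, `age_17`, ...
#'
#' @inheritParams read_long
#' @return A [sequence_panel()].
#' @export
read_wide <- function(x, alphabet = employment_alphabet(),
                      start_age = NULL, end_age = NULL) {
  tab <- as_table(x)
  need <- c("subject_id", "gender", "birth_year")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop("wide table missing columns: ", paste(miss, collapse = ", "))
  agecols <- grep("^age_[0-9]+$", names(tab), value = TRUE)
  extra <- setdiff(names(tab), c(need, agecols))
  if (length(extra)) stop("unrecognised columns in wide table: ",
                          paste(extra, collapse = ", "))
  if (!length(agecols)) stop("wide table has no age_* columns")
  ages <- as.integer(sub("^age_", "", agecols))
  o <- order(ages)
  ages <- ages[o]; agecols <- agecols[o]
  if (!is.null(start_age) || !is.null(end_age)) {
    sa <- if (is.null(start_age)) min(ages) else as.integer(start_age)
    ea <- if (is.null(end_age)) max(ages) + 1L else as.integer(end_age)
    out_of_span <- ages < sa | ages >= ea
    if (any(out_of_span))
      stop("column header outside span: age_", ages[out_of_span][1L])
  }
  if (!identical(ages, seq.int(min(ages), max(ages))))
    stop("wide age columns must cover contiguous ages")
  m <- as.matrix(tab[agecols])
  sequence_panel(m, subject_id = tab$subject_id, gender = tab$gender,
                 birth_year = tab$birth_year, start_age = min(ages),
                 alphabet = alphabet)
}

#' Write a panel in wide format
#'
#' @inheritParams write_long
#' @return The wide-format data frame, invisibly when written to file.
#' @export
write_wide <- function(panel, file = NULL) {
  out <- cbind(panel$meta, as.data.frame(panel$states, row.names = NULL))
  if (is.null(file)) return(out)
  utils::write.csv(out, file, row.names = FALSE, na = "")
  invisible(out)
}

#' Align a panel to a common age span
#'
#' Restricts every sequence to ages in the half-open interval
#' `[start_age, end_age)`. The default span 16-65 yields sequences of length
#' 49. Ages present in the panel but outside the span are discarded; ages in
#' the span but absent from the panel become missing. Idempotent.
#'
#' @param panel a `sequence_panel`.
#' @param start_age first age retained (default 16).
#' @param end_age first age beyond the span (default 65, exclusive).
#' @return An aligned `sequence_panel` of width `end_age - start_age`.
#' @export
#' @examples
#' p <- sequence_panel(matrix(1L, 1, 60), "s1", start_age = 15)
#' ncol(align(p)$states)  # 49
align <- function(panel, start_age = 16L, end_age = 65L) {
  start_age <- as.integer(start_age); end_age <- as.integer(end_age)
  if (start_age >= end_age) stop("start_age must be below end_age")
  L <- end_age - start_age
  old_ages <- panel_ages(panel)
  m <- matrix(NA_integer_, n_sequences(panel), L)
  new_ages <- seq.int(start_age, end_age - 1L)
  common <- intersect(old_ages, new_ages)
  if (length(common))
    m[, match(common, new_ages)] <- panel$states[, match(common, old_ages)]
  sequence_panel(m, subject_id = panel$meta$subject_id,
                 gender = panel$meta$gender,
                 birth_year = panel$meta$birth_year,
                 start_age = start_age, alphabet = panel$alphabet)
}

#' Drop subjects with incomplete sequences
#'
#' Mirrors the complete-case inclusion rule of retrospective life-history
#' studies: a subject is retained only if a state is recorded for every age
#' in the span. No imputation is attempted.
#'
#' @param panel an aligned `sequence_panel`.
#' @return A list with elements `panel` (the retained subjects, unaltered) and
#'   `report`, a data frame of exclusion reasons and counts.
#' @export
filter_complete <- function(panel) {
  complete <- rowSums(is.na(panel$states)) == 0L
  kept <- sequence_panel(panel$states[complete, , drop = FALSE],
                         subject_id = panel$meta$subject_id[complete],
                         gender = panel$meta$gender[complete],
                         birth_year = panel$meta$birth_year[complete],
                         start_age = panel$start_age,
                         alphabet = panel$alphabet)
  report <- data.frame(
    reason = c("retained", "missing employment information"),
    n = c(sum(complete), sum(!complete)),
    stringsAsFactors = FALSE
  )
  attr(report, "excluded_ids") <- panel$meta$subject_id[!complete]
  list(panel = kept, report = report)
}
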