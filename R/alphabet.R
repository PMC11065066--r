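#' State alphabets for life-calendar sequences
#'
#' A state alphabet maps small integer codes to state labels. Codes must be
#' unique and contiguous from 1 so that sequences can be stored as plain
#' integer vectors and chronogram rows indexed by code.
#'
#' @param labels character vector of state labels; codes are assigned 1..K in
#'   order.
#' @return An object of class `state_alphabet`: a data frame with columns
#'   `code` (integer) and `label` (character).
#' @seealso [employment_alphabet()] for the default 8-state employment coding.
#' @export
#' @examples
#' state_alphabet(c("A", "B", "C"))
state_alphabet <- function(labels) {
  labels <- as.character(labels)
  if (length(labels) < 1L) stop("alphabet needs at least one state")
  if (anyDuplicated(labels)) stop("alphabet labels must be unique")
  out <- data.frame(code = seq_along(labels), label = labels,
                    stringsAsFactors = FALSE)
  class(out) <- c("state_alphabet", "data.frame")
  out
}

#' The 8-category employment state alphabet
#'
#' Default coding of yearly labour-market status used throughout the package:
#' 1 employed full-time, 2 employed part-time, 3 self-employed, 4 unemployed,
#' 5 home/family, 6 retired, 7 full-time education, 8 other (illness or
#' disability, voluntary work, military service, travelling).
#'
#' @return A `state_alphabet` with exactly 8 entries.
#' @export
#' @examples
#' employment_alphabet()
employment_alphabet <- function() {
  state_alphabet(c(
    "Employed full-time",
    "Employed part-time",
    "Self-employed",
    "Unemployed",
    "Home/family",
    "Retired",
    "Full-time education",
    "Other"
  ))
}

n_states <- function(alphabet) nrow(alphabet)

check_alphabet <- function(alphabet) {
  if (!inherits(alphabet, "state_alphabet")) stop("not a state_alphabet")
  if (!identical(alphabet$code, seq_len(nrow(alphabet))))
    stop("alphabet codes must be contiguous from 1")
  invisible(alphabet)
}
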