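#' Pairwise Hamming dissimilarity between aligned sequences
#'
#' The Hamming distance between two equal-length state sequences is the number
#' of ages at which they hold different states. Because no shifting or indels
#' are allowed, it is sensitive to the *timing* of states: the same spell
#' occurring at different ages counts as mismatch. It is a metric (symmetric,
#' zero diagonal, triangle inequality) bounded by the sequence length.
#'
#' @param panel an aligned, complete [sequence_panel()] (no missing states).
#' @return A symmetric numeric matrix of class `dissimilarity_matrix` with
#'   subject ids as dimnames and the sequence length in
#'   `attr(, "seq_length")`.
#' @export
#' @examples
#' p <- sequence_panel(rbind(c(1, 1, 5, 5), c(1, 5, 5, 6)), c("a", "b"))
#' hamming_matrix(p)["a", "b"]  # 2
hamming_matrix <- function(panel) {
  if (!inherits(panel, "sequence_panel")) stop("panel must be a sequence_panel")
  if (anyNA(panel$states))
    stop("panel has missing states; align and filter_complete first")
  m <- panel$states
  n <- nrow(m)
  L <- ncol(m)
  d <- matrix(0, n, n)
  # accumulate positionwise mismatch indicators age by age
  for (j in seq_len(L)) {
    s <- m[, j]
    d <- d + (outer(s, s, "!=") * 1)
  }
  dimnames(d) <- list(panel$meta$subject_id, panel$meta$subject_id)
  attr(d, "seq_length") <- L
  class(d) <- c("dissimilarity_matrix", class(d))
  d
}

#' Normalize a dissimilarity matrix
#'
#' @param d a `dissimilarity_matrix`.
#' @param by `"none"` (identity) or `"length"` (divide by the sequence length,
#'   mapping entries into `[0, 1]`).
#' @return The (possibly rescaled) matrix; `attr(, "normalized")` records the
#'   choice.
#' @export
normalize_dissimilarity <- function(d, by = c("none", "length")) {
  by <- match.arg(by)
  if (by == "none") return(d)
  L <- attr(d, "seq_length")
  if (is.null(L) || L <= 0) stop("matrix has no positive seq_length attribute")
  out <- d / L
  attr(out, "seq_length") <- L
  attr(out, "normalized") <- "length"
  class(out) <- class(d)
  out
}

#' Export / import a dissimilarity matrix as CSV
#'
#' The CSV has a header row of subject ids and one labelled row per subject.
#'
#' @param d a `dissimilarity_matrix`.
#' @param file path to a CSV file.
#' @return `read_dissimilarity` returns a `dissimilarity_matrix`.
#' @export
write_dissimilarity <- function(d, file) {
  utils::write.csv(as.data.frame(unclass(d)), file, row.names = TRUE)
  invisible(d)
}

#' @rdname write_dissimilarity
#' @param seq_length the sequence length the distances were computed on
#'   (restored into the attribute; optional).
#' @export
read_dissimilarity <- function(file, seq_length = NULL) {
  tab <- utils::read.csv(file, row.names = 1, check.names = FALSE)
  d <- as.matrix(tab)
  if (!isTRUE(all.equal(d, t(d)))) stop("matrix in file is not symmetric")
  if (!is.null(seq_length)) attr(d, "seq_length") <- as.integer(seq_length)
  class(d) <- c("dissimilarity_matrix", class(d))
  d
}
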