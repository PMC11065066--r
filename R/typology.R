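#' Chronograms: age-by-state distributions per cluster
#'
#' A chronogram describes a trajectory type by the cross-sectional state
#' distribution at every age: entry (state, age) is the fraction of the
#' cluster's subjects holding that state at that age. Every age column of a
#' complete panel sums to 1.
#'
#' @param panel an aligned, complete [sequence_panel()].
#' @param cluster cluster assignment vector (one label per subject).
#' @return A named list of matrices, one per cluster, with one row per
#'   alphabet state (labelled) and one column per age.
#' @export
chronogram <- function(panel, cluster) {
  if (length(cluster) != n_sequences(panel))
    stop("cluster must have one label per subject")
  if (anyNA(panel$states)) stop("panel has missing states")
  K <- n_states(panel$alphabet)
  ages <- panel_ages(panel)
  out <- lapply(split(seq_len(n_sequences(panel)), cluster), function(rows) {
    if (!length(rows)) stop("empty cluster")
    m <- vapply(seq_along(ages), function(j)
      tabulate(panel$states[rows, j], nbins = K) / length(rows),
      numeric(K))
    dimnames(m) <- list(panel$alphabet$label, paste0("age_", ages))
    m
  })
  out
}

#' Write chronogram matrices to CSV, one file per cluster
#'
#' @param chron result of [chronogram()].
#' @param dir output directory; files are named `chronogram_<cluster>.csv`.
#' @return The file paths, invisibly.
#' @export
write_chronogram <- function(chron, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- vapply(names(chron), function(cl) {
    path <- file.path(dir, paste0("chronogram_", cl, ".csv"))
    utils::write.csv(as.data.frame(chron[[cl]]), path, row.names = TRUE)
    path
  }, character(1))
  invisible(paths)
}

# total Hamming distance of each row to all other rows, via per-age state
# counts: sum_j 1[s_i(a) != s_j(a)] = n - count(s_i(a)); O(n * L), no matrix
hamming_rowsums <- function(m, K) {
  n <- nrow(m)
  tot <- numeric(n)
  for (j in seq_len(ncol(m))) {
    cnt <- tabulate(m[, j], nbins = K)
    tot <- tot + (n - cnt[m[, j]])
  }
  tot
}

# round half away from zero, as printed tables do (base round() is half-even)
round_half_up <- function(x, digits = 1L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Cluster composition summary for a trajectory typology
#'
#' Produces the counts, percentages, modal state path and medoid of every
#' cluster, in the shape of a cohort characteristics table. Cluster naming is
#' deliberately left to the user: the modal path is provided to assist naming,
#' never to auto-name.
#'
#' @param panel an aligned, complete [sequence_panel()].
#' @param cluster cluster assignment vector.
#' @param label_names optional named character vector mapping cluster labels
#'   to display names; clusters missing from the map fall back to their label.
#' @param d optional dissimilarity matrix used to locate each cluster's
#'   medoid. When absent, Hamming medoids are found directly from state
#'   counts (equivalent, and linear in panel size).
#' @return A data frame of class `typology_summary` with columns `cluster`,
#'   `name`, `n`, `pct` (half-up, one decimal), `medoid_id`, `modal_path`
#'   (modal state code per age, collapsed to a string).
#' @export
typology_summary <- function(panel, cluster, label_names = NULL, d = NULL) {
  if (length(cluster) != n_sequences(panel))
    stop("cluster must have one label per subject")
  groups <- split(seq_len(n_sequences(panel)), cluster)
  n_total <- n_sequences(panel)
  K <- n_states(panel$alphabet)
  rows <- lapply(names(groups), function(cl) {
    rows <- groups[[cl]]
    if (is.null(d)) {
      med <- rows[which.min(hamming_rowsums(panel$states[rows, , drop = FALSE], K))]
    } else {
      sub <- unclass(d)[rows, rows, drop = FALSE]
      med <- rows[which.min(rowSums(sub))]
    }
    modal <- apply(panel$states[rows, , drop = FALSE], 2L, function(s)
      which.max(tabulate(s, nbins = K)))
    nm <- if (!is.null(label_names) && cl %in% names(label_names))
      unname(label_names[cl]) else cl
    data.frame(cluster = cl, name = nm, n = length(rows),
               pct = round_half_up(100 * length(rows) / n_total, 1L),
               medoid_id = panel$meta$subject_id[med],
               modal_path = paste(modal, collapse = "-"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$n), ]
  rownames(out) <- NULL
  class(out) <- c("typology_summary", "data.frame")
  out
}
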