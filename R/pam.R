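#' Partitioning around medoids on a precomputed dissimilarity matrix
#'
#' Classical deterministic PAM. The BUILD phase seeds medoids greedily: the
#' first medoid minimizes the total distance to all points, and each further
#' medoid is the point whose addition most reduces the total cost. The SWAP
#' phase then repeatedly applies the single best (medoid, non-medoid) exchange
#' as long as it *strictly* reduces the total cost, so the result is
#' reproducible without random restarts. Ties (equal gains, equidistant
#' medoids) always resolve to the lowest index.
#'
#' @param d a symmetric dissimilarity matrix (e.g. from [hamming_matrix()]).
#' @param k number of clusters, `1 <= k <= n`.
#' @param max_swaps safety cap on SWAP iterations (each strictly decreases the
#'   cost, so termination is guaranteed anyway).
#' @return An object of class `cluster_solution`: `k`, `medoids` (row indices,
#'   ascending), `medoid_ids`, `cluster` (assignment 1..k per subject),
#'   `total_cost` (sum of distances to assigned medoids), and `asw` (mean
#'   silhouette width, `NA` when `k == 1`).
#' @export
pam_cluster <- function(d, k, max_swaps = 10000L) {
  d <- unclass(d)
  n <- nrow(d)
  if (is.null(n) || n != ncol(d)) stop("d must be a square matrix")
  k <- as.integer(k)
  if (k < 1L || k > n) stop("k must be between 1 and n = ", n)

  # BUILD
  medoids <- which.min(colSums(d))
  dn <- d[, medoids]
  while (length(medoids) < k) {
    cand <- setdiff(seq_len(n), medoids)
    gains <- colSums(pmax(dn - d[, cand, drop = FALSE], 0))
    new <- cand[which.max(gains)]
    medoids <- c(medoids, new)
    dn <- pmin(dn, d[, new])
  }
  medoids <- sort(medoids)

  # SWAP: best-improvement exchanges while the cost strictly decreases
  swaps <- 0L
  repeat {
    near <- nearest_medoids(d, medoids)
    cost <- sum(near$dn)
    if (k == n || swaps >= max_swaps) break
    cand <- setdiff(seq_len(n), medoids)
    best_delta <- 0
    best_m <- NA_integer_; best_h <- NA_integer_
    for (mi in seq_along(medoids)) {
      inm <- near$label == mi
      new_cost <- colSums(pmin(d[inm, cand, drop = FALSE], near$ds[inm])) +
        colSums(pmin(d[!inm, cand, drop = FALSE], near$dn[!inm]))
      delta <- new_cost - cost
      j <- which.min(delta)
      if (delta[j] < best_delta - 1e-12) {
        best_delta <- delta[j]
        best_m <- mi; best_h <- cand[j]
      }
    }
    if (is.na(best_m)) break
    medoids <- sort(c(medoids[-best_m], best_h))
    swaps <- swaps + 1L
  }

  near <- nearest_medoids(d, medoids)
  cl <- near$label
  cl[medoids] <- seq_len(k)  # a medoid always belongs to its own cluster
  ids <- rownames(d)
  structure(
    list(k = k,
         medoids = medoids,
         medoid_ids = if (!is.null(ids)) ids[medoids] else as.character(medoids),
         cluster = cl,
         total_cost = sum(d[cbind(seq_len(n), medoids[cl])]),
         asw = if (k >= 2L) asw(d, cl) else NA_real_,
         n = n,
         swaps = swaps),
    class = "cluster_solution"
  )
}

# distance to nearest / second-nearest medoid and nearest-medoid label
# (ties to the lowest medoid index; medoids are kept sorted ascending)
nearest_medoids <- function(d, medoids) {
  dm <- d[, medoids, drop = FALSE]
  lab <- max.col(-dm, ties.method = "first")
  n <- nrow(dm)
  dn <- dm[cbind(seq_len(n), lab)]
  if (length(medoids) > 1L) {
    dm2 <- dm
    dm2[cbind(seq_len(n), lab)] <- Inf
    ds <- dm2[cbind(seq_len(n), max.col(-dm2, ties.method = "first"))]
  } else {
    ds <- rep(Inf, n)
  }
  list(label = lab, dn = dn, ds = ds)
}

#' @export
print.cluster_solution <- function(x, ...) {
  cat(sprintf("cluster_solution: k = %d, n = %d, total cost = %g, ASW = %s\n",
              x$k, x$n, x$total_cost,
              if (is.na(x$asw)) "NA" else formatC(x$asw, digits = 3, format = "f")))
  cat("medoids:", paste(x$medoid_ids, collapse = ", "), "\n")
  invisible(x)
}

#' Silhouette widths and average silhouette width
#'
#' For subject i with mean within-cluster dissimilarity `a(i)` (excluding
#' itself) and `b(i)` the smallest mean dissimilarity to any other cluster,
#' the silhouette width is `s(i) = (b(i) - a(i)) / max(a(i), b(i))`. Members
#' of singleton clusters get `s(i) = 0`, as do points with `a = b = 0`.
#' The average silhouette width (ASW) is the mean of `s(i)`; values near 1
#' indicate a strong clustering structure.
#'
#' @param d a symmetric dissimilarity matrix.
#' @param cluster cluster assignment vector (any label type), at least two
#'   distinct non-empty clusters.
#' @return `silhouette_width`: numeric vector of `s(i)` in `[-1, 1]`;
#'   `asw`: their mean.
#' @export
silhouette_width <- function(d, cluster) {
  d <- unclass(d)
  n <- nrow(d)
  if (length(cluster) != n) stop("cluster must have one label per subject")
  f <- factor(cluster)
  if (nlevels(f) < 2L) stop("silhouette needs at least two clusters")
  ind <- stats::model.matrix(~ f - 1)
  counts <- colSums(ind)
  sums <- d %*% ind                      # total distance of i to each cluster
  own <- as.integer(f)
  i <- seq_len(n)
  a <- sums[cbind(i, own)] / (counts[own] - 1)   # self excluded (d[i,i] = 0)
  means <- sweep(sums, 2L, counts, "/")
  means[cbind(i, own)] <- Inf
  b <- means[cbind(i, max.col(-means, ties.method = "first"))]
  s <- (b - a) / pmax(a, b)
  s[counts[own] == 1L] <- 0              # singleton clusters
  s[!is.finite(s)] <- 0                  # a = b = 0 (exact duplicates)
  unname(s)
}

#' @rdname silhouette_width
#' @export
asw <- function(d, cluster) mean(silhouette_width(d, cluster))

#' Choose the number of clusters by average silhouette width
#'
#' Runs [pam_cluster()] for every `k` in `k_min:k_max` and returns the
#' solution with the highest ASW (ties go to the smaller `k`), together with
#' the full ASW profile.
#'
#' @param d a symmetric dissimilarity matrix.
#' @param k_min,k_max inclusive range of cluster counts to try (default 2-10).
#' @param max_swaps passed to [pam_cluster()].
#' @return A list with `best` (a `cluster_solution`) and `profile` (data frame
#'   of `k` and `asw`).
#' @export
select_k <- function(d, k_min = 2L, k_max = 10L, max_swaps = 10000L) {
  k_min <- as.integer(k_min); k_max <- as.integer(k_max)
  if (k_min > k_max) stop("empty k range")
  if (k_min < 2L) stop("ASW selection needs k_min >= 2")
  if (k_max > nrow(d)) stop("k_max exceeds the number of subjects")
  ks <- seq.int(k_min, k_max)
  sols <- lapply(ks, function(k) pam_cluster(d, k, max_swaps = max_swaps))
  profile <- data.frame(k = ks, asw = vapply(sols, `[[`, numeric(1), "asw"))
  list(best = sols[[which.max(profile$asw)]], profile = profile)
}

#' Export a clustering solution
#'
#' @param solution a `cluster_solution`.
#' @param panel the clustered `sequence_panel` (for subject ids).
#' @param file CSV path for subject/cluster assignments.
#' @return The assignment data frame, invisibly when written.
#' @export
write_assignments <- function(solution, panel, file = NULL) {
  out <- data.frame(subject_id = panel$meta$subject_id,
                    cluster = solution$cluster,
                    stringsAsFactors = FALSE)
  if (is.null(file)) return(out)
  utils::write.csv(out, file, row.names = FALSE)
  invisible(out)
}
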