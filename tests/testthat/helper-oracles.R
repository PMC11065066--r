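# Independent oracles and small fixture builders. These deliberately use
# naive loops so they stay independent of the implementations they check.

# strip dimnames/class/attributes for value-only matrix comparison
plain <- function(m) {
  m <- unclass(m)
  attributes(m) <- list(dim = dim(m))
  m
}

# random Hamming matrix from a random panel (the input class PAM sees)
random_hamming <- function(n, L = 8L, K = 4L) plain(hamming_matrix(random_panel(n, L, K)))

# brute-force positional mismatch count, double loop
brute_hamming <- function(m) {
  n <- nrow(m)
  d <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n))
    d[i, j] <- sum(m[i, ] != m[j, ])
  d
}

# exhaustive k-medoids optimum: enumerate all medoid subsets
exhaustive_pam_cost <- function(d, k) {
  n <- nrow(d)
  best <- Inf
  best_set <- NULL
  sets <- utils::combn(n, k)
  for (c in seq_len(ncol(sets))) {
    cost <- sum(apply(d[, sets[, c], drop = FALSE], 1L, min))
    if (cost < best) {
      best <- cost
      best_set <- sets[, c]
    }
  }
  list(cost = best, medoids = best_set)
}

# straightforward silhouette per the textbook formula, all loops
naive_silhouette <- function(d, cl) {
  n <- nrow(d)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- which(cl == cl[i] & seq_len(n) != i)
    if (length(own) == 0L) { s[i] <- 0; next }
    a <- mean(d[i, own])
    b <- min(vapply(setdiff(unique(cl), cl[i]),
                    function(g) mean(d[i, cl == g]), numeric(1)))
    s[i] <- if (max(a, b) == 0) 0 else (b - a) / max(a, b)
  }
  s
}

# random state-sequence panel for property tests
random_panel <- function(n, L = 6L, K = 8L) {
  m <- matrix(sample.int(K, n * L, replace = TRUE), n, L)
  sequence_panel(m, subject_id = sprintf("r%03d", seq_len(n)), start_age = 16L)
}

# symmetric non-negative dissimilarity with zero diagonal (not necessarily
# metric; PAM and silhouette only need symmetry)
random_dissimilarity <- function(n) {
  d <- matrix(stats::runif(n * n, 0.1, 5), n, n)
  d <- (d + t(d)) / 2
  diag(d) <- 0
  d
}

# two well-separated blocks: within-block distance 1, between-block 10
two_block_matrix <- function(n1, n2) {
  n <- n1 + n2
  d <- matrix(10, n, n)
  d[seq_len(n1), seq_len(n1)] <- 1
  d[(n1 + 1):n, (n1 + 1):n] <- 1
  diag(d) <- 0
  d
}
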