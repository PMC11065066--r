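test_that("degenerate cluster counts behave as contracted", {
  set.seed(21)
  d <- random_dissimilarity(7)
  all_own <- pam_cluster(d, 7)
  expect_equal(all_own$total_cost, 0)
  expect_equal(sort(all_own$medoids), 1:7)
  one <- pam_cluster(d, 1)
  expect_equal(one$medoids, which.min(rowSums(d)))  # brute-force 1-medoid
  expect_equal(one$total_cost, min(rowSums(d)))
  expect_error(pam_cluster(d, 0), "between 1 and")
  expect_error(pam_cluster(d, 8), "between 1 and")
})

test_that("two well-separated blocks are recovered exactly at the exhaustive optimum", {
  d <- two_block_matrix(5, 7)
  sol <- pam_cluster(d, 2)
  expect_equal(sol$cluster[1:5], rep(sol$cluster[1], 5))
  expect_equal(sol$cluster[6:12], rep(sol$cluster[6], 7))
  expect_equal(sol$total_cost, exhaustive_pam_cost(d, 2)$cost)
})

test_that("PAM lands within 5% of the exhaustive optimum on clustered sequence data", {
  set.seed(27)
  for (rep in 1:6) {
    cfg <- synthetic_config(builtin_templates("female")[sample(8, 3)],
                            n_per_cluster = sample(3:4, 1), noise_rate = 0.1,
                            seed = 600 + rep)
    d <- plain(hamming_matrix(generate_panel(cfg)$panel))
    sol <- pam_cluster(d, 3)
    opt <- exhaustive_pam_cost(d, 3)$cost
    expect_gte(sol$total_cost, opt - 1e-9)
    expect_lte(sol$total_cost, 1.05 * opt)
  }
})

test_that("PAM solutions are locally optimal and internally consistent", {
  set.seed(22)
  for (rep in 1:8) {
    n <- sample(5:12, 1)
    k <- sample(2:3, 1)
    d <- random_hamming(n)
    sol <- pam_cluster(d, k)
    opt <- exhaustive_pam_cost(d, k)$cost
    expect_gte(sol$total_cost, opt - 1e-9)
    # no single (medoid, non-medoid) exchange can strictly reduce the cost
    cost_of <- function(m) sum(apply(d[, m, drop = FALSE], 1, min))
    for (mi in seq_len(k)) for (h in setdiff(seq_len(n), sol$medoids))
      expect_gte(cost_of(c(sol$medoids[-mi], h)), sol$total_cost)
    # total_cost is the sum of distances to assigned medoids
    expect_equal(sol$total_cost,
                 sum(d[cbind(seq_len(n), sol$medoids[sol$cluster])]))
    # every subject sits with its nearest medoid and medoids with themselves
    expect_equal(sol$cluster[sol$medoids], seq_len(k))
    dm <- d[, sol$medoids, drop = FALSE]
    expect_equal(dm[cbind(seq_len(n), sol$cluster)], apply(dm, 1, min))
  }
})

test_that("PAM agrees with an established k-medoids implementation on separated data", {
  skip_if_not_installed("cluster")
  # identical partition and cost on well-separated blocks (medoid identity can
  # legitimately differ: any within-block point is an equally good medoid)
  d <- two_block_matrix(4, 6)
  ours <- pam_cluster(d, 2)
  ref <- cluster::pam(stats::as.dist(d), 2)
  expect_equal(ours$total_cost, ref$objective[["swap"]] * nrow(d))
  if (requireNamespace("mclust", quietly = TRUE))
    expect_equal(mclust::adjustedRandIndex(ours$cluster, ref$clustering), 1)
  # near-identical cost on random sequence instances (tie-breaking aside)
  set.seed(26)
  for (rep in 1:6) {
    dh <- random_hamming(sample(8:14, 1))
    ours <- pam_cluster(dh, 3)
    ref <- cluster::pam(stats::as.dist(dh), 3)
    expect_lte(abs(ours$total_cost - ref$objective[["swap"]] * nrow(dh)),
               0.05 * ours$total_cost)
  }
})

test_that("silhouette follows the (b - a) / max(a, b) formula", {
  # two tight clusters: a = 0 limit gives s = 1
  d <- two_block_matrix(3, 3)
  d[d == 1] <- 0
  expect_equal(silhouette_width(d, c(1, 1, 1, 2, 2, 2)), rep(1, 6))
  # a point equidistant between its own and the other cluster: s = 0
  d2 <- matrix(c(0, 2, 2, 2,
                 2, 0, 2, 2,
                 2, 2, 0, 2,
                 2, 2, 2, 0), 4, 4)
  expect_equal(silhouette_width(d2, c(1, 1, 2, 2)), rep(0, 4))
  # hand-computed case with a(i) = 1, b(i) = 3 -> s = 2/3
  d3 <- matrix(c(0, 1, 3, 3,
                 1, 0, 3, 3,
                 3, 3, 0, 1,
                 3, 3, 1, 0), 4, 4)
  expect_equal(silhouette_width(d3, c(1, 1, 2, 2)), rep(2 / 3, 4))
  expect_error(silhouette_width(d3, rep(1, 4)), "two clusters")
})

test_that("silhouette matches independent reimplementations to 1e-12", {
  set.seed(23)
  for (rep in 1:10) {
    n <- sample(6:15, 1)
    d <- random_dissimilarity(n)
    cl <- sample(1:3, n, replace = TRUE)
    if (length(unique(cl)) < 2) next
    s <- silhouette_width(d, cl)
    expect_equal(s, naive_silhouette(d, cl), tolerance = 1e-12)
    if (requireNamespace("cluster", quietly = TRUE) && all(table(cl) > 1)) {
      ref <- cluster::silhouette(cl, dmatrix = d)[, "sil_width"]
      expect_equal(s, unname(ref), tolerance = 1e-12)
    }
  }
})

test_that("ASW is the mean silhouette and mixed labels score no better than 0", {
  d <- two_block_matrix(3, 3); d[d == 1] <- 0
  expect_equal(asw(d, c(1, 1, 1, 2, 2, 2)), 1)
  # perfectly mixed labels across two symmetric tight clouds
  expect_lte(asw(two_block_matrix(2, 2), c(1, 2, 1, 2)), 0)
  set.seed(25)
  dr <- random_dissimilarity(8)
  cl <- rep(1:2, 4)
  expect_equal(asw(dr, cl), mean(silhouette_width(dr, cl)))
  expect_true(abs(asw(dr, cl)) <= 1)
})

test_that("ASW-driven selection finds planted cluster counts and breaks ties low", {
  # two exact point clouds, far apart: k = 2 with ASW = 1, searched over 2..4
  d <- two_block_matrix(4, 4)
  d[d == 1] <- 0
  sel <- select_k(d, 2, 4)
  expect_equal(sel$best$k, 2L)
  expect_equal(sel$best$asw, 1)
  expect_equal(sel$profile$k, 2:4)
  # synthetic two-template panel
  cfg <- synthetic_config(builtin_templates("male"), n_per_cluster = 25,
                          noise_rate = 0.03, gender = "male", seed = 5)
  gp <- generate_panel(cfg)
  sel2 <- select_k(hamming_matrix(gp$panel), 2, 6)
  expect_equal(sel2$best$k, 2L)
  expect_error(select_k(d, 3, 2), "empty k range")
})

test_that("cluster labels are permutation-equivariant (ARI = 1)", {
  skip_if_not_installed("mclust")
  set.seed(24)
  cfg <- synthetic_config(builtin_templates("female")[1:4], n_per_cluster = 15,
                          noise_rate = 0.05, seed = 6)
  gp <- generate_panel(cfg)
  d <- unclass(hamming_matrix(gp$panel))
  n <- nrow(d)
  perm <- sample(n)
  a <- pam_cluster(d, 4)$cluster
  b <- pam_cluster(d[perm, perm], 4)$cluster
  expect_equal(mclust::adjustedRandIndex(a[perm], b), 1)
})
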