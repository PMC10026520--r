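test_that("sort_for_map groups by IS in descending binary-index order", {
  bm <- rbind(c(1, 0), c(0, 1), c(1, 0), c(0, 1), c(1, 1))
  colnames(bm) <- c("A", "B")
  cat_ <- group_into_index_sets(bm)
  cat_$status <- rep("abundant", length(cat_$index))
  map <- sort_for_map(cat_, bm)
  expect_equal(attr(map, "block_index"), c("1_1", "1_0", "0_1"))
  expect_equal(attr(map, "block_sizes"), c(1L, 2L, 2L))
  expect_equal(map[1, ], c(A = 1, B = 1))
  # rows of one IS are contiguous
  expect_equal(map[2:3, 1], c(1, 1))
})

test_that("shannon entropy: constant map 0, uniform map ln(windows)", {
  const <- matrix(1L, 50, 4)
  se <- shannon_entropy(const, N = 5, M_values = c(2, 4))
  expect_equal(se$SE, c(0, 0))

  # all 2^(N*M) patterns once: N=1, M=3 over the 8 distinct rows
  rows <- as.matrix(expand.grid(0:1, 0:1, 0:1))
  se_u <- shannon_entropy(rows, N = 1, M_values = 3)
  expect_equal(se_u$SE, log(8))

  expect_error(shannon_entropy(const, N = 100), "exceeds")
})

test_that("shannon entropy matches a dictionary recount to 1e-12", {
  set.seed(14)
  map <- matrix(rbinom(200 * 6, 1, 0.5), 200, 6)
  for (M in c(3L, 5L)) {
    se <- shannon_entropy(map, N = 5, M_values = M)
    expect_lt(abs(se$SE - oracle_entropy(map, 5L, M)), 1e-12)
  }
  # offset windows
  se_off <- shannon_entropy(map, N = 5, M_values = 3, col_offset = 2L)
  expect_lt(abs(se_off$SE - oracle_entropy(map, 5L, 3L, col_offset = 2L)),
            1e-12)
  # invariance to flipping all bits (pattern relabeling bijection)
  se_flip <- shannon_entropy(1L - map, N = 5, M_values = 5)
  expect_equal(se_flip$SE, shannon_entropy(map, N = 5, M_values = 5)$SE)
})

test_that("ARI: identical 1, permuted-label 1, independent ~0, symmetric", {
  lab <- rep(1:5, each = 20)
  expect_equal(adjusted_rand_index(lab, lab), 1)
  relabeled <- c(3, 5, 1, 2, 4)[lab]
  expect_equal(adjusted_rand_index(lab, relabeled), 1)

  set.seed(66)
  a <- sample.int(10, 1000, replace = TRUE)
  b <- sample.int(10, 1000, replace = TRUE)
  expect_lt(abs(adjusted_rand_index(a, b)), 0.05)
  expect_equal(adjusted_rand_index(a, b), adjusted_rand_index(b, a))
  # both trivial single-cluster partitions: defined as 1
  expect_equal(adjusted_rand_index(rep(1, 5), rep(2, 5)), 1)
})

test_that("noise-injection protocol returns all pairwise ARIs", {
  set.seed(10)
  data <- rbind(matrix(rnorm(200, sd = 0.1), 100, 2) + 3,
                matrix(rnorm(200, sd = 0.1), 100, 2) - 3)
  labeler <- function(d, s) as.integer(d[, 1] > 0)
  ari <- ari_reproducibility(labeler, data, n_reps = 5, seed = 2)
  expect_length(ari, choose(5, 2))
  expect_equal(as.numeric(ari), rep(1, 10))  # well-separated: stable labels
})

test_that("rare_cluster_frequency counts recovery per round", {
  set.seed(30)
  means <- rbind(c(10, 0, 0), c(0, 10, 0), c(0, 0, 10))
  data <- means[rep(1:3, each = 100), ] +
    matrix(rnorm(900, sd = 0.01), 300, 3)
  counts <- rare_cluster_frequency(means, data, K = 3, rounds = 10, seed = 4)
  expect_equal(counts, rep(10L, 3))  # exact recovery every round

  # an orthogonal mean no data row points at scores zero
  means4 <- rbind(means, c(-10, -10, -10))
  counts4 <- rare_cluster_frequency(means4, data, K = 3, rounds = 10,
                                    seed = 4)
  expect_equal(counts4[4], 0L)
  # zero-vector centroid convention: distance 1
  expect_equal(ccrecluster:::cosine_distance(c(0, 0), c(1, 1)), 1)
})
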