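#' Row-order the binary matrix for the 2D cluster map
#'
#' Rows are grouped by final Index-Set; ISs are ordered by interpreting the
#' index string as a binary number over the linearized-tree bit order
#' (descending), so lineage-adjacent patterns sit together. The null IS (if
#' present) comes last.
#'
#' @param catalog Final `is_catalog`.
#' @param bm Binary matrix whose rows the catalog members refer to.
#' @return The re-ordered 0/1 matrix with attributes `block_sizes` (per-IS
#'   row counts) and `block_index` (IS index per block).
#' @export
sort_for_map <- function(catalog, bm) {
  stopifnot(inherits(catalog, "is_catalog"))
  real <- which(catalog$status != "null")
  ord <- real[order(index_binary_value(catalog$index[real]),
                    decreasing = TRUE)]
  ord <- c(ord, which(catalog$status == "null"))
  ord <- ord[catalog$size[ord] > 0L]
  rows <- unlist(catalog$members[ord])
  out <- bm[rows, , drop = FALSE]
  attr(out, "block_sizes") <- catalog$size[ord]
  attr(out, "block_index") <- catalog$index[ord]
  out
}

#' Sliding-window Shannon entropy of a binary cluster map
#'
#' A window of N adjacent rows by M cell-type columns slides down the sorted
#' map one row at a time; each distinct N-by-M pattern's probability `P_i`
#' (occurrences over total windows) enters `SE = -sum_i P_i ln(P_i)` (natural
#' log). Lower entropy means a more ordered, more interpretable map. Window
#' columns are the contiguous slice of `M` columns starting after
#' `col_offset`.
#'
#' @param map 0/1 matrix, typically from [sort_for_map()].
#' @param N Window height in rows.
#' @param M_values Window widths (numbers of cell types) to evaluate.
#' @param col_offset 0-based offset of the first window column (default 0).
#' @return data.frame with columns `N`, `M`, `n_windows`, `n_patterns`, `SE`.
#' @export
shannon_entropy <- function(map, N, M_values = ncol(map), col_offset = 0L) {
  stopifnot(is.matrix(map))
  if (N > nrow(map)) {
    stop("window height N = ", N, " exceeds map rows (", nrow(map), ")",
         call. = FALSE)
  }
  out <- lapply(M_values, function(M) {
    if (col_offset + M > ncol(map)) {
      stop("col_offset + M exceeds map columns", call. = FALSE)
    }
    cols <- (col_offset + 1L):(col_offset + M)
    row_str <- apply(map[, cols, drop = FALSE], 1L, paste, collapse = "")
    n_win <- nrow(map) - N + 1L
    win <- vapply(seq_len(n_win), function(t) {
      paste(row_str[t:(t + N - 1L)], collapse = "|")
    }, character(1))
    p <- as.numeric(table(win)) / n_win
    data.frame(N = N, M = M, n_windows = n_win, n_patterns = length(p),
               SE = -sum(p * log(p)))
  })
  do.call(rbind, out)
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same items. 1
#' means identical partitions (up to label permutation), about 0 means
#' independent labelings. When both partitions are trivial (a single cluster
#' each) the denominator vanishes; the ARI is then defined as 1 (the
#' partitions are equal).
#'
#' @param a,b Label vectors of equal length.
#' @return The ARI.
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) > 0L)
  tab <- table(a, b)
  n <- length(a)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  denom <- (sum_a + sum_b) / 2 - expected
  if (denom == 0) return(1)
  (sum_ij - expected) / denom
}

#' Noise-injection reproducibility protocol
#'
#' Re-clusters the same signal matrix `n_reps` times, each time after adding
#' fresh uniform noise in `[noise_low, noise_high]` to every entry, and
#' returns all pairwise adjusted Rand indices between the resulting
#' labelings.
#'
#' @param cluster_fn Function `(data, seed) -> integer labels`; must be
#'   deterministic given its arguments.
#' @param data Signal matrix.
#' @param n_reps Number of noisy re-clusterings (default 5).
#' @param noise_low,noise_high Uniform noise bounds (default -0.1, 0.1).
#' @param seed Base seed; rep `r` draws noise under `seed + r` and passes
#'   `seed + r` to `cluster_fn`.
#' @return Numeric vector of the `choose(n_reps, 2)` pairwise ARIs, with the
#'   labelings in attribute `labels`.
#' @export
ari_reproducibility <- function(cluster_fn, data, n_reps = 5L,
                                noise_low = -0.1, noise_high = 0.1,
                                seed = 1L) {
  labels <- vector("list", n_reps)
  for (r in seq_len(n_reps)) {
    set.seed(seed + r)
    noisy <- data + matrix(stats::runif(length(data), noise_low, noise_high),
                           nrow = nrow(data))
    labels[[r]] <- cluster_fn(noisy, seed + r)
  }
  pairs <- utils::combn(n_reps, 2L)
  ari <- apply(pairs, 2L, function(p) {
    adjusted_rand_index(labels[[p[1L]]], labels[[p[2L]]])
  })
  attr(ari, "labels") <- labels
  ari
}

cosine_distance <- function(x, y) {
  nx <- sqrt(sum(x^2)); ny <- sqrt(sum(y^2))
  if (nx == 0 || ny == 0) return(1)
  1 - sum(x * y) / (nx * ny)
}

#' How often K-means recovers each Meta-IS pattern
#'
#' Runs `rounds` K-means clusterings of the signal matrix with different
#' seeds. In each round every K-means centroid is matched to its
#' cosine-nearest Meta-IS mean vector; a Meta-IS whose mean is nearest to at
#' least one centroid scores one count for that round. Rare but real
#' patterns score well below `rounds` while dominant patterns score close to
#' it.
#'
#' @param meta_means Matrix of Meta-IS mean-signal vectors.
#' @param data Signal matrix to cluster.
#' @param K Number of K-means clusters (paper protocol: the Meta-IS count).
#' @param rounds Number of K-means rounds (default 100).
#' @param seed Base seed; round `r` uses `seed + r`.
#' @param nstart Random restarts per K-means round (default 10, the common
#'   K-means default; the best run by within-cluster sum of squares wins).
#' @return Integer vector, one count in `[0, rounds]` per Meta-IS.
#' @export
rare_cluster_frequency <- function(meta_means, data, K = nrow(meta_means),
                                   rounds = 100L, seed = 1L, nstart = 10L) {
  stopifnot(is.matrix(meta_means), nrow(meta_means) > 0L)
  counts <- integer(nrow(meta_means))
  for (r in seq_len(rounds)) {
    set.seed(seed + r)
    km <- stats::kmeans(data, centers = K, nstart = nstart, iter.max = 50L)
    nearest <- apply(km$centers, 1L, function(ctr) {
      which.min(apply(meta_means, 1L, cosine_distance, y = ctr))
    })
    counts[unique(nearest)] <- counts[unique(nearest)] + 1L
  }
  counts
}
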