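naive_complete_linkage_heights <- function(X) {
  # O(n^3) agglomeration oracle: merge the closest pair under complete
  # linkage, record merge heights
  clusters <- as.list(seq_len(nrow(X)))
  D <- as.matrix(dist(X))
  heights <- numeric(0)
  while (length(clusters) > 1L) {
    best <- c(NA, NA); bd <- Inf
    for (i in seq_along(clusters)) for (j in seq_len(i - 1L)) {
      d <- max(D[clusters[[i]], clusters[[j]]])
      if (d < bd) { bd <- d; best <- c(j, i) }
    }
    heights <- c(heights, bd)
    clusters[[best[1L]]] <- c(clusters[[best[1L]]], clusters[[best[2L]]])
    clusters[[best[2L]]] <- NULL
  }
  heights
}

test_that("linkage merges identical vectors at height 0, outliers last", {
  X <- rbind(c(0, 0), c(0, 0), c(10, 10))
  hc <- build_linkage(X)
  expect_equal(hc$height[1L], 0)
  expect_equal(sort(hc$merge[2L, ]), c(-3, 1))  # outlier joins last
})

test_that("linkage heights match a brute-force agglomeration oracle", {
  set.seed(19)
  X <- matrix(rnorm(20 * 4), 20, 4)
  hc <- build_linkage(X)
  expect_equal(sort(hc$height), sort(naive_complete_linkage_heights(X)),
               tolerance = 1e-12)
})

test_that("AIC selects the planted number of archetypes", {
  # infinite-cCRE limit: ISs sharing an archetype have identical mean
  # vectors, so the residual sum of squares vanishes exactly at the true K
  set.seed(57)
  centers <- rbind(c(0, 0, 0, 0), c(20, 0, 0, 0), c(0, 20, 0, 0))
  X <- centers[rep(1:3, each = 10L), ]
  hc <- build_linkage(X)
  sel <- select_k_by_aic(hc, X, k_range = 1:10)
  expect_equal(sel$K, 3L)
  # single IS
  expect_equal(select_k_by_aic(NULL, X[1, , drop = FALSE])$K, 1L)
  # chosen K stable under input order permutation
  perm <- sample.int(30)
  sel2 <- select_k_by_aic(build_linkage(X[perm, ]), X[perm, ], k_range = 1:10)
  expect_equal(sel2$K, 3L)
  # AIC curve is finite when the fit is imperfect
  Xn <- X + matrix(rnorm(120, sd = 0.5), 30, 4)
  seln <- select_k_by_aic(build_linkage(Xn), Xn, k_range = 2:8)
  expect_true(all(is.finite(seln$aic$aic)))
})

test_that("assign_meta cuts and renumbers along the dendrogram", {
  set.seed(3)
  ms <- matrix(rnorm(8 * 3), 8, 3)
  cat_ <- structure(list(index = paste0("i", 1:8),
                         members = as.list(1:8), size = rep(1L, 8),
                         mean_signal = ms, status = rep("abundant", 8),
                         cells = c("A", "B", "C"), dropped = integer(0)),
                    class = "is_catalog")
  hc <- build_linkage(ms)
  # K = n: each IS its own Meta-IS; K = 1: everything together
  m_n <- assign_meta(hc, 8L, cat_)
  expect_equal(sort(lengths(m_n$member_is)), rep(1L, 8))
  m_1 <- assign_meta(hc, 1L, cat_)
  expect_equal(m_1$K, 1L)
  expect_equal(sum(m_1$size), 8)
  # meta ids follow leaf order
  m_3 <- assign_meta(hc, 3L, cat_)
  ids_along_leaves <- m_3$meta_id[hc$order]
  expect_equal(unique(ids_along_leaves), sort(unique(ids_along_leaves)))
  # partition of ISs
  expect_setequal(unlist(m_3$member_is), 1:8)
})

test_that("meta merge is size-independent and archetype-pure on a fixture", {
  set.seed(91)
  arch <- rbind(c(10, 10, 0, 0), c(0, 0, 10, 10), c(10, 0, 10, 0),
                c(5, 5, 5, 5), c(0, 10, 0, 10))
  which_arch <- rep(1:5, each = 8L)
  ms <- arch[which_arch, ]
  sizes <- sample.int(500L, 40L)
  cat_ <- structure(list(index = paste0("i", 1:40),
                         members = as.list(1:40), size = sizes,
                         mean_signal = ms, status = rep("abundant", 40),
                         cells = letters[1:4], dropped = integer(0)),
                    class = "is_catalog")
  meta <- merge_into_meta(cat_, k_range = 2:10)
  expect_equal(meta$K, 5L)
  # each Meta-IS pure in archetype
  for (g in meta$member_is) {
    expect_length(unique(which_arch[g]), 1L)
  }
  # multiplying one IS's size 10x changes nothing (means drive the merge)
  cat10 <- cat_
  cat10$size[7L] <- cat10$size[7L] * 10L
  meta10 <- merge_into_meta(cat10, k_range = 2:10)
  expect_equal(meta10$meta_id, meta$meta_id)
})
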