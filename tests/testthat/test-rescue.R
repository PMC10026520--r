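make_catalog <- function(members, status, cells) {
  structure(list(index = paste0("is", seq_along(members)),
                 members = members, size = lengths(members),
                 mean_signal = NULL, status = status, cells = cells,
                 dropped = integer(0)),
            class = "is_catalog")
}

test_that("priors normalize and degenerate classes get a ridge identity", {
  X <- rbind(matrix(c(1, 2), 10, 2, byrow = TRUE),
             matrix(c(5, 6), 10, 2, byrow = TRUE))
  cat_ <- make_catalog(list(1:10, 11:20), c("abundant", "abundant"),
                       c("A", "B"))
  m <- fit_qda(X, cat_)
  expect_equal(vapply(m$classes, `[[`, numeric(1), "prior"), c(0.5, 0.5))
  # members identical within class: covariance is the ridge identity only
  S <- t(m$classes[[1]]$chol) %*% m$classes[[1]]$chol
  expect_equal(S, m$classes[[1]]$ridge_used * diag(2), tolerance = 1e-12)
})

test_that("estimated means are within 3 standard errors on Gaussian classes", {
  set.seed(31)
  d <- 3L
  mu1 <- c(0, 0, 0); mu2 <- c(4, -2, 1)
  X <- rbind(matrix(rnorm(2000 * d), ncol = d) + rep(mu1, each = 2000),
             matrix(rnorm(2000 * d, sd = 2), ncol = d) + rep(mu2, each = 2000))
  cat_ <- make_catalog(list(1:2000, 2001:4000), rep("abundant", 2),
                       c("A", "B", "C"))
  m <- fit_qda(X, cat_)
  expect_true(all(abs(m$classes[[1]]$mu - mu1) < 3 * 1 / sqrt(2000)))
  expect_true(all(abs(m$classes[[2]]$mu - mu2) < 3 * 2 / sqrt(2000)))
})

test_that("discriminant scores match the direct MVN oracle up to a constant", {
  set.seed(17)
  d <- 4L
  mus <- list(rnorm(d), rnorm(d, 3), rnorm(d, -2))
  Xs <- lapply(mus, function(mu) {
    matrix(rnorm(60 * d, sd = c(1, 0.5, 2, 1)), ncol = d) + rep(mu, each = 60)
  })
  X <- do.call(rbind, Xs)
  cat_ <- make_catalog(list(1:60, 61:120, 121:180), rep("abundant", 3),
                       letters[1:4])
  m <- fit_qda(X, cat_, ridge = 1e-9)
  probe <- X[c(1, 75, 150), ]
  scores <- qda_scores(m, probe)
  for (i in seq_len(nrow(probe))) {
    oracle <- vapply(seq_along(m$classes), function(j) {
      Xj <- X[cat_$members[[j]], ]
      S <- cov(Xj)
      S <- S + 1e-9 * (sum(diag(S)) / d) * diag(d)
      as.numeric(mvn_logpdf(probe[i, ], colMeans(Xj), S)) +
        log(m$classes[[j]]$prior)
    }, numeric(1))
    # equality up to the shared -(d/2) log 2 pi constant
    diffs <- scores[i, ] - oracle
    expect_lt(max(diffs) - min(diffs), 1e-9)
    expect_equal(diffs[1], 0.5 * d * log(2 * pi), tolerance = 1e-9,
                 ignore_attr = TRUE)
  }
})

test_that("posteriors sum to one and the 0.5 boundary is assigned", {
  set.seed(23)
  X <- rbind(matrix(rnorm(100, sd = 0.3), 50, 2) + 5,
             matrix(rnorm(100, sd = 0.3), 50, 2) - 5)
  cat_ <- make_catalog(list(1:50, 51:100), rep("abundant", 2), c("A", "B"))
  m <- fit_qda(X, cat_)
  post <- ccrecluster:::softmax_rows(qda_scores(m, X))
  expect_equal(rowSums(post), rep(1, 100))

  # a probe at a class mean is assigned to that class with high posterior
  r <- qda_rescue(m, matrix(m$classes[[1]]$mu, 1))
  expect_equal(r$assigned, 1L)
  expect_gt(r$max_posterior, 0.5)

  # equidistant probe between symmetric classes: posterior 0.5 -> assigned
  mid <- (m$classes[[1]]$mu + m$classes[[2]]$mu) / 2
  r2 <- qda_rescue(m, matrix(mid, 1))
  if (abs(r2$max_posterior - 0.5) < 1e-6) {
    expect_false(is.na(r2$assigned))
  }
  # strictly below the cutoff goes to null
  r3 <- qda_rescue(m, matrix(mid, 1), null_posterior_cutoff = 0.9)
  expect_true(is.na(r3$assigned))

  expect_error(qda_scores(m, matrix(0, 1, 5)), "dimension")
})

test_that("finalize conserves cCREs and never moves abundant members", {
  fx <- small_fixture(seed = 29L)
  keep <- rowSums(fx$observed) > 0L
  bm <- fx$observed[keep, ]
  sig <- fx$signal[keep, ]
  cat_ <- filter_index_sets(group_into_index_sets(bm, signal = sig))
  m <- fit_qda(sig, cat_)
  ff <- filtered_features(cat_, sig)
  res <- qda_rescue(m, ff)
  final <- finalize_index_sets(cat_, m, res, signal = sig)

  expect_equal(sum(final$size), sum(cat_$size))
  expect_equal(final$status[length(final$status)], "null")
  # abundant members before are still in the same IS after
  for (j in seq_along(m$class_is)) {
    expect_true(all(cat_$members[[m$class_is[j]]] %in% final$members[[j]]))
  }
  # rescued cCREs carry the abundant IS's index in the assignment table
  tab <- attr(final, "rescue")
  expect_true(all(tab$final_index %in% c(final$index)))

  # zero filtered cCREs: catalog unchanged plus an empty null IS
  cat2 <- cat_
  cat2$status[cat2$status == "filtered"] <- "abundant"
  m2 <- fit_qda(sig, cat2)
  final2 <- finalize_index_sets(
    cat2, m2, qda_rescue(m2, filtered_features(cat2, sig)), signal = sig)
  expect_equal(final2$size[length(final2$size)], 0L)
  expect_equal(sum(final2$size), sum(cat2$size))
})
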