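test_that("identical sizes fall back to Poisson with a warning", {
  expect_warning(bg <- fit_nb_background(rep(3, 50)), "Poisson")
  expect_equal(bg$model, "poisson")
  expect_equal(bg$mu, 3)
})

test_that("top-fraction exclusion removes only the large outliers", {
  sizes <- c(rep(1, 95), rep(1000, 5))
  expect_warning(bg <- fit_nb_background(sizes, 0.05), "Poisson")
  expect_equal(bg$mu, 1)          # the fit saw only the 1s
  expect_equal(bg$n_fit, 95L)
  # a clean top fraction is excluded entirely...
  sizes2 <- c(rep(2, 90), rep(7, 10))
  bg2 <- suppressWarnings(fit_nb_background(sizes2, 0.10))
  expect_equal(bg2$n_fit, 90L)
  # ...but sizes tied with the boundary value stay in the fit
  sizes3 <- c(rep(2, 90), rep(7, 15))
  bg3 <- suppressWarnings(fit_nb_background(sizes3, 0.10))
  expect_equal(bg3$n_fit, 105L)
})

test_that("method-of-moments recovers NB location on simulated sizes", {
  set.seed(7)
  sizes <- rnbinom(2000L, size = 2, prob = 0.1)
  bg <- fit_nb_background(sizes, 0.05)
  expect_equal(bg$model, "nb")
  # compare against moments of the same truncated sample (the estimator's
  # own target), within 10%
  boundary <- quantile(sizes, 0.95, type = 1L)
  kept <- sizes[sizes <= boundary]
  expect_lt(abs(bg$mu - mean(kept)) / mean(kept), 0.10)
})

test_that("NB tail p-values match brute-force pmf summation to 1e-10", {
  bg <- structure(list(model = "nb", mu = 12.5, size = 1.7, prob = NA),
                  class = "nb_background")
  for (q in c(1L, 5L, 80L, 1000L, 10000L)) {
    brute <- 1 - sum(dnbinom(0:(q - 1L), size = 1.7, mu = 12.5))
    expect_lt(abs(nb_tail_p(bg, q) - brute), 1e-10)
  }
  bgp <- structure(list(model = "poisson", mu = 4), class = "nb_background")
  brute <- 1 - sum(dpois(0:9, 4))
  expect_lt(abs(nb_tail_p(bgp, 10L) - brute), 1e-10)
})

test_that("abundance threshold is monotone and respects overrides", {
  set.seed(42)
  sizes <- c(rnbinom(300L, size = 1, mu = 4) + 1L, 500L, 800L, 900L)
  bg <- fit_nb_background(sizes)
  thr <- abundance_threshold(bg, sizes, fdr_alpha = 0.01)
  ab <- thr$status == "abundant"
  # monotonicity: every IS at least as large as an abundant one is abundant
  expect_true(all(sizes[!ab] < min(sizes[ab])))
  expect_true(all(sizes[ab] >= thr$threshold_size))

  # stricter alpha never enlarges the abundant set
  thr2 <- abundance_threshold(bg, sizes, fdr_alpha = 0.001)
  expect_true(all(which(thr2$status == "abundant") %in% which(ab)))

  # manual threshold: strictly greater than the given size
  thr3 <- abundance_threshold(bg, sizes, manual_threshold = 173L)
  expect_equal(thr3$status == "abundant", sizes > 173L)

  expect_error(abundance_threshold(bg, c(1L, 2L), fdr_alpha = 1e-12),
               "manual")
})

test_that("filter keeps exactly the planted ISs on the small fixture", {
  fx <- small_fixture(seed = 13L)
  bm <- fx$observed[rowSums(fx$observed) > 0L, ]
  cat_ <- filter_index_sets(group_into_index_sets(bm))
  planted <- unique(fx$truth$planted_index[
    fx$truth$role %in% names(fx$config$patterns)])
  expect_setequal(cat_$index[cat_$status == "abundant"], planted)

  # robustness of the abundant set across the documented alpha range
  for (alpha in c(0.001, 0.2)) {
    cat_a <- filter_index_sets(group_into_index_sets(bm), fdr_alpha = alpha)
    expect_setequal(cat_a$index[cat_a$status == "abundant"], planted)
  }
})
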