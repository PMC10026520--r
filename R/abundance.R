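#' Fit a negative-binomial background to Index-Set sizes
#'
#' The most abundant ISs (top `exclusion_fraction` by size, default 5%) are
#' excluded before fitting to avoid bias from the planted/abundant outliers;
#' sizes tied with the boundary value are kept in the fit. Parameters come
#' from method-of-moments (`r = m^2/(v - m)`, `p = m/v`). When the sample
#' variance does not exceed the mean the model degenerates and a Poisson
#' background with the same mean is used instead.
#'
#' @param sizes Integer vector of IS sizes.
#' @param exclusion_fraction Top quantile of sizes excluded from the fit
#'   (0 < f < 0.5).
#' @return An `nb_background`: list with `model` ("nb" or "poisson"), `mu`,
#'   and for NB `size` (r) and `prob` (p), plus the fitting subset summary.
#' @export
fit_nb_background <- function(sizes, exclusion_fraction = 0.05) {
  stopifnot(is.numeric(sizes), length(sizes) > 0L)
  if (exclusion_fraction <= 0 || exclusion_fraction >= 0.5) {
    stop("exclusion_fraction must be in (0, 0.5)", call. = FALSE)
  }
  boundary <- stats::quantile(sizes, 1 - exclusion_fraction, type = 1L,
                              names = FALSE)
  fit_sizes <- sizes[sizes <= boundary]
  if (length(fit_sizes) < 5L) {
    stop("need at least 5 IS sizes after exclusion to fit a background",
         call. = FALSE)
  }
  m <- mean(fit_sizes)
  v <- stats::var(fit_sizes)
  if (!is.finite(v) || v <= m) {
    if (v == 0) {
      warning("all IS sizes identical after exclusion; ",
              "falling back to a Poisson background", call. = FALSE)
    }
    bg <- list(model = "poisson", mu = m, size = NA_real_, prob = NA_real_,
               n_fit = length(fit_sizes), boundary = boundary,
               exclusion_fraction = exclusion_fraction)
  } else {
    r <- m^2 / (v - m)
    p <- m / v
    bg <- list(model = "nb", mu = m, size = r, prob = p,
               n_fit = length(fit_sizes), boundary = boundary,
               exclusion_fraction = exclusion_fraction)
  }
  structure(bg, class = "nb_background")
}

#' @export
print.nb_background <- function(x, ...) {
  if (x$model == "nb") {
    cat(sprintf("nb_background: NB(mu = %.3f, r = %.3f) fit on %d sizes\n",
                x$mu, x$size, x$n_fit))
  } else {
    cat(sprintf("nb_background: Poisson(%.3f) fallback fit on %d sizes\n",
                x$mu, x$n_fit))
  }
  invisible(x)
}

#' Upper-tail probability P(X >= q) under the fitted background
#'
#' @param bg An `nb_background`.
#' @param q Vector of sizes.
#' @return P(X >= q) for each entry.
#' @export
nb_tail_p <- function(bg, q) {
  stopifnot(inherits(bg, "nb_background"))
  if (bg$model == "nb") {
    stats::pnbinom(q - 1, size = bg$size, mu = bg$mu, lower.tail = FALSE)
  } else {
    stats::ppois(q - 1, lambda = bg$mu, lower.tail = FALSE)
  }
}

#' Abundance threshold from FDR-adjusted tail p-values
#'
#' Computes the upper-tail p-value of every IS size under the background,
#' adjusts across all ISs by Benjamini-Hochberg, and sets the abundance
#' threshold to the smallest size whose adjusted p-value is below
#' `fdr_alpha`. An IS is abundant iff its size is at least `threshold_size`
#' (equivalently, strictly greater than `threshold_size - 1`). A
#' `manual_threshold` overrides the model: abundant iff size is strictly
#' greater than the manual value.
#'
#' @param bg An `nb_background` (ignored when `manual_threshold` is given).
#' @param sizes IS sizes, in catalog order.
#' @param fdr_alpha Adjusted-p cutoff (default 0.01).
#' @param manual_threshold Optional user threshold overriding the model.
#' @return List with `threshold_size`, `status` (character
#'   "abundant"/"filtered" per IS), `p_value`, `p_adj`, `fdr_alpha`,
#'   `manual_threshold`.
#' @export
abundance_threshold <- function(bg, sizes, fdr_alpha = 0.01,
                                manual_threshold = NULL) {
  stopifnot(length(sizes) > 0L)
  if (!is.null(manual_threshold)) {
    abundant <- sizes > manual_threshold
    if (!any(abundant)) {
      stop("no IS exceeds the manual threshold ", manual_threshold,
           call. = FALSE)
    }
    return(list(threshold_size = manual_threshold + 1,
                status = ifelse(abundant, "abundant", "filtered"),
                p_value = rep(NA_real_, length(sizes)),
                p_adj = rep(NA_real_, length(sizes)),
                fdr_alpha = fdr_alpha, manual_threshold = manual_threshold))
  }
  if (fdr_alpha <= 0 || fdr_alpha >= 1) {
    stop("fdr_alpha must be in (0, 1)", call. = FALSE)
  }
  p <- nb_tail_p(bg, sizes)
  padj <- stats::p.adjust(p, method = "BH")
  pass <- padj < fdr_alpha
  if (!any(pass)) {
    stop("no IS size reaches adjusted p < ", fdr_alpha,
         "; consider supplying a manual abundance threshold", call. = FALSE)
  }
  threshold_size <- min(sizes[pass])
  abundant <- sizes >= threshold_size
  list(threshold_size = threshold_size,
       status = ifelse(abundant, "abundant", "filtered"),
       p_value = p, p_adj = padj,
       fdr_alpha = fdr_alpha, manual_threshold = NULL)
}

#' Apply abundance filtering to an IS catalog
#'
#' @param catalog An `is_catalog` (status "initial").
#' @param exclusion_fraction,fdr_alpha,manual_threshold See
#'   [fit_nb_background()] and [abundance_threshold()].
#' @return The catalog with `status` set to "abundant"/"filtered" and
#'   attributes `background` and `threshold` recording the fit.
#' @export
filter_index_sets <- function(catalog, exclusion_fraction = 0.05,
                              fdr_alpha = 0.01, manual_threshold = NULL) {
  stopifnot(inherits(catalog, "is_catalog"))
  bg <- if (is.null(manual_threshold)) {
    fit_nb_background(catalog$size, exclusion_fraction)
  } else NULL
  thr <- abundance_threshold(bg, catalog$size, fdr_alpha, manual_threshold)
  catalog$status <- thr$status
  attr(catalog, "background") <- bg
  attr(catalog, "threshold") <- thr
  catalog
}
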