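#' Fit per-Index-Set multivariate Gaussians for QDA rescue
#'
#' Each abundant IS gets a mean vector, a (ridge-regularized) covariance and
#' a prior equal to its share of cCREs among abundant ISs. Classes with fewer
#' than `d + 2` members use the covariance pooled across all abundant classes
#' instead of their own. Regularization adds `ridge * (tr(Sigma)/d)` to the
#' diagonal (plain `ridge * I` when the covariance is all-zero, e.g. for a
#' class of identical vectors); if Cholesky still fails the ridge is
#' multiplied by 10 up to 3 times before erroring.
#'
#' @param features Numeric matrix, rows = cCREs, columns = cell types. The
#'   default pipeline feature is the normalized signal vector; a strictly
#'   binary feature matrix is also accepted (`feature_mode = "binary"`
#'   upstream).
#' @param catalog An `is_catalog` with status set by [filter_index_sets()].
#' @param ridge Relative ridge (default 1e-6).
#' @return A `qda_model`: per-class `mu`, upper-triangular Cholesky `chol`,
#'   `logdet`, `prior`, plus `classes` (IS indices into the catalog),
#'   `index` strings and `d`.
#' @export
fit_qda <- function(features, catalog, ridge = 1e-6) {
  stopifnot(inherits(catalog, "is_catalog"), is.matrix(features))
  abundant <- which(catalog$status == "abundant")
  if (length(abundant) == 0L) stop("no abundant IS to train on", call. = FALSE)
  d <- ncol(features)
  sizes <- catalog$size[abundant]
  priors <- sizes / sum(sizes)

  stats_by_class <- lapply(abundant, function(i) {
    X <- features[catalog$members[[i]], , drop = FALSE]
    mu <- colMeans(X)
    S <- if (nrow(X) > 1L) stats::cov(X) else matrix(0, d, d)
    list(mu = mu, S = S, n = nrow(X))
  })
  # pooled within-class covariance, for classes too small to estimate their own
  n_tot <- sum(vapply(stats_by_class, `[[`, numeric(1), "n"))
  k <- length(stats_by_class)
  pooled <- Reduce(`+`, lapply(stats_by_class, function(s) s$S * max(s$n - 1L, 0L)))
  pooled <- pooled / max(n_tot - k, 1L)

  regularize <- function(S) {
    scale <- sum(diag(S)) / d
    if (scale <= 0) scale <- 1
    r <- ridge
    for (attempt in 1:4) {
      Sr <- S + r * scale * diag(d)
      R <- tryCatch(chol(Sr), error = function(e) NULL)
      if (!is.null(R)) return(list(chol = R, ridge_used = r))
      if (attempt == 4L) break
      r <- r * 10
    }
    stop("covariance remains singular after ridge escalation", call. = FALSE)
  }

  classes <- lapply(seq_along(abundant), function(j) {
    s <- stats_by_class[[j]]
    S <- if (s$n < d + 2L) pooled else s$S
    reg <- regularize(S)
    list(mu = s$mu, chol = reg$chol,
         logdet = 2 * sum(log(diag(reg$chol))),
         prior = priors[j], n = s$n, pooled = s$n < d + 2L,
         ridge_used = reg$ridge_used)
  })
  structure(
    list(classes = classes, class_is = abundant,
         index = catalog$index[abundant], d = d, ridge = ridge),
    class = "qda_model"
  )
}

#' @export
print.qda_model <- function(x, ...) {
  cat("qda_model:", length(x$classes), "abundant Index-Set classes, d =",
      x$d, "\n")
  invisible(x)
}

#' Discriminant scores for feature vectors under a QDA model
#'
#' Computes, per cCRE and per abundant IS `i`, the unnormalized log-posterior
#' `-1/2 log|Sigma_i| - 1/2 (x - mu_i)' Sigma_i^{-1} (x - mu_i) + log P0_i`.
#' The shared `-(d/2) log 2*pi` constant is omitted; it cancels in the
#' softmax.
#'
#' @param model A `qda_model`.
#' @param features Matrix of feature rows to score.
#' @return Matrix, rows = cCREs, one column per abundant IS.
#' @export
qda_scores <- function(model, features) {
  stopifnot(inherits(model, "qda_model"))
  if (is.null(dim(features))) features <- matrix(features, nrow = 1L)
  if (ncol(features) != model$d) {
    stop("feature length ", ncol(features), " does not match model dimension ",
         model$d, call. = FALSE)
  }
  scores <- vapply(model$classes, function(cl) {
    centered <- t(features) - cl$mu
    z <- backsolve(cl$chol, centered, transpose = TRUE)
    quad <- colSums(z^2)
    -0.5 * cl$logdet - 0.5 * quad + log(cl$prior)
  }, numeric(nrow(features)))
  matrix(scores, nrow = nrow(features), ncol = length(model$classes),
         dimnames = list(NULL, model$index))
}

softmax_rows <- function(m) {
  mx <- apply(m, 1L, max)
  e <- exp(m - mx)
  e / rowSums(e)
}

#' Rescue filtered cCREs into abundant Index-Sets
#'
#' Posterior probabilities are the row-wise softmax of the discriminant
#' scores. A cCRE is assigned to the argmax IS when its maximum posterior is
#' at least `null_posterior_cutoff` (ties at exactly the cutoff are
#' assigned); otherwise it goes to the null class (`assigned = NA`).
#'
#' @param model A `qda_model`.
#' @param features Feature matrix of the cCREs to re-classify.
#' @param null_posterior_cutoff Posterior below which a cCRE is nulled
#'   (default 0.5).
#' @return data.frame with `assigned` (column index into the model's classes,
#'   NA for null), `assigned_index` (index string or NA) and `max_posterior`.
#' @export
qda_rescue <- function(model, features, null_posterior_cutoff = 0.5) {
  if (is.null(dim(features))) features <- matrix(features, nrow = 1L)
  if (nrow(features) == 0L) {
    return(data.frame(assigned = integer(0), assigned_index = character(0),
                      max_posterior = numeric(0)))
  }
  post <- softmax_rows(qda_scores(model, features))
  best <- max.col(post, ties.method = "first")
  maxp <- post[cbind(seq_len(nrow(post)), best)]
  nulled <- maxp < null_posterior_cutoff
  data.frame(
    assigned = ifelse(nulled, NA_integer_, best),
    assigned_index = ifelse(nulled, NA_character_, model$index[best]),
    max_posterior = maxp,
    stringsAsFactors = FALSE
  )
}

#' Finalize the Index-Set catalog after rescue
#'
#' Members of filtered ISs move into the abundant IS the QDA assigned them to
#' (their index string is replaced by the abundant IS's index), or into a
#' single null IS (index `"null"`). Membership of cCREs already in abundant
#' ISs never changes. Mean-signal vectors are recomputed and the total cCRE
#' count is conserved.
#'
#' @param catalog Filtered `is_catalog`.
#' @param model The fitted `qda_model`.
#' @param rescue_res Result of [qda_rescue()] on the filtered cCREs, in the
#'   order produced by [filtered_features()] (filtered ISs in catalog order,
#'   members in stored order).
#' @param signal Optional signal matrix to recompute `mean_signal`.
#' @return A final `is_catalog` whose ISs are the abundant ISs plus one null
#'   IS (status `"null"`, present even when empty), with `rescued_from`
#'   recording each member's original index, and a `rescue` attribute with
#'   the per-cCRE table.
#' @export
finalize_index_sets <- function(catalog, model, rescue_res, signal = NULL) {
  stopifnot(inherits(catalog, "is_catalog"))
  abundant <- model$class_is
  filtered <- which(catalog$status == "filtered")
  filt_rows <- unlist(catalog$members[filtered])
  if (length(filt_rows) != nrow(rescue_res)) {
    stop("rescue result rows (", nrow(rescue_res),
         ") do not match filtered cCRE count (", length(filt_rows), ")",
         call. = FALSE)
  }
  members <- catalog$members[abundant]
  null_members <- integer(0)
  if (length(filt_rows) > 0L) {
    for (j in seq_along(model$classes)) {
      members[[j]] <- sort(c(members[[j]],
                             filt_rows[which(rescue_res$assigned == j)]))
    }
    null_members <- sort(filt_rows[is.na(rescue_res$assigned)])
  }
  members <- c(members, list(null_members))
  idx <- c(catalog$index[abundant], "null")
  final <- structure(
    list(index = idx,
         members = members,
         size = lengths(members),
         mean_signal = NULL,
         status = c(rep("abundant", length(abundant)), "null"),
         cells = catalog$cells,
         dropped = catalog$dropped),
    class = "is_catalog"
  )
  if (!is.null(signal)) {
    ms <- matrix(NA_real_, length(final$index), ncol(signal),
                 dimnames = list(final$index, colnames(signal)))
    for (j in seq_along(final$members)) {
      if (final$size[j] > 0L) {
        ms[j, ] <- colMeans(signal[final$members[[j]], , drop = FALSE])
      }
    }
    final$mean_signal <- ms
  }
  tab <- data.frame(
    row = filt_rows,
    original_index = rep(catalog$index[filtered], catalog$size[filtered]),
    final_index = ifelse(is.na(rescue_res$assigned), "null",
                         rescue_res$assigned_index),
    max_posterior = rescue_res$max_posterior,
    stringsAsFactors = FALSE
  )
  attr(final, "rescue") <- tab
  final
}

#' Feature rows of all filtered cCREs, in catalog order
#'
#' @param catalog Filtered `is_catalog`.
#' @param features Full feature matrix (rows = all cCREs).
#' @return Matrix of the filtered cCREs' feature rows, with an attribute
#'   `rows` giving their row ids.
#' @export
filtered_features <- function(catalog, features) {
  filt_rows <- unlist(catalog$members[catalog$status == "filtered"])
  if (is.null(filt_rows)) filt_rows <- integer(0)
  out <- features[filt_rows, , drop = FALSE]
  attr(out, "rows") <- filt_rows
  out
}
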