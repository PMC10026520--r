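#' Hierarchical linkage over Index-Set mean-signal vectors
#'
#' Agglomerative (complete-linkage) clustering of the per-IS mean-signal
#' vectors under Euclidean distance. Only the mean vectors enter, so the
#' merge is independent of IS sizes. Identical vectors merge at height 0.
#'
#' @param is_mean_signals Matrix, rows = ISs, columns = cell types.
#' @return An `hclust` object.
#' @export
build_linkage <- function(is_mean_signals) {
  stopifnot(is.matrix(is_mean_signals), nrow(is_mean_signals) >= 2L)
  stats::hclust(stats::dist(is_mean_signals, method = "euclidean"),
                method = "complete")
}

#' Choose the Meta-IS count by AIC
#'
#' For each candidate `K` the dendrogram is cut into `K` groups and the IS
#' mean vectors are modeled as spherical Gaussians around their group means
#' with one shared variance, giving `AIC = 2 (K d + 1) + n d ln(RSS / (n d))`
#' where `RSS` is the within-group sum of squares, `n` the IS count and `d`
#' the number of cell types. The smallest `K` attaining the minimum wins; a
#' perfect fit (`RSS = 0`, guarded by an epsilon in the log) wins outright at
#' the smallest such `K`.
#'
#' @param hc Dendrogram from [build_linkage()] (NULL allowed when `n = 1`).
#' @param is_mean_signals Matrix of IS mean-signal vectors.
#' @param k_range Candidate cluster counts; default `2..min(30, n - 1)`.
#' @return List with `K` (chosen count) and `aic` (data.frame of `k`, `rss`,
#'   `aic`).
#' @export
select_k_by_aic <- function(hc, is_mean_signals,
                            k_range = NULL) {
  n <- nrow(is_mean_signals)
  d <- ncol(is_mean_signals)
  if (n == 1L) {
    return(list(K = 1L, aic = data.frame(k = 1L, rss = 0, aic = -Inf)))
  }
  if (is.null(k_range)) k_range <- 2:max(2L, min(30L, n - 1L))
  k_range <- sort(unique(as.integer(k_range)))
  if (any(k_range < 1L | k_range > n)) {
    stop("k_range must lie within [1, number of ISs]", call. = FALSE)
  }
  eps <- .Machine$double.eps
  rss_k <- vapply(k_range, function(k) {
    grp <- stats::cutree(hc, k = k)
    rss <- 0
    for (g in unique(grp)) {
      X <- is_mean_signals[grp == g, , drop = FALSE]
      mu <- colMeans(X)
      rss <- rss + sum(sweep(X, 2L, mu)^2)
    }
    rss
  }, numeric(1))
  aic <- 2 * (k_range * d + 1) + n * d * log(pmax(rss_k, eps) / (n * d))
  perfect <- which(rss_k <= eps)
  chosen <- if (length(perfect) > 0L) k_range[perfect[1L]] else
    k_range[which.min(aic)]
  list(K = chosen, aic = data.frame(k = k_range, rss = rss_k, aic = aic))
}

#' Cut the dendrogram into Meta-Index-Sets
#'
#' Meta ids are numbered by first appearance along the dendrogram leaf order,
#' so adjacent leaves share consecutive meta ids. Meta-IS mean signals are
#' cCRE-weighted means over member ISs.
#'
#' @param hc Dendrogram from [build_linkage()].
#' @param K Number of Meta-ISs.
#' @param catalog Final `is_catalog` whose rows (restricted to `which_is`)
#'   correspond to the dendrogram leaves.
#' @param which_is Integer indices of the catalog ISs that were clustered
#'   (default: all).
#' @return A `meta_catalog`: list with `meta_id` (per clustered IS),
#'   `member_is` (list of IS indices per meta), `size`, `mean_signal`, `K`.
#' @export
assign_meta <- function(hc, K, catalog, which_is = seq_along(catalog$index)) {
  stopifnot(inherits(catalog, "is_catalog"))
  n <- length(which_is)
  if (n == 1L) {
    grp <- 1L
    leaf_order <- 1L
  } else {
    grp <- stats::cutree(hc, k = K)
    leaf_order <- hc$order
  }
  # renumber by first appearance along the dendrogram leaf order
  first_seen <- unique(grp[leaf_order])
  relabel <- match(grp, first_seen)
  member_is <- split(which_is, relabel)
  sizes <- vapply(member_is, function(ids) sum(catalog$size[ids]), numeric(1))
  ms <- NULL
  if (!is.null(catalog$mean_signal)) {
    ms <- t(vapply(member_is, function(ids) {
      w <- catalog$size[ids]
      if (sum(w) == 0) return(rep(NA_real_, ncol(catalog$mean_signal)))
      colSums(catalog$mean_signal[ids, , drop = FALSE] * w) / sum(w)
    }, numeric(ncol(catalog$mean_signal))))
    ms <- matrix(ms, nrow = length(member_is),
                 dimnames = list(NULL, colnames(catalog$mean_signal)))
  }
  structure(
    list(meta_id = relabel, member_is = unname(member_is),
         size = unname(sizes), mean_signal = ms, K = max(relabel),
         which_is = which_is),
    class = "meta_catalog"
  )
}

#' @export
print.meta_catalog <- function(x, ...) {
  cat("meta_catalog:", x$K, "Meta-Index-Sets over",
      length(x$which_is), "ISs;", sum(x$size), "cCREs\n")
  invisible(x)
}

#' Merge Index-Sets into Meta-Index-Sets
#'
#' Convenience wrapper: linkage on IS mean-signal vectors, AIC model
#' selection, and the cut. The null IS is excluded by default (it is a
#' catch-all, not a signal pattern).
#'
#' @param catalog Final `is_catalog` with `mean_signal` available.
#' @param k_range Candidate K values (see [select_k_by_aic()]).
#' @param include_null Include the null IS as a leaf (default FALSE).
#' @return A `meta_catalog` with attribute `aic` (the model-selection table).
#' @export
merge_into_meta <- function(catalog, k_range = NULL, include_null = FALSE) {
  stopifnot(inherits(catalog, "is_catalog"))
  if (is.null(catalog$mean_signal)) {
    stop("catalog has no mean_signal; supply signals upstream", call. = FALSE)
  }
  which_is <- seq_along(catalog$index)
  if (!include_null) {
    which_is <- which_is[catalog$status != "null"]
  }
  which_is <- which_is[catalog$size[which_is] > 0L]
  means <- catalog$mean_signal[which_is, , drop = FALSE]
  if (length(which_is) == 1L) {
    meta <- assign_meta(NULL, 1L, catalog, which_is)
    attr(meta, "aic") <- data.frame(k = 1L, rss = 0, aic = -Inf)
    return(meta)
  }
  hc <- build_linkage(means)
  sel <- select_k_by_aic(hc, means, k_range)
  meta <- assign_meta(hc, sel$K, catalog, which_is)
  attr(meta, "aic") <- sel$aic
  meta
}
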