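#' Column scaling normalization
#'
#' Each column is z-scaled (zero mean, unit variance) and then shifted so its
#' minimum is 0, keeping signals non-negative. Zero-variance columns are left
#' unscaled with a warning.
#'
#' @param sm Signal matrix (rows = cCREs, columns = cell types).
#' @return Normalized matrix of the same shape.
#' @export
scale_norm <- function(sm) {
  stopifnot(is.matrix(sm))
  out <- sm
  for (j in seq_len(ncol(sm))) {
    s <- stats::sd(sm[, j])
    if (!is.finite(s) || s == 0) {
      warning("column ", colnames(sm)[j] %||% j,
              " has zero variance; left unscaled", call. = FALSE)
      next
    }
    z <- (sm[, j] - mean(sm[, j])) / s
    out[, j] <- z - min(z)
  }
  attr(out, "norm_method") <- "scale"
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Quantile normalization
#'
#' Classic quantile normalization (ties averaged): each column's sorted
#' values are replaced by the across-column mean of sorted values.
#'
#' @param sm Signal matrix without NAs.
#' @return Normalized matrix.
#' @export
quantile_norm <- function(sm) {
  stopifnot(is.matrix(sm), !anyNA(sm))
  out <- limma::normalizeQuantiles(sm, ties = TRUE)
  dimnames(out) <- dimnames(sm)
  attr(out, "norm_method") <- "quantile"
  out
}

#' Signal-to-noise anchored normalization
#'
#' Uses the common-peak IS (all-ones index: cCREs called in every cell type)
#' and the common-background IS (all-zeros index) as anchors. Per cell type
#' the signal-to-noise value is the mean signal over common-peak cCREs minus
#' the mean over common-background cCREs; every column is multiplied by
#' `reference / S/N_c`, with the reference the across-cell-type average S/N.
#' This is a single multiplicative factor per cell type, a simplification of
#' the published two-factor signal-to-noise matching.
#'
#' @param sm Signal matrix.
#' @param bm 0/1 presence matrix of the same shape (before dropping all-zero
#'   rows).
#' @param min_members Minimum members required in each anchor IS (default 10).
#' @param on_log Compute the S/N anchors on `log1p` signal (factors still
#'   applied multiplicatively on the raw scale). Default FALSE (raw).
#' @return Normalized matrix with attribute `sn_factors`.
#' @export
s3norm_like <- function(sm, bm, min_members = 10L, on_log = FALSE) {
  stopifnot(is.matrix(sm), identical(dim(sm), dim(bm)))
  ones <- which(rowSums(bm) == ncol(bm))
  zeros <- which(rowSums(bm) == 0L)
  if (length(ones) < min_members || length(zeros) < min_members) {
    stop("need >= ", min_members, " common-peak and common-background cCREs ",
         "for signal-to-noise anchoring (found ", length(ones), " and ",
         length(zeros), "); consider quantile normalization instead",
         call. = FALSE)
  }
  base <- if (on_log) log1p(sm) else sm
  sn <- colMeans(base[ones, , drop = FALSE]) -
    colMeans(base[zeros, , drop = FALSE])
  if (any(sn <= 0)) {
    stop("non-positive signal-to-noise in column(s) ",
         paste(which(sn <= 0), collapse = ", "),
         "; anchors do not separate signal from background", call. = FALSE)
  }
  ref <- mean(sn)
  factors <- ref / sn
  out <- sweep(sm, 2L, factors, `*`)
  attr(out, "norm_method") <- "s3norm"
  attr(out, "sn_factors") <- factors
  out
}

#' Dispatch signal normalization by method name
#'
#' @param sm Signal matrix.
#' @param method One of "none", "scale", "quantile", "s3norm".
#' @param bm Binary matrix (required for "s3norm").
#' @param ... Passed to the method.
#' @return Normalized matrix.
#' @export
normalize_signal <- function(sm, method = c("none", "scale", "quantile",
                                            "s3norm"), bm = NULL, ...) {
  method <- match.arg(method)
  switch(method,
         none = { attr(sm, "norm_method") <- "none"; sm },
         scale = scale_norm(sm),
         quantile = quantile_norm(sm),
         s3norm = {
           if (is.null(bm)) stop("s3norm requires the binary matrix",
                                 call. = FALSE)
           s3norm_like(sm, bm, ...)
         })
}
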