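#' Binarize cCRE presence across cell types
#'
#' Entry `(i, c)` is 1 iff master interval `i` overlaps at least 1 bp of any
#' peak of cell type `c`. Column order follows the linearized cell tree
#' (`tree$leaf_order`), which is the bit order of the index strings.
#'
#' @param master Master-list `GRanges` from [build_master_list()] or a
#'   user-supplied list.
#' @param peak_lists Named list of per-cell-type peak `GRanges`.
#' @param tree A `cell_tree`, or a character vector giving an explicit
#'   cell-type order.
#' @return Integer 0/1 matrix, `length(master)` rows, one column per cell
#'   type in bit order.
#' @export
binarize <- function(master, peak_lists, tree) {
  cells <- if (inherits(tree, "cell_tree")) tree$leaf_order else as.character(tree)
  missing <- setdiff(cells, names(peak_lists))
  if (length(missing) > 0L) {
    stop("cell type(s) in tree with no peak list: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  bm <- vapply(cells, function(ct) {
    as.integer(GenomicRanges::countOverlaps(master, peak_lists[[ct]],
                                            minoverlap = 1L) > 0L)
  }, integer(length(master)))
  bm <- matrix(bm, nrow = length(master), ncol = length(cells),
               dimnames = list(NULL, cells))
  bm
}

#' Encode a 0/1 vector as an index string
#'
#' Bits are joined with underscores in cell-type bit order, e.g.
#' `c(0,0,0,1,0)` becomes `"0_0_0_1_0"`.
#'
#' @param row 0/1 vector (or a 0/1 matrix for the row-wise vectorized form).
#' @return Index string (or character vector, one per matrix row).
#' @export
make_index <- function(row) {
  if (is.matrix(row)) return(make_indices(row))
  if (!all(row %in% c(0L, 1L))) {
    stop("index bits must be 0 or 1", call. = FALSE)
  }
  paste(as.integer(row), collapse = "_")
}

#' @rdname make_index
#' @param bm 0/1 matrix, rows = cCREs.
#' @export
make_indices <- function(bm) {
  if (!all(bm %in% c(0L, 1L))) {
    stop("index bits must be 0 or 1", call. = FALSE)
  }
  unname(apply(bm, 1L, paste, collapse = "_"))
}

index_to_bits <- function(index) {
  lapply(strsplit(index, "_", fixed = TRUE), as.integer)
}

#' Numeric rank of index strings along the linearized tree
#'
#' Interprets each index string as a binary number with the first bit (the
#' tree root end of `leaf_order`) most significant. Used to order Index-Sets
#' in the 2D cluster map.
#'
#' @param index Character vector of index strings.
#' @return Numeric vector of binary values.
#' @export
index_binary_value <- function(index) {
  bits <- index_to_bits(index)
  vapply(bits, function(b) sum(b * 2^(rev(seq_along(b)) - 1)), numeric(1))
}

#' Group cCREs into Index-Sets
#'
#' All cCREs sharing the same index string form one Index-Set (IS). cCREs
#' with an all-zero row (no peak in any cell type; possible when a master
#' list is user-supplied) are excluded before IS formation.
#'
#' @param bm 0/1 matrix from [binarize()].
#' @param signal Optional signal matrix of the same shape; per-IS mean-signal
#'   vectors are computed from it.
#' @param drop_all_zero Drop all-zero rows first (default TRUE).
#' @return An `is_catalog`: list with `index` (character), `members` (list of
#'   integer row ids into `bm`), `size`, `mean_signal` (IS x cell matrix or
#'   NULL), `status` (all `"initial"`), `cells`, and `dropped` (row ids of
#'   all-zero cCREs). ISs are ordered by descending binary value of the
#'   index.
#' @export
group_into_index_sets <- function(bm, signal = NULL, drop_all_zero = TRUE) {
  stopifnot(is.matrix(bm), nrow(bm) > 0L)
  if (!is.null(signal)) stopifnot(identical(dim(signal), dim(bm)))
  rows <- seq_len(nrow(bm))
  dropped <- integer(0)
  if (drop_all_zero) {
    zero <- rowSums(bm) == 0L
    dropped <- rows[zero]
    rows <- rows[!zero]
  }
  if (length(rows) == 0L) {
    stop("no cCRE overlaps any peak; nothing to cluster", call. = FALSE)
  }
  idx <- make_indices(bm[rows, , drop = FALSE])
  members <- split(rows, idx)
  ord <- order(index_binary_value(names(members)), decreasing = TRUE)
  members <- members[ord]
  cat <- structure(
    list(index = names(members),
         members = unname(members),
         size = lengths(unname(members)),
         mean_signal = NULL,
         status = rep("initial", length(members)),
         cells = colnames(bm),
         dropped = dropped),
    class = "is_catalog"
  )
  if (!is.null(signal)) cat$mean_signal <- catalog_mean_signal(cat, signal)
  cat
}

catalog_mean_signal <- function(catalog, signal) {
  ms <- t(vapply(catalog$members, function(ids) {
    colMeans(signal[ids, , drop = FALSE])
  }, numeric(ncol(signal))))
  ms <- matrix(ms, nrow = length(catalog$members), ncol = ncol(signal),
               dimnames = list(catalog$index, colnames(signal)))
  ms
}

#' @export
print.is_catalog <- function(x, ...) {
  cat("is_catalog:", length(x$index), "Index-Sets over", length(x$cells),
      "cell types;", sum(x$size), "cCREs\n")
  tab <- table(x$status)
  cat("  status:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Per-cCRE assignment table from an IS catalog
#'
#' @param catalog An `is_catalog`.
#' @param master Optional master `GRanges` to add coordinates.
#' @return data.frame with one row per member cCRE: `ccre_id` (0-based master
#'   id), `index`, `is_status`, plus coordinates when `master` is given.
#' @export
catalog_assignments <- function(catalog, master = NULL) {
  n <- sum(catalog$size)
  df <- data.frame(
    row = unlist(catalog$members),
    index = rep(catalog$index, catalog$size),
    is_status = rep(catalog$status, catalog$size),
    stringsAsFactors = FALSE
  )
  df <- df[order(df$row), , drop = FALSE]
  rownames(df) <- NULL
  df$ccre_id <- df$row - 1L
  if (!is.null(master)) {
    df$chrom <- as.character(GenomicRanges::seqnames(master))[df$row]
    df$start <- GenomicRanges::start(master)[df$row] - 1L
    df$end <- GenomicRanges::end(master)[df$row]
    df <- df[, c("ccre_id", "chrom", "start", "end", "index", "is_status")]
  } else {
    df <- df[, c("ccre_id", "index", "is_status")]
  }
  df
}
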