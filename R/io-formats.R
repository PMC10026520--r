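#' Read a BED3+ peak file
#'
#' Parses a (possibly headerless) BED file with at least three columns into a
#' sorted `GRanges`. Coordinates are BED-style 0-based half-open on disk and
#' converted to the 1-based closed convention used by `GenomicRanges`.
#' `track`, `browser` and `#`-comment lines are skipped. Extra columns beyond
#' the first three are ignored.
#'
#' @param path Path to a BED file.
#' @return A sorted `GRanges`, possibly empty (with a warning) for an empty
#'   file.
#' @export
read_peak_bed <- function(path) {
  if (!file.exists(path)) {
    stop("BED file not found: ", path, call. = FALSE)
  }
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^(track|browser|#)", lines) & nzchar(trimws(lines))
  if (!any(keep)) {
    warning("BED file has no intervals: ", path, call. = FALSE)
    return(GenomicRanges::GRanges())
  }
  line_no <- which(keep)
  fields <- strsplit(lines[keep], "[\t ]+")
  nf <- lengths(fields)
  if (any(nf < 3L)) {
    bad <- line_no[which(nf < 3L)[1L]]
    stop("malformed BED line (fewer than 3 columns) in ", path,
         " at line ", bad, call. = FALSE)
  }
  chrom <- vapply(fields, `[[`, character(1), 1L)
  s_chr <- vapply(fields, `[[`, character(1), 2L)
  e_chr <- vapply(fields, `[[`, character(1), 3L)
  start0 <- suppressWarnings(as.numeric(s_chr))
  end0 <- suppressWarnings(as.numeric(e_chr))
  bad <- which(!is.finite(start0) | !is.finite(end0) |
                 start0 < 0 | end0 < 0 | start0 != floor(start0) |
                 end0 != floor(end0) | start0 >= end0)
  if (length(bad) > 0L) {
    stop("malformed BED coordinates in ", path, " at line ", line_no[bad[1L]],
         ": '", lines[line_no[bad[1L]]], "'", call. = FALSE)
  }
  gr <- GenomicRanges::GRanges(
    seqnames = chrom,
    ranges = IRanges::IRanges(start = start0 + 1, end = end0)
  )
  GenomicRanges::sort(gr)
}

#' Read one peak BED per cell type
#'
#' @param paths Named character vector of BED paths; names are cell-type
#'   labels. Unnamed paths are named by file basename without extension.
#' @return Named list of sorted `GRanges`, one per cell type.
#' @export
read_peak_beds <- function(paths) {
  paths <- unlist(paths)
  if (is.null(names(paths)) || any(!nzchar(names(paths)))) {
    nm <- names(paths)
    auto <- sub("\\.[^.]*$", "", basename(paths))
    if (is.null(nm)) nm <- auto else nm[!nzchar(nm)] <- auto[!nzchar(nm)]
    names(paths) <- nm
  }
  lapply(paths, read_peak_bed)
}

#' Build a master cCRE list by pooling and merging peaks
#'
#' Concatenates peak calls from all cell types and merges any two intervals
#' that share at least 1 bp. Book-ended intervals (end of one equals start of
#' the next in BED coordinates, 0 shared bp) are kept separate, matching a
#' distance-0 merge. Stable integer ids `0..n-1` are assigned in sorted order.
#'
#' @param peak_lists List of `GRanges` (one per cell type).
#' @return Sorted, non-overlapping `GRanges` with an integer `id` metadata
#'   column.
#' @export
build_master_list <- function(peak_lists) {
  if (!is.list(peak_lists)) peak_lists <- list(peak_lists)
  peak_lists <- peak_lists[vapply(peak_lists, length, integer(1)) > 0L]
  if (length(peak_lists) == 0L) {
    stop("all peak lists are empty; cannot build a master list", call. = FALSE)
  }
  pooled <- suppressWarnings(do.call(c, unname(lapply(peak_lists, function(g) {
    GenomicRanges::granges(g)
  }))))
  # min.gapwidth = 0L merges only intervals sharing >= 1 bp; book-ended
  # intervals stay separate.
  master <- GenomicRanges::reduce(GenomicRanges::sort(pooled), min.gapwidth = 0L)
  master <- GenomicRanges::sort(master)
  S4Vectors::mcols(master)$id <- seq_along(master) - 1L
  master
}

is_bigwig_path <- function(path) {
  grepl("\\.(bw|bigwig)$", path, ignore.case = TRUE)
}

read_signal_track <- function(path) {
  if (is_bigwig_path(path)) {
    rtracklayer::import(rtracklayer::BigWigFile(path))
  } else {
    rtracklayer::import(path, format = "bedGraph")
  }
}

#' Mean signal per interval from a bigWig or bedGraph track
#'
#' Computes, for every master-list interval, the arithmetic mean of the
#' per-base signal over the interval. Bases not covered by the track count as
#' signal 0. Intervals on chromosomes absent from the track get value 0 with
#' a warning.
#'
#' @param path Path to a bigWig (`.bw`/`.bigWig`) or bedGraph track.
#' @param intervals `GRanges` of intervals (e.g. from [build_master_list()]).
#' @return Numeric vector of per-interval means, in `intervals` order.
#' @export
read_signal <- function(path, intervals) {
  track <- read_signal_track(path)
  cov <- GenomicRanges::coverage(track, weight = "score")
  n <- length(intervals)
  out <- numeric(n)
  chrom <- as.character(GenomicRanges::seqnames(intervals))
  starts <- GenomicRanges::start(intervals)
  ends <- GenomicRanges::end(intervals)
  missing_chr <- unique(chrom[!(chrom %in% names(cov))])
  if (length(missing_chr) > 0L) {
    warning("chromosome(s) absent from signal track ", path, ": ",
            paste(missing_chr, collapse = ", "),
            "; affected intervals set to 0", call. = FALSE)
  }
  for (chr in intersect(unique(chrom), names(cov))) {
    rle <- cov[[chr]]
    idx <- which(chrom == chr)
    # pad with zeros so intervals past the track's last base count as 0
    need <- max(ends[idx])
    if (length(rle) < need) {
      rle <- c(rle, S4Vectors::Rle(0, need - length(rle)))
    }
    v <- IRanges::Views(rle, start = starts[idx], end = ends[idx])
    out[idx] <- IRanges::viewSums(v) / (ends[idx] - starts[idx] + 1)
  }
  out
}

#' Build the per-cCRE, per-cell-type signal matrix
#'
#' @param paths Named character vector of signal-track paths (bigWig or
#'   bedGraph), one per cell type.
#' @param intervals Master-list `GRanges`.
#' @param cells Cell types (column order); defaults to `names(paths)`.
#' @return Numeric matrix, rows = intervals, columns = cell types.
#' @export
read_signal_matrix <- function(paths, intervals, cells = names(paths)) {
  stopifnot(!is.null(cells), all(cells %in% names(paths)))
  sm <- vapply(cells, function(ct) read_signal(paths[[ct]], intervals),
               numeric(length(intervals)))
  sm <- matrix(sm, nrow = length(intervals), ncol = length(cells),
               dimnames = list(NULL, cells))
  sm
}

#' Read a cell-differentiation tree from parent-child edges
#'
#' The file holds one `parent child` pair per line, whitespace- or
#' comma-separated. The linear cell-type order (`leaf_order`) used as the bit
#' order for indexing is the depth-first pre-order traversal from the root,
#' with children visited in file order, unless `order` is supplied.
#'
#' @param path Path to the edge-list file.
#' @param order Optional explicit cell-type order; must be a permutation of
#'   the tree's nodes.
#' @return An object of class `cell_tree` with elements `nodes`, `edges`
#'   (data.frame `parent`,`child`), `roots` and `leaf_order`.
#' @export
read_cell_tree <- function(path, order = NULL) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !grepl("^#", lines)]
  if (length(lines) == 0L) stop("empty tree file: ", path, call. = FALSE)
  parts <- strsplit(lines, "[,\t ]+")
  nf <- lengths(parts)
  if (any(!nf %in% c(1L, 2L))) {
    stop("malformed tree line in ", path, ": '",
         lines[which(!nf %in% c(1L, 2L))[1L]], "'", call. = FALSE)
  }
  single <- vapply(parts, length, integer(1)) == 1L
  edges <- if (any(!single)) {
    data.frame(parent = vapply(parts[!single], `[[`, character(1), 1L),
               child = vapply(parts[!single], `[[`, character(1), 2L),
               stringsAsFactors = FALSE)
  } else {
    data.frame(parent = character(0), child = character(0))
  }
  isolated <- unlist(parts[single])
  cell_tree(edges, isolated = isolated, order = order)
}

#' Construct a `cell_tree` from an edge table
#'
#' @param edges data.frame with columns `parent` and `child`.
#' @param isolated Optional labels of single nodes with no edges.
#' @param order Optional explicit leaf order.
#' @return A `cell_tree` object.
#' @export
cell_tree <- function(edges, isolated = character(0), order = NULL) {
  edges$parent <- as.character(edges$parent)
  edges$child <- as.character(edges$child)
  nodes <- unique(c(edges$parent, edges$child, isolated))
  if (anyDuplicated(edges$child)) {
    stop("duplicate child in tree: ",
         edges$child[duplicated(edges$child)][1L], call. = FALSE)
  }
  children <- split(edges$child, factor(edges$parent, levels = nodes))
  roots <- setdiff(nodes, edges$child)
  if (nrow(edges) > 0L && length(roots) == 0L) {
    stop("cycle detected in cell tree: no root node", call. = FALSE)
  }
  preorder <- character(0)
  visit <- function(node, path) {
    if (node %in% path) stop("cycle detected in cell tree at node ", node,
                             call. = FALSE)
    preorder <<- c(preorder, node)
    for (ch in children[[node]]) visit(ch, c(path, node))
  }
  for (r in roots) visit(r, character(0))
  if (length(preorder) != length(nodes)) {
    stop("cycle detected in cell tree: unreachable nodes ",
         paste(setdiff(nodes, preorder), collapse = ", "), call. = FALSE)
  }
  leaf_order <- if (is.null(order)) preorder else {
    if (!setequal(order, nodes) || length(order) != length(nodes)) {
      stop("explicit order must be a permutation of the tree's nodes",
           call. = FALSE)
    }
    as.character(order)
  }
  structure(
    list(nodes = nodes, edges = edges, roots = roots, leaf_order = leaf_order),
    class = "cell_tree"
  )
}

#' @export
print.cell_tree <- function(x, ...) {
  cat("cell_tree:", length(x$nodes), "cell types,",
      nrow(x$edges), "edges\n")
  cat("  order:", paste(x$leaf_order, collapse = " > "), "\n")
  invisible(x)
}

#' Read per-cell-type epigenetic-state segmentations (BED4)
#'
#' Each file holds fixed-width bins `chrom start end state_label`. Bins within
#' a cell type must be non-overlapping.
#'
#' @param paths Named character vector of BED4 paths, one per cell type.
#' @param bin_width Expected bin width in bp (informational; default 200).
#' @return Named list of `GRanges` with a `state` metadata column.
#' @export
read_state_beds <- function(paths, bin_width = 200L) {
  out <- lapply(paths, function(path) {
    lines <- readLines(path, warn = FALSE)
    keep <- !grepl("^(track|browser|#)", lines) & nzchar(trimws(lines))
    if (!any(keep)) {
      warning("state BED has no bins: ", path, call. = FALSE)
      gr <- GenomicRanges::GRanges()
      S4Vectors::mcols(gr)$state <- character(0)
      return(gr)
    }
    fields <- strsplit(lines[keep], "[\t ]+")
    if (any(lengths(fields) < 4L)) {
      stop("state BED needs 4 columns (chrom start end state): ", path,
           " line ", which(keep)[which(lengths(fields) < 4L)[1L]],
           call. = FALSE)
    }
    gr <- GenomicRanges::GRanges(
      seqnames = vapply(fields, `[[`, character(1), 1L),
      ranges = IRanges::IRanges(
        start = as.integer(vapply(fields, `[[`, character(1), 2L)) + 1L,
        end = as.integer(vapply(fields, `[[`, character(1), 3L))
      ),
      state = vapply(fields, `[[`, character(1), 4L)
    )
    gr <- GenomicRanges::sort(gr)
    ov <- GenomicRanges::findOverlaps(gr, drop.self = TRUE)
    if (length(ov) > 0L) {
      stop("overlapping state bins in ", path, call. = FALSE)
    }
    gr
  })
  attr(out, "bin_width") <- as.integer(bin_width)
  out
}

#' Read a state color table
#'
#' Two columns: state label and an `R,G,B` triple (0-255), tab- or
#' whitespace-separated.
#'
#' @param path Path to the color table.
#' @return data.frame with columns `state`, `r`, `g`, `b` and a `hex` column.
#' @export
read_color_table <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !grepl("^#", lines)]
  parts <- strsplit(lines, "[\t ]+")
  if (any(lengths(parts) < 2L)) {
    stop("color table lines need 'state R,G,B': ", path, call. = FALSE)
  }
  state <- vapply(parts, `[[`, character(1), 1L)
  rgb_chr <- vapply(parts, `[[`, character(1), 2L)
  rgb <- t(vapply(strsplit(rgb_chr, ","), function(v) {
    x <- suppressWarnings(as.numeric(v))
    if (length(x) != 3L || any(!is.finite(x)) || any(x < 0 | x > 255)) {
      stop("malformed RGB triple in color table: ", paste(v, collapse = ","),
           call. = FALSE)
    }
    x
  }, numeric(3)))
  if (anyDuplicated(state)) {
    stop("duplicate state label in color table: ",
         state[duplicated(state)][1L], call. = FALSE)
  }
  data.frame(state = state, r = rgb[, 1L], g = rgb[, 2L], b = rgb[, 3L],
             hex = grDevices::rgb(rgb[, 1L], rgb[, 2L], rgb[, 3L],
                                  maxColorValue = 255),
             stringsAsFactors = FALSE)
}

#' Write a `GRanges` as BED3 (0-based half-open)
#'
#' @param gr Intervals to write.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed3 <- function(gr, path) {
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr) - 1L,
                   end = GenomicRanges::end(gr))
  data.table::fwrite(df, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

write_bedgraph <- function(gr, score, path) {
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr) - 1L,
                   end = GenomicRanges::end(gr),
                   score = score)
  data.table::fwrite(df, path, sep = "\t", col.names = FALSE)
  invisible(path)
}
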