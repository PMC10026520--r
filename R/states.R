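#' Dominant epigenetic state of a cCRE in one cell type
#'
#' Applies, in order: (1) if any overlapping non-quiescent state exists,
#' quiescent states are ineligible; (2) among eligible states pick the one
#' covering the largest proportion of the cCRE; (3) on a tie, the state whose
#' covering bins' midpoint (midpoint of the union of that state's overlapping
#' bins, clipped to the cCRE) is closest to the cCRE midpoint; (4) on a
#' further tie, the state whose overlapping bins span more total base pairs
#' (unclipped, so extension beyond the cCRE breaks the tie); any remaining
#' tie goes to the lexicographically smallest label. A cCRE with no
#' overlapping bin is labelled with the first quiescent label, with a
#' warning.
#'
#' @param ccre_start,ccre_end cCRE coordinates, 0-based half-open.
#' @param bin_start,bin_end,bin_state Parallel vectors describing the state
#'   bins overlapping the cCRE (same chromosome; 0-based half-open).
#' @param quiescent_labels Labels treated as quiescent
#'   (default `c("0", "Q", "quiescent")`).
#' @return A single state label.
#' @export
dominant_state <- function(ccre_start, ccre_end, bin_start, bin_end,
                           bin_state,
                           quiescent_labels = c("0", "Q", "quiescent")) {
  stopifnot(ccre_start < ccre_end)
  ov <- pmin(bin_end, ccre_end) - pmax(bin_start, ccre_start)
  keep <- which(ov > 0)
  if (length(keep) == 0L) {
    warning("cCRE [", ccre_start, ",", ccre_end,
            ") overlaps no state bin; assigning quiescent", call. = FALSE)
    return(quiescent_labels[1L])
  }
  bs <- bin_start[keep]; be <- bin_end[keep]; st <- bin_state[keep]
  width <- ccre_end - ccre_start
  states <- sort(unique(st))
  cov_bp <- vapply(states, function(s) {
    i <- st == s
    sum(pmin(be[i], ccre_end) - pmax(bs[i], ccre_start))
  }, numeric(1))
  total_bp <- vapply(states, function(s) sum(be[st == s] - bs[st == s]),
                     numeric(1))
  mid_dist <- vapply(states, function(s) {
    i <- st == s
    lo <- max(min(bs[i]), ccre_start)
    hi <- min(max(be[i]), ccre_end)
    abs((lo + hi) / 2 - (ccre_start + ccre_end) / 2)
  }, numeric(1))

  eligible <- rep(TRUE, length(states))
  if (any(!(states %in% quiescent_labels)))
    eligible <- !(states %in% quiescent_labels)

  cand <- which(eligible)
  prop <- cov_bp / width
  cand <- cand[prop[cand] == max(prop[cand])]
  if (length(cand) > 1L) cand <- cand[mid_dist[cand] == min(mid_dist[cand])]
  if (length(cand) > 1L) cand <- cand[total_bp[cand] == max(total_bp[cand])]
  states[cand[1L]]  # states sorted: lexicographic final tie-break
}

#' Dominant states for all cCREs across all cell types
#'
#' @param master Master `GRanges`.
#' @param state_tracks Named list of state `GRanges` (from
#'   [read_state_beds()]), one per cell type.
#' @param cells Cell types to annotate (default: names of `state_tracks`).
#' @param quiescent_labels See [dominant_state()].
#' @return Character matrix, rows = cCREs, columns = cell types.
#' @export
annotate_states <- function(master, state_tracks,
                            cells = names(state_tracks),
                            quiescent_labels = c("0", "Q", "quiescent")) {
  out <- matrix(NA_character_, nrow = length(master), ncol = length(cells),
                dimnames = list(NULL, cells))
  m_start <- GenomicRanges::start(master) - 1L
  m_end <- GenomicRanges::end(master)
  for (ct in cells) {
    gr <- state_tracks[[ct]]
    if (is.null(gr)) stop("no state track for cell type ", ct, call. = FALSE)
    hits <- GenomicRanges::findOverlaps(master, gr, minoverlap = 1L)
    q <- S4Vectors::queryHits(hits)
    s <- S4Vectors::subjectHits(hits)
    b_start <- GenomicRanges::start(gr) - 1L
    b_end <- GenomicRanges::end(gr)
    b_state <- S4Vectors::mcols(gr)$state
    by_ccre <- split(s, q)
    for (key in names(by_ccre)) {
      i <- as.integer(key)
      js <- by_ccre[[key]]
      out[i, ct] <- dominant_state(m_start[i], m_end[i],
                                   b_start[js], b_end[js], b_state[js],
                                   quiescent_labels)
    }
    none <- which(is.na(out[, ct]))
    if (length(none) > 0L) {
      warning(length(none), " cCRE(s) overlap no state bin in ", ct,
              "; assigned quiescent", call. = FALSE)
      out[none, ct] <- quiescent_labels[1L]
    }
  }
  out
}

#' Representative states (and color) of a cluster in one cell type
#'
#' States are sorted by member frequency (ties broken by label order) and the
#' minimal prefix whose cumulative frequency exceeds 0.5 is the
#' representative set. The display color is the frequency-weighted average of
#' the prefix states' RGB colors, with weights renormalized over the prefix.
#'
#' @param member_states Character vector: the cluster members' dominant
#'   states in that cell type.
#' @param colors Color table from [read_color_table()].
#' @return List with `states`, `freqs` (renormalized prefix weights), `rgb`
#'   (length-3), `hex`.
#' @export
representative_states <- function(member_states, colors) {
  stopifnot(length(member_states) > 0L)
  tab <- table(member_states)
  freq <- as.numeric(tab) / length(member_states)
  labels <- names(tab)
  ord <- order(-freq, labels)
  freq <- freq[ord]; labels <- labels[ord]
  cum <- cumsum(freq)
  k <- which(cum > 0.5)[1L]
  if (is.na(k)) k <- length(labels)  # numerically defensive; cum ends at 1
  prefix <- labels[seq_len(k)]
  w <- freq[seq_len(k)] / sum(freq[seq_len(k)])
  miss <- setdiff(prefix, colors$state)
  if (length(miss) > 0L) {
    stop("state(s) missing from color table: ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  m <- match(prefix, colors$state)
  rgb <- c(sum(w * colors$r[m]), sum(w * colors$g[m]), sum(w * colors$b[m]))
  list(states = prefix, freqs = w, rgb = rgb,
       hex = grDevices::rgb(rgb[1L], rgb[2L], rgb[3L], maxColorValue = 255))
}

#' Representative states for every cluster and cell type
#'
#' @param state_matrix Character matrix from [annotate_states()].
#' @param members List of integer row-id vectors, one per cluster.
#' @param colors Color table.
#' @param cluster_ids Labels for the clusters (default seq).
#' @return data.frame with one row per (cluster, cell type):
#'   `cluster`, `cell_type`, `states` (comma-joined), `hex`.
#' @export
cluster_representative_states <- function(state_matrix, members, colors,
                                          cluster_ids = seq_along(members)) {
  rows <- list()
  for (j in seq_along(members)) {
    ids <- members[[j]]
    if (length(ids) == 0L) next
    for (ct in colnames(state_matrix)) {
      rep <- representative_states(state_matrix[ids, ct], colors)
      rows[[length(rows) + 1L]] <- data.frame(
        cluster = as.character(cluster_ids[j]), cell_type = ct,
        states = paste(rep$states, collapse = ","), hex = rep$hex,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
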