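#' Default hematopoietic-like differentiation tree edges
#'
#' 13 cell types: stem (HSC), myeloid (CMP, MEP, ERY, MK, GMP, MON, NEU) and
#' lymphoid (CLP, B, NK, TCD4, TCD8) branches, mirroring the scale and shape
#' of a typical blood-cell differentiation hierarchy.
#'
#' @return data.frame of `parent`, `child` edges.
#' @export
default_fixture_tree <- function() {
  data.frame(
    parent = c("HSC", "HSC", "CMP", "CMP", "MEP", "MEP", "GMP", "GMP",
               "CLP", "CLP", "CLP", "CLP"),
    child = c("CMP", "CLP", "MEP", "GMP", "ERY", "MK", "MON", "NEU",
              "B", "NK", "TCD4", "TCD8"),
    stringsAsFactors = FALSE
  )
}

default_fixture_patterns <- function(cells) {
  pat <- function(on) as.integer(cells %in% on)
  list(
    common = pat(cells),
    myeloid_prog = pat(c("HSC", "CMP", "MEP", "ERY", "MK")),
    erythroid = pat(c("CMP", "MEP", "ERY")),
    lymphoid = pat(c("CLP", "B", "NK", "TCD4", "TCD8")),
    ery_only = pat("ERY")
  )
}

#' Configuration for the synthetic fixture generator
#'
#' Defaults emulate a down-scaled multi-cell-type chromatin-accessibility
#' study: 13 cell types on a hematopoietic-like tree, 5 planted index
#' patterns with strongly unbalanced abundances (2000/1000/500/300/174),
#' a 5% per-cCRE chance of one spurious (flipped) peak call, 200 noise cCREs with
#' singleton-ish patterns at Hamming distance 1-2 from planted patterns, and
#' 300 all-background cCREs (anchors for signal-to-noise normalization).
#' Signals are log-normal: present bits high location, absent bits low.
#'
#' @param n_patterns Unused placeholder for partial overrides; patterns are
#'   set via `patterns`.
#' @param tree_edges data.frame of parent/child edges.
#' @param cell_order Optional explicit bit order (default: tree pre-order).
#' @param patterns Named list of 0/1 vectors in bit order.
#' @param abundances Planted copies per pattern.
#' @param bit_flip_rate Probability that a planted member carries one
#'   spurious peak call (a single uniformly chosen bit inverted);
#'   0 <= rate < 0.5.
#' @param n_noise_singletons Number of noise cCREs with patterns at Hamming
#'   distance 1-2 from a random planted pattern.
#' @param n_background Number of all-zero (no peak anywhere) cCREs.
#' @param signal_present,signal_absent `c(meanlog, sdlog)` of the log-normal
#'   signal for present / absent bits.
#' @param scale_distortions NULL (off) or `c(log_min, log_max)`: per-cell
#'   multiplicative distortion drawn log-uniform on that natural-log range.
#' @param states,state_colors State alphabet and their RGB rows.
#' @param state_freq_present,state_freq_absent Named state probabilities for
#'   200 bp bins where the planted bit is 1 / 0.
#' @param ccre_width,ccre_spacing,chrom Geometry of the synthetic master
#'   list; width and spacing must be multiples of the 200 bp state bin.
#' @param seed Master seed: the same config is byte-identical across runs.
#' @return A `fixture_config` list.
#' @export
fixture_config <- function(tree_edges = default_fixture_tree(),
                           cell_order = NULL,
                           patterns = NULL,
                           abundances = c(2000L, 1000L, 500L, 300L, 174L),
                           bit_flip_rate = 0.05,
                           n_noise_singletons = 200L,
                           n_background = 300L,
                           signal_present = c(meanlog = 2, sdlog = 0.5),
                           signal_absent = c(meanlog = -1, sdlog = 0.5),
                           scale_distortions = NULL,
                           states = c("Q", "E", "H", "T"),
                           state_colors = rbind(Q = c(220, 220, 220),
                                                E = c(255, 69, 0),
                                                H = c(255, 215, 0),
                                                T = c(0, 128, 0)),
                           state_freq_present = c(E = 0.7, H = 0.2, T = 0.1),
                           state_freq_absent = c(Q = 0.8, H = 0.2),
                           ccre_width = 400L,
                           ccre_spacing = 1000L,
                           chrom = "chr1",
                           seed = 42L,
                           n_patterns = NULL) {
  tree <- cell_tree(tree_edges, order = cell_order)
  cells <- tree$leaf_order
  if (is.null(patterns)) patterns <- default_fixture_patterns(cells)
  stopifnot(length(abundances) == length(patterns),
            all(abundances >= 1L),
            bit_flip_rate >= 0, bit_flip_rate < 0.5,
            all(vapply(patterns, length, integer(1)) == length(cells)),
            signal_present[["meanlog"]] > signal_absent[["meanlog"]],
            ccre_width %% 200L == 0L, ccre_spacing %% 200L == 0L,
            ccre_spacing >= ccre_width)
  if (!setequal(rownames(state_colors), states)) {
    stop("state_colors rows must match the state alphabet", call. = FALSE)
  }
  if (!all(names(state_freq_present) %in% states) ||
      !all(names(state_freq_absent) %in% states)) {
    stop("state frequencies name states outside the alphabet", call. = FALSE)
  }
  structure(
    list(tree = tree, cells = cells, patterns = patterns,
         abundances = as.integer(abundances),
         bit_flip_rate = bit_flip_rate,
         n_noise_singletons = as.integer(n_noise_singletons),
         n_background = as.integer(n_background),
         signal_present = signal_present, signal_absent = signal_absent,
         scale_distortions = scale_distortions,
         states = states, state_colors = state_colors,
         state_freq_present = state_freq_present,
         state_freq_absent = state_freq_absent,
         ccre_width = as.integer(ccre_width),
         ccre_spacing = as.integer(ccre_spacing),
         chrom = chrom, seed = as.integer(seed)),
    class = "fixture_config"
  )
}

sample_states <- function(n, freq, alphabet) {
  probs <- stats::setNames(rep(0, length(alphabet)), alphabet)
  probs[names(freq)] <- freq
  sample(alphabet, n, replace = TRUE, prob = probs)
}

#' Generate a synthetic input bundle with ground truth
#'
#' Writes, under `dir`: one peak BED and one bedGraph signal track per cell
#' type (`peaks_<cell>.bed`, `signal_<cell>.bedgraph`), one state BED4 per
#' cell type (`states_<cell>.bed`, 200 bp bins), `tree.txt`,
#' `state_colors.txt`, `master_synthetic.bed` (all intervals, including
#' all-background cCREs) and `ground_truth.tsv`. Peak calls come from the
#' *observed* (bit-flipped) patterns while signals and states follow the
#' *planted* patterns, so spurious peak calls are correctable from the
#' signal profile — the situation the rescue step is designed for.
#'
#' @param config A `fixture_config`.
#' @param dir Output directory (created if absent).
#' @return Invisible list with `paths` (named file paths), `truth`
#'   (data.frame), `config`, `tree`, and the `planted`/`observed` matrices.
#' @export
generate_fixture <- function(config, dir) {
  stopifnot(inherits(config, "fixture_config"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(config$seed)
  cells <- config$cells
  d <- length(cells)

  pat_mat <- do.call(rbind, config$patterns)
  roles <- c(rep(names(config$patterns), config$abundances),
             rep("noise", config$n_noise_singletons),
             rep("background", config$n_background))
  planted <- pat_mat[rep(seq_along(config$patterns), config$abundances), ,
                     drop = FALSE]
  if (config$n_noise_singletons > 0L) {
    # singleton noise ISs: patterns at Hamming distance 1-2 from a planted
    # pattern, distinct from the planted patterns and from each other so
    # each contributes an IS of size 1
    seen <- new.env(hash = TRUE)
    for (p in make_indices(pat_mat)) seen[[p]] <- TRUE
    noise <- matrix(0L, config$n_noise_singletons, d)
    for (i in seq_len(config$n_noise_singletons)) {
      for (try in 1:200) {
        cand <- pat_mat[sample.int(nrow(pat_mat), 1L), ]
        flip <- sample.int(d, sample(1:2, 1L))
        cand[flip] <- 1L - cand[flip]
        if (sum(cand) == 0L) next
        key <- paste(cand, collapse = "_")
        if (is.null(seen[[key]])) {
          seen[[key]] <- TRUE
          noise[i, ] <- cand
          break
        }
        if (try == 200L) stop("cannot draw enough distinct noise patterns; ",
                              "reduce n_noise_singletons", call. = FALSE)
      }
    }
    planted <- rbind(planted, noise)
  }
  if (config$n_background > 0L) {
    planted <- rbind(planted, matrix(0L, config$n_background, d))
  }
  n <- nrow(planted)
  colnames(planted) <- cells

  # bit_flip_rate is the per-cCRE probability of one spurious peak call:
  # a flipped cCRE gets exactly one uniformly chosen bit inverted. (A per-bit
  # rate would make Hamming-1 neighbor ISs of large patterns as big as the
  # smallest planted IS, so no abundance threshold could separate them.)
  observed <- planted
  is_planted_member <- roles %in% names(config$patterns)
  if (config$bit_flip_rate > 0 && any(is_planted_member)) {
    idx <- which(is_planted_member)
    hit <- idx[stats::runif(length(idx)) < config$bit_flip_rate]
    if (length(hit) > 0L) {
      bit <- sample.int(d, length(hit), replace = TRUE)
      observed[cbind(hit, bit)] <- 1L - observed[cbind(hit, bit)]
    }
  }
  flipped <- rowSums(observed != planted) > 0L

  # master geometry: equally spaced, 200 bp-aligned intervals on one chromosome
  starts0 <- (seq_len(n) - 1L) * config$ccre_spacing
  ends0 <- starts0 + config$ccre_width
  master <- GenomicRanges::GRanges(
    config$chrom, IRanges::IRanges(start = starts0 + 1L, end = ends0))
  S4Vectors::mcols(master)$id <- seq_len(n) - 1L

  # signals follow the planted (true) pattern
  sig <- matrix(0, n, d, dimnames = list(NULL, cells))
  for (j in seq_len(d)) {
    on <- planted[, j] == 1L
    sig[on, j] <- stats::rlnorm(sum(on),
                                config$signal_present[["meanlog"]],
                                config$signal_present[["sdlog"]])
    sig[!on, j] <- stats::rlnorm(sum(!on),
                                 config$signal_absent[["meanlog"]],
                                 config$signal_absent[["sdlog"]])
  }
  distortions <- rep(1, d)
  if (!is.null(config$scale_distortions)) {
    distortions <- exp(stats::runif(d, config$scale_distortions[1L],
                                    config$scale_distortions[2L]))
    sig <- sweep(sig, 2L, distortions, `*`)
  }

  paths <- list(peaks = character(0), signals = character(0),
                states = character(0))
  n_bins <- config$ccre_width %/% 200L
  bin_starts0 <- as.vector(vapply(seq_len(n_bins) - 1L,
                                  function(b) starts0 + b * 200L,
                                  numeric(n)))
  bin_starts0 <- sort(bin_starts0)
  for (j in seq_len(d)) {
    ct <- cells[j]
    pk_path <- file.path(dir, paste0("peaks_", ct, ".bed"))
    on <- observed[, j] == 1L
    write_bed3(master[on], pk_path)
    paths$peaks[ct] <- pk_path

    sg_path <- file.path(dir, paste0("signal_", ct, ".bedgraph"))
    write_bedgraph(master, round(sig[, j], 6), sg_path)
    paths$signals[ct] <- sg_path

    st_path <- file.path(dir, paste0("states_", ct, ".bed"))
    bin_on <- rep(planted[, j] == 1L, each = n_bins)
    st <- character(length(bin_starts0))
    st[bin_on] <- sample_states(sum(bin_on), config$state_freq_present,
                                config$states)
    st[!bin_on] <- sample_states(sum(!bin_on), config$state_freq_absent,
                                 config$states)
    data.table::fwrite(
      data.frame(config$chrom, bin_starts0, bin_starts0 + 200L, st),
      st_path, sep = "\t", col.names = FALSE)
    paths$states[ct] <- st_path
  }

  tree_path <- file.path(dir, "tree.txt")
  writeLines(paste(config$tree$edges$parent, config$tree$edges$child),
             tree_path)
  color_path <- file.path(dir, "state_colors.txt")
  writeLines(paste0(rownames(config$state_colors), "\t",
                    apply(config$state_colors, 1L, paste, collapse = ",")),
             color_path)
  master_path <- file.path(dir, "master_synthetic.bed")
  write_bed3(master, master_path)

  truth <- data.frame(
    ccre_id = seq_len(n) - 1L,
    chrom = config$chrom, start = starts0, end = ends0,
    role = roles,
    planted_index = make_indices(planted),
    observed_index = make_indices(observed),
    flipped = as.integer(flipped),
    stringsAsFactors = FALSE
  )
  truth_path <- file.path(dir, "ground_truth.tsv")
  data.table::fwrite(truth, truth_path, sep = "\t")

  invisible(list(
    paths = c(paths, list(tree = tree_path, colors = color_path,
                          master = master_path, truth = truth_path)),
    truth = truth, config = config, tree = config$tree,
    planted = planted, observed = observed, signal = sig,
    distortions = distortions, master = master
  ))
}
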