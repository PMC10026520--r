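#' Evaluation protocols over a finished pipeline run
#'
#' Re-loads the tabular outputs of [run_pipeline()] from `out_dir` and runs
#' the three assessment protocols: sliding-window Shannon entropy of the
#' sorted binary map, noise-injection ARI reproducibility of a K-means
#' re-clustering of the signal matrix, and the Meta-IS K-means recovery
#' frequency. Results are written as TSVs (`entropy.tsv`, `ari.tsv`,
#' `rarity.tsv`) next to the run outputs; all seeds are logged in the
#' tables.
#'
#' @param out_dir Directory produced by [run_pipeline()].
#' @param N_values Window heights for the entropy scan (default
#'   `c(5, 10, 50)`).
#' @param M_values Window widths; default 2..n_celltypes.
#' @param n_reps ARI noise repetitions (default 5).
#' @param rounds K-means rounds for the rarity protocol (default 100).
#' @param seed Master seed for the stochastic protocols.
#' @return Invisible list with `entropy`, `ari`, `rarity` data.frames.
#' @export
evaluate_run <- function(out_dir, N_values = c(5L, 10L, 50L),
                         M_values = NULL, n_reps = 5L, rounds = 100L,
                         seed = 1L) {
  bm <- as.matrix(data.table::fread(file.path(out_dir, "binary_matrix.tsv")))
  sig <- as.matrix(data.table::fread(file.path(out_dir, "signal_matrix.tsv")))
  asg <- data.table::fread(file.path(out_dir, "ccre_catalog.tsv"),
                           colClasses = list(character = c("original_index",
                                                           "final_index")))
  meta_tab <- data.table::fread(file.path(out_dir, "meta_catalog.tsv"))
  if (is.null(M_values)) M_values <- 2:ncol(bm)

  # rebuild the sorted map from the per-cCRE final assignment
  rows <- asg$ccre_id + 1L
  fin <- asg$final_index
  real <- fin != "null"
  ord <- c(order(index_binary_value(fin[real]), decreasing = TRUE) |>
             (\(o) which(real)[o])(),
           which(!real))
  map <- bm[rows[ord], , drop = FALSE]

  entropy <- do.call(rbind, lapply(N_values, function(N) {
    if (N > nrow(map)) return(NULL)
    shannon_entropy(map, N, M_values)
  }))
  entropy$seed <- seed
  write_tsv(entropy, file.path(out_dir, "entropy.tsv"))

  K <- max(meta_tab$meta_id)
  kmeans_labeler <- function(data, s) {
    set.seed(s)
    stats::kmeans(data, centers = K, nstart = 1L, iter.max = 100L,
                  algorithm = "Lloyd")$cluster
  }
  ari <- ari_reproducibility(kmeans_labeler, sig, n_reps = n_reps,
                             seed = seed)
  ari_df <- data.frame(pair = seq_along(ari), ari = as.numeric(ari),
                       seed = seed)
  write_tsv(ari_df, file.path(out_dir, "ari.tsv"))

  meta_means <- as.matrix(meta_tab[, setdiff(colnames(meta_tab),
                                             c("meta_id", "size")),
                                   with = FALSE])
  counts <- rare_cluster_frequency(meta_means, sig, K = K, rounds = rounds,
                                   seed = seed)
  rarity <- data.frame(meta_id = meta_tab$meta_id, size = meta_tab$size,
                       count = counts, rounds = rounds, seed = seed)
  write_tsv(rarity, file.path(out_dir, "rarity.tsv"))

  invisible(list(entropy = entropy, ari = ari_df, rarity = rarity))
}
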