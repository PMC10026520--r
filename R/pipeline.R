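#' Assemble and validate an end-to-end run configuration
#'
#' @param peaks Named character vector of per-cell-type peak BED paths.
#' @param signals Named character vector of per-cell-type signal tracks
#'   (bigWig or bedGraph).
#' @param tree Path to a tree edge file, or a `cell_tree`.
#' @param out_dir Output directory.
#' @param master Optional path to a user master cCRE list (BED); when NULL
#'   the master list is pooled and merged from the peak files.
#' @param states Optional named character vector of state BED4 paths.
#' @param colors Optional path to the state color table (required with
#'   `states`).
#' @param cell_order Optional explicit bit order overriding tree pre-order.
#' @param normalization One of "none", "scale", "quantile", "s3norm".
#' @param exclusion_fraction,fdr_alpha,manual_threshold Abundance-filter
#'   settings.
#' @param feature_mode QDA features: "signal" (default) or "binary".
#' @param null_posterior_cutoff,ridge Rescue settings.
#' @param k_range,include_null Meta-clustering settings.
#' @param plots Emit figure files (default TRUE).
#' @param seed Seed recorded in the manifest (the core pipeline is
#'   deterministic; the seed feeds evaluation protocols).
#' @return A validated `run_config` list.
#' @export
run_config <- function(peaks, signals, tree, out_dir,
                       master = NULL, states = NULL, colors = NULL,
                       cell_order = NULL,
                       normalization = c("none", "scale", "quantile",
                                         "s3norm"),
                       exclusion_fraction = 0.05, fdr_alpha = 0.01,
                       manual_threshold = NULL,
                       feature_mode = c("signal", "binary"),
                       null_posterior_cutoff = 0.5, ridge = 1e-6,
                       k_range = NULL, include_null = FALSE,
                       plots = TRUE, seed = 1L) {
  normalization <- match.arg(normalization)
  feature_mode <- match.arg(feature_mode)
  for (p in c(peaks, signals, master,
              if (is.character(tree)) tree else NULL, states, colors)) {
    if (!file.exists(p)) stop("input file not found: ", p, call. = FALSE)
  }
  if (!is.null(states) && is.null(colors)) {
    stop("state tracks supplied without a state color table", call. = FALSE)
  }
  if (is.null(names(peaks)) || is.null(names(signals))) {
    stop("peaks and signals must be named by cell type", call. = FALSE)
  }
  structure(
    list(peaks = peaks, signals = signals, tree = tree, out_dir = out_dir,
         master = master, states = states, colors = colors,
         cell_order = cell_order, normalization = normalization,
         exclusion_fraction = exclusion_fraction, fdr_alpha = fdr_alpha,
         manual_threshold = manual_threshold, feature_mode = feature_mode,
         null_posterior_cutoff = null_posterior_cutoff, ridge = ridge,
         k_range = k_range, include_null = include_null, plots = plots,
         seed = as.integer(seed)),
    class = "run_config"
  )
}

write_tsv <- function(df, path) {
  data.table::fwrite(df, path, sep = "\t")
  path
}

#' Run the full clustering pipeline
#'
#' Executes: read inputs, build/accept master list, binarize, group into
#' Index-Sets, negative-binomial abundance filter, QDA rescue, finalize
#' (abundant + null ISs), Meta-IS merge with AIC, optional state annotation,
#' optional figures. All tabular outputs are TSVs under `config$out_dir`; a
#' `manifest.json` lists every artifact with its md5 checksum plus
#' stage-level counts.
#'
#' @param config A `run_config`.
#' @return Invisible list with the in-memory objects (`master`, `bm`,
#'   `signal`, `catalog`, `final`, `meta`, `state_matrix`, `manifest`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  tree <- stage("tree", {
    if (inherits(config$tree, "cell_tree")) {
      if (!is.null(config$cell_order))
        cell_tree(config$tree$edges, order = config$cell_order)
      else config$tree
    } else {
      read_cell_tree(config$tree, order = config$cell_order)
    }
  })
  cells <- tree$leaf_order
  peaks <- stage("peaks", read_peak_beds(config$peaks))
  master <- stage("master", {
    if (is.null(config$master)) build_master_list(peaks) else {
      m <- read_peak_bed(config$master)
      S4Vectors::mcols(m)$id <- seq_along(m) - 1L
      m
    }
  })
  sig_raw <- stage("signal", read_signal_matrix(config$signals, master,
                                                cells = cells))
  bm <- stage("binarize", binarize(master, peaks, tree))
  sig <- stage("normalize",
               normalize_signal(sig_raw, config$normalization, bm = bm))
  catalog <- stage("group", group_into_index_sets(bm, signal = sig))
  catalog <- stage("filter", filter_index_sets(
    catalog, exclusion_fraction = config$exclusion_fraction,
    fdr_alpha = config$fdr_alpha,
    manual_threshold = config$manual_threshold))
  features <- if (config$feature_mode == "signal") sig else bm * 1.0
  model <- stage("rescue", fit_qda(features, catalog, ridge = config$ridge))
  ff <- filtered_features(catalog, features)
  res <- stage("rescue", qda_rescue(model, ff,
                                    config$null_posterior_cutoff))
  final <- stage("finalize", finalize_index_sets(catalog, model, res,
                                                 signal = sig))
  meta <- stage("meta", merge_into_meta(final, k_range = config$k_range,
                                        include_null = config$include_null))

  state_matrix <- NULL
  rep_states <- NULL
  colors <- NULL
  if (!is.null(config$states)) {
    state_tracks <- stage("states", read_state_beds(config$states))
    colors <- stage("states", read_color_table(config$colors))
    state_matrix <- stage("states",
                          annotate_states(master, state_tracks,
                                          cells = cells))
    rep_states <- stage("states", cluster_representative_states(
      state_matrix, final$members, colors, cluster_ids = final$index))
  }

  ## ---- tabular outputs -------------------------------------------------
  files <- character(0)
  asg <- catalog_assignments(final, master)
  rescue_tab <- attr(final, "rescue")
  asg$original_index <- asg$index
  if (!is.null(rescue_tab) && nrow(rescue_tab) > 0L) {
    m <- match(asg$ccre_id + 1L, rescue_tab$row)
    hit <- !is.na(m)
    asg$original_index[hit] <- rescue_tab$original_index[m[hit]]
    asg$max_posterior <- NA_real_
    asg$max_posterior[hit] <- rescue_tab$max_posterior[m[hit]]
  } else {
    asg$max_posterior <- NA_real_
  }
  names(asg)[names(asg) == "index"] <- "final_index"
  asg <- asg[, c("ccre_id", "chrom", "start", "end", "original_index",
                 "final_index", "is_status", "max_posterior")]
  files["ccre_catalog"] <- write_tsv(
    asg, file.path(config$out_dir, "ccre_catalog.tsv"))

  is_tab <- data.frame(index = final$index, status = final$status,
                       size = final$size, stringsAsFactors = FALSE)
  if (!is.null(final$mean_signal)) {
    is_tab <- cbind(is_tab, as.data.frame(final$mean_signal,
                                          row.names = NULL))
  }
  files["is_catalog"] <- write_tsv(
    is_tab, file.path(config$out_dir, "is_catalog.tsv"))

  meta_map <- data.frame(is_index = final$index[meta$which_is],
                         meta_id = meta$meta_id)
  files["meta_map"] <- write_tsv(
    meta_map, file.path(config$out_dir, "meta_map.tsv"))
  meta_tab <- data.frame(meta_id = seq_len(meta$K), size = meta$size)
  if (!is.null(meta$mean_signal)) {
    meta_tab <- cbind(meta_tab, as.data.frame(meta$mean_signal,
                                              row.names = NULL))
  }
  files["meta_catalog"] <- write_tsv(
    meta_tab, file.path(config$out_dir, "meta_catalog.tsv"))
  aic_path <- file.path(config$out_dir, "aic.json")
  jsonlite::write_json(attr(meta, "aic"), aic_path, digits = NA)
  files["aic"] <- aic_path

  if (!is.null(state_matrix)) {
    st_long <- data.frame(
      ccre_id = rep(seq_len(nrow(state_matrix)) - 1L, ncol(state_matrix)),
      cell_type = rep(colnames(state_matrix), each = nrow(state_matrix)),
      state = as.vector(state_matrix), stringsAsFactors = FALSE)
    files["ccre_states"] <- write_tsv(
      st_long, file.path(config$out_dir, "ccre_states.tsv"))
    files["representative_states"] <- write_tsv(
      rep_states, file.path(config$out_dir, "representative_states.tsv"))
  }

  files["binary_matrix"] <- write_tsv(
    as.data.frame(bm), file.path(config$out_dir, "binary_matrix.tsv"))
  files["signal_matrix"] <- write_tsv(
    as.data.frame(sig), file.path(config$out_dir, "signal_matrix.tsv"))

  if (isTRUE(config$plots)) {
    map <- sort_for_map(final, bm)
    files["binary_map"] <- plot_binary_map(
      map, file.path(config$out_dir, "binary_map.pdf"))
    files["mean_signal_heatmap"] <- plot_mean_signal_heatmap(
      final$mean_signal[final$size > 0L, , drop = FALSE],
      file.path(config$out_dir, "is_mean_signal.pdf"))
  }

  thr <- attr(catalog, "threshold")
  counts <- list(
    n_ccres = nrow(bm),
    n_dropped_all_zero = length(catalog$dropped),
    n_initial_is = length(catalog$index),
    n_abundant_is = sum(catalog$status == "abundant"),
    threshold_size = thr$threshold_size,
    n_rescued = if (is.null(rescue_tab)) 0L else
      sum(rescue_tab$final_index != "null"),
    null_size = final$size[final$status == "null"],
    n_final_is = length(final$index),
    K_meta = meta$K
  )
  manifest <- list(
    seed = config$seed,
    normalization = config$normalization,
    feature_mode = config$feature_mode,
    counts = counts,
    files = lapply(stats::setNames(as.list(files), names(files)), function(f) {
      list(path = f, md5 = unname(tools::md5sum(f)))
    })
  )
  manifest_path <- file.path(config$out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA)
  invisible(list(master = master, bm = bm, signal = sig, catalog = catalog,
                 model = model, final = final, meta = meta,
                 state_matrix = state_matrix, tree = tree,
                 manifest = manifest, files = files))
}
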