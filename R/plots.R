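#' Plot the sorted binary cluster map
#'
#' Black = presence (1), white = absence (0); rows are cCREs in sorted-map
#' order (top to bottom), columns are cell types in bit order.
#'
#' @param map Sorted 0/1 matrix from [sort_for_map()] (or any 0/1 matrix).
#' @param file Output path (`.png` or `.pdf`); NULL plots to the active
#'   device.
#' @param main Plot title.
#' @return `file` (or NULL), invisibly.
#' @export
plot_binary_map <- function(map, file = NULL, main = "binary cCRE map") {
  stopifnot(is.matrix(map))
  if (nrow(map) == 0L) stop("empty map: nothing to plot", call. = FALSE)
  if (!is.null(file)) open_device(file, width = 5, height = 7)
  on.exit(if (!is.null(file)) grDevices::dev.off(), add = TRUE)
  graphics::image(
    x = seq_len(ncol(map)), y = seq_len(nrow(map)),
    z = t(map[rev(seq_len(nrow(map))), , drop = FALSE]),
    col = c("white", "black"), zlim = c(0, 1),
    axes = FALSE, xlab = "", ylab = "cCREs", main = main, useRaster = TRUE)
  graphics::axis(1L, at = seq_len(ncol(map)), labels = colnames(map),
                 las = 2, cex.axis = 0.7, tick = FALSE)
  graphics::box()
  invisible(file)
}

open_device <- function(file, width, height) {
  if (grepl("\\.png$", file, ignore.case = TRUE)) {
    grDevices::png(file, width = width * 100, height = height * 100)
  } else if (grepl("\\.svg$", file, ignore.case = TRUE)) {
    grDevices::svg(file, width = width, height = height)
  } else {
    grDevices::pdf(file, width = width, height = height)
  }
}

#' Mean-signal heatmap of clusters
#'
#' @param mean_signal Cluster x cell-type matrix.
#' @param file Output path or NULL.
#' @param main Title.
#' @return `file`, invisibly.
#' @export
plot_mean_signal_heatmap <- function(mean_signal, file = NULL,
                                     main = "cluster mean signal") {
  stopifnot(is.matrix(mean_signal))
  # quantile-clipped scale so outliers do not wash out patterns
  lims <- stats::quantile(mean_signal, c(0.01, 0.99), na.rm = TRUE)
  z <- pmin(pmax(mean_signal, lims[1L]), lims[2L])
  if (!is.null(file)) open_device(file, width = 6, height = 6)
  on.exit(if (!is.null(file)) grDevices::dev.off(), add = TRUE)
  pal <- grDevices::colorRampPalette(c("white", "orange", "red"))(64)
  graphics::image(x = seq_len(ncol(z)), y = seq_len(nrow(z)),
                  z = t(z[rev(seq_len(nrow(z))), , drop = FALSE]),
                  col = pal, axes = FALSE, xlab = "", ylab = "cluster",
                  main = main)
  graphics::axis(1L, at = seq_len(ncol(z)), labels = colnames(z), las = 2,
                 cex.axis = 0.7, tick = FALSE)
  graphics::box()
  invisible(file)
}

#' Layered top-down layout of a cell tree
#'
#' @param tree A `cell_tree`.
#' @return data.frame `node`, `x`, `y` (root at top) plus the edge table.
#' @export
layout_cell_tree <- function(tree) {
  depth <- stats::setNames(rep(0L, length(tree$nodes)), tree$nodes)
  children <- split(tree$edges$child,
                    factor(tree$edges$parent, levels = tree$nodes))
  xpos <- stats::setNames(rep(NA_real_, length(tree$nodes)), tree$nodes)
  counter <- 0
  assign_x <- function(node, d) {
    depth[node] <<- d
    kids <- children[[node]]
    if (length(kids) == 0L) {
      counter <<- counter + 1
      xpos[node] <<- counter
    } else {
      for (k in kids) assign_x(k, d + 1L)
      xpos[node] <<- mean(xpos[kids])
    }
  }
  for (r in tree$roots) assign_x(r, 0L)
  data.frame(node = tree$nodes, x = xpos[tree$nodes],
             y = -depth[tree$nodes], stringsAsFactors = FALSE)
}

draw_colored_tree <- function(tree, node_colors, main) {
  lay <- layout_cell_tree(tree)
  rownames(lay) <- lay$node
  graphics::plot(NA, xlim = range(lay$x) + c(-0.5, 0.5),
                 ylim = range(lay$y) + c(-0.5, 0.5),
                 axes = FALSE, xlab = "", ylab = "", main = main)
  for (i in seq_len(nrow(tree$edges))) {
    p <- tree$edges$parent[i]; ch <- tree$edges$child[i]
    graphics::segments(lay[p, "x"], lay[p, "y"], lay[ch, "x"], lay[ch, "y"],
                       col = "grey50")
  }
  graphics::points(lay$x, lay$y, pch = 21, cex = 3,
                   bg = node_colors[lay$node])
  graphics::text(lay$x, lay$y + 0.35, lay$node, cex = 0.7)
}

violin_panel <- function(values_by_cell, main) {
  cells <- names(values_by_cell)
  graphics::plot(NA, xlim = c(0.5, length(cells) + 0.5),
                 ylim = range(unlist(values_by_cell), finite = TRUE),
                 xlab = "", ylab = "signal", main = main, xaxt = "n")
  graphics::axis(1L, at = seq_along(cells), labels = cells, las = 2,
                 cex.axis = 0.7)
  for (j in seq_along(cells)) {
    v <- values_by_cell[[j]]
    if (length(unique(v)) < 2L) {
      graphics::points(j, v[1L], pch = 16)
      next
    }
    dn <- stats::density(v)
    w <- 0.4 * dn$y / max(dn$y)
    graphics::polygon(c(j - w, rev(j + w)), c(dn$x, rev(dn$x)),
                      col = "grey80", border = "grey40")
  }
}

state_bar_panel <- function(state_props, colors, main) {
  # state_props: states x cell types proportion matrix
  cols <- colors$hex[match(rownames(state_props), colors$state)]
  graphics::barplot(state_props, col = cols, las = 2, cex.names = 0.7,
                    main = main, border = NA,
                    legend.text = rownames(state_props),
                    args.legend = list(x = "topright", cex = 0.6, bty = "n"))
}

#' Composite per-cluster panel
#'
#' Four panels for one cluster: the cell tree colored by mean signal, the
#' tree colored by representative epigenetic state, per-cell-type signal
#' violins, and stacked per-cell-type state-proportion bars.
#'
#' @param members Integer cCRE row ids of the cluster.
#' @param signal Full signal matrix.
#' @param state_matrix Dominant-state matrix from [annotate_states()] (NULL
#'   skips the state panels).
#' @param tree A `cell_tree`.
#' @param colors Color table (required with `state_matrix`).
#' @param file Output path or NULL.
#' @param main Title prefix.
#' @return `file`, invisibly.
#' @export
plot_cluster_panel <- function(members, signal, state_matrix, tree, colors,
                               file = NULL, main = "cluster") {
  if (length(members) == 0L) stop("empty cluster: nothing to plot",
                                  call. = FALSE)
  if (!is.null(state_matrix) && is.null(colors)) {
    stop("state panels need a color table", call. = FALSE)
  }
  cells <- tree$leaf_order
  if (!is.null(file)) open_device(file, width = 9, height = 7)
  on.exit(if (!is.null(file)) grDevices::dev.off(), add = TRUE)
  old <- graphics::par(mfrow = c(2, 2), mar = c(4, 3, 2, 1))
  on.exit(graphics::par(old), add = TRUE)

  mu <- colMeans(signal[members, cells, drop = FALSE])
  rel <- (mu - min(mu)) / max(max(mu) - min(mu), .Machine$double.eps)
  pal <- grDevices::colorRampPalette(c("white", "red"))(101)
  draw_colored_tree(tree, stats::setNames(pal[round(rel * 100) + 1L], cells),
                    paste(main, "- mean signal"))

  if (!is.null(state_matrix)) {
    node_cols <- vapply(cells, function(ct) {
      representative_states(state_matrix[members, ct], colors)$hex
    }, character(1))
    draw_colored_tree(tree, node_cols, paste(main, "- representative state"))
  } else {
    graphics::plot.new()
  }

  violin_panel(lapply(cells, function(ct) signal[members, ct]) |>
                 stats::setNames(cells), paste(main, "- signal"))

  if (!is.null(state_matrix)) {
    props <- vapply(cells, function(ct) {
      tab <- table(factor(state_matrix[members, ct], levels = colors$state))
      as.numeric(tab) / length(members)
    }, numeric(nrow(colors)))
    props <- matrix(props, nrow = nrow(colors),
                    dimnames = list(colors$state, cells))
    state_bar_panel(props, colors, paste(main, "- state proportions"))
  } else {
    graphics::plot.new()
  }
  invisible(file)
}
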