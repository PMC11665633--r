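# Publication plots: effect-size barplot, per-feature abundance histogram,
# and taxonomic cladogram. Color-blind-safe Okabe-Ito pair by default, with
# neutral gray for background cladogram nodes. Each function returns its
# plot object (with the underlying layout data attached) invisibly, so tests
# can assert on structure rather than pixels, and writes exactly one file
# when `out_path` is given.

default_palette <- function() c("#0072B2", "#E69F00")  # blue / orange
neutral_color <- function() "#999999"

# Save a ggplot to png/pdf/svg chosen by extension, via base devices (no
# svglite dependency).
save_plot_file <- function(plot, path, width = 7, height = 5) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png = grDevices::png(path, width = width, height = height,
                         units = "in", res = 150),
    pdf = grDevices::pdf(path, width = width, height = height),
    svg = grDevices::svg(path, width = width, height = height),
    stop("unsupported image extension '", ext, "' (use png, pdf, or svg)")
  )
  on.exit(grDevices::dev.off(), add = TRUE)
  print(plot)
  invisible(path)
}

#' Barplot of marker LDA scores
#'
#' One horizontal bar per selected feature, length equal to its signed LDA
#' score, ordered by score; bar color encodes the class in which the feature
#' is enriched (negative scores: reference class).
#'
#' @param result A nonempty `marker_result` (or data frame with `features`
#'   and `scores` columns).
#' @param out_path Optional output file (`.png`, `.pdf`, or `.svg`).
#' @param palette Two colors, reference class first; default Okabe-Ito
#'   blue/orange.
#' @return The ggplot object, invisibly.
#' @export
plot_bar <- function(result, out_path = NULL, palette = NULL) {
  stopifnot(is.data.frame(result),
            all(c("features", "scores") %in% colnames(result)))
  if (nrow(result) == 0) stop("empty marker result: nothing to plot")
  if (is.null(palette)) palette <- default_palette()
  lev <- attr(result, "class_levels")
  if (is.null(lev)) lev <- c("reference class", "non-reference class")
  df <- data.frame(features = result$features, scores = result$scores,
                   enriched = factor(ifelse(result$scores >= 0, lev[2], lev[1]),
                                     levels = lev),
                   stringsAsFactors = FALSE)
  df$features <- factor(df$features, levels = df$features[order(df$scores)])
  g <- ggplot2::ggplot(df, ggplot2::aes(x = .data$scores, y = .data$features,
                                        fill = .data$enriched)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(values = stats::setNames(palette, lev),
                               drop = FALSE, name = "enriched in") +
    ggplot2::labs(x = "LDA score (log10)", y = NULL) +
    ggplot2::theme_minimal()
  if (!is.null(out_path)) save_plot_file(g, out_path)
  invisible(g)
}

#' Histogram of a feature's relative abundance by class
#'
#' Abundances are rendered as per-sample proportions in (0, 1) regardless of
#' the input scale, one panel per class; subclasses, when present, are
#' color-coded. A solid vertical line marks each panel's mean and a dashed
#' line its median.
#'
#' @param table An [abundance_table].
#' @param groups A [sample_groups].
#' @param feature_id The feature to plot.
#' @param out_path Optional output file (`.png`, `.pdf`, or `.svg`).
#' @param bins Histogram bin count; default 30.
#' @param palette Colors for the subclass legend; defaults to an Okabe-Ito
#'   derived set.
#' @return The ggplot object, invisibly.
#' @export
plot_feature_histogram <- function(table, groups, feature_id, out_path = NULL,
                                   bins = 30, palette = NULL) {
  v <- validate_inputs(table, groups)
  if (!feature_id %in% rownames(v$table)) {
    stop("unknown feature id: ", feature_id)
  }
  prop <- sweep(unclass(v$table), 2, colSums(v$table), "/")  # back to (0,1)
  df <- data.frame(abundance = prop[feature_id, ],
                   class = v$groups$class_labels)
  has_sub <- !is.null(v$groups$subclass_labels)
  if (has_sub) df$subclass <- v$groups$subclass_labels
  stat_df <- do.call(rbind, lapply(split(df$abundance, df$class), function(x) {
    data.frame(mean = mean(x), median = stats::median(x))
  }))
  stat_df$class <- factor(rownames(stat_df), levels = levels(df$class))
  aes_fill <- if (has_sub) ggplot2::aes(x = .data$abundance,
                                        fill = .data$subclass)
              else ggplot2::aes(x = .data$abundance)
  g <- ggplot2::ggplot(df, aes_fill) +
    ggplot2::geom_histogram(bins = bins, position = "identity", alpha = 0.7) +
    ggplot2::geom_vline(data = stat_df,
                        ggplot2::aes(xintercept = .data$mean),
                        linetype = "solid") +
    ggplot2::geom_vline(data = stat_df,
                        ggplot2::aes(xintercept = .data$median),
                        linetype = "dashed") +
    ggplot2::facet_wrap(~class, ncol = 1) +
    ggplot2::labs(x = "relative abundance", y = "samples",
                  title = feature_id) +
    ggplot2::theme_minimal()
  if (has_sub) {
    pal <- if (is.null(palette)) {
      grDevices::colorRampPalette(c("#0072B2", "#E69F00", "#009E73",
                                    "#CC79A7"))(nlevels(df$subclass))
    } else palette
    g <- g + ggplot2::scale_fill_manual(values = pal)
  }
  if (!is.null(out_path)) save_plot_file(g, out_path)
  invisible(g)
}

#' Build a lineage tree from pipe-delimited feature ids
#'
#' Each feature id is parsed as a root-to-leaf lineage; shared prefixes share
#' nodes, so the result is a single rooted tree (a virtual root joins
#' top-level ranks).
#'
#' @param feature_ids Character vector of lineage strings.
#' @param separator Rank separator; default `"|"`.
#' @return A data frame of nodes with columns `id` (full path), `parent`
#'   (path of parent, `NA` for the root), `label` (last rank name), `depth`
#'   (root = 0), and `n_leaves` (leaf count of the subtree), with class
#'   `lineage_tree`.
#' @export
build_lineage_tree <- function(feature_ids, separator = "|") {
  paths <- lapply(feature_ids, parse_lineage, separator = separator)
  ids <- "<root>"; parents <- NA_character_; labels <- "<root>"; depths <- 0L
  seen <- new.env(parent = emptyenv())
  assign("<root>", TRUE, envir = seen)
  for (pth in paths) {
    acc <- "<root>"
    for (d in seq_along(pth)) {
      id <- paste(pth[seq_len(d)], collapse = separator)
      if (!exists(id, envir = seen, inherits = FALSE)) {
        assign(id, TRUE, envir = seen)
        ids <- c(ids, id); parents <- c(parents, acc)
        labels <- c(labels, pth[d]); depths <- c(depths, d)
      }
      acc <- id
    }
  }
  nodes <- data.frame(id = ids, parent = parents, label = labels,
                      depth = depths, stringsAsFactors = FALSE)
  is_parent <- nodes$id %in% nodes$parent
  leaf_count <- integer(nrow(nodes))
  for (i in order(nodes$depth, decreasing = TRUE)) {
    if (!is_parent[i]) {
      leaf_count[i] <- 1L
    } else {
      leaf_count[i] <- sum(leaf_count[which(nodes$parent == nodes$id[i])])
    }
  }
  nodes$n_leaves <- leaf_count
  class(nodes) <- c("lineage_tree", "data.frame")
  nodes
}

# Equal-angle radial layout: each node's angular wedge is split among its
# children proportionally to subtree leaf counts; radius is depth scaled to
# [0, 1].
layout_radial <- function(nodes) {
  nodes$angle <- NA_real_
  kids <- split(seq_len(nrow(nodes)), factor(nodes$parent, levels = nodes$id))
  assign_wedge <- function(i, a0, a1) {
    nodes$angle[i] <<- (a0 + a1) / 2
    ch <- kids[[nodes$id[i]]]
    if (is.null(ch) || length(ch) == 0) return(invisible())
    w <- nodes$n_leaves[ch] / sum(nodes$n_leaves[ch])
    edges <- a0 + c(0, cumsum(w)) * (a1 - a0)
    for (k in seq_along(ch)) assign_wedge(ch[k], edges[k], edges[k + 1])
  }
  assign_wedge(which(nodes$depth == 0L), 0, 2 * pi)
  maxd <- max(nodes$depth)
  nodes$radius <- if (maxd > 0) nodes$depth / maxd else 0
  nodes$x <- nodes$radius * cos(nodes$angle)
  nodes$y <- nodes$radius * sin(nodes$angle)
  nodes
}

#' Cladogram of differentially abundant taxa
#'
#' Draws the full lineage tree of `all_feature_ids` as a neutral radial
#' background, then colors the nodes matching significant features by their
#' enriched class and sizes them monotonically in absolute LDA score
#' (linear by default; set `size_log = TRUE` for `log10(1 + |score|)`
#' scaling).
#'
#' @param result A `marker_result`; may be empty (background-only cladogram).
#' @param all_feature_ids All feature lineages defining the background
#'   topology.
#' @param out_path Optional output file (`.png`, `.pdf`, or `.svg`).
#' @param separator Lineage separator; default `"|"`.
#' @param label `"significant"` (default), `"all"`, or `"none"`: which node
#'   labels to draw.
#' @param size_range Point-size range mapped from absolute score.
#' @param size_log Use log-scaled node sizes; default `FALSE`.
#' @param palette Two colors, reference class first.
#' @return Invisibly, a list of class `cladogram_plot` with elements `plot`
#'   (ggplot) and `nodes` (layout data frame with `angle`, `radius`, `x`,
#'   `y`, `score`, `enriched`, `size`).
#' @export
plot_cladogram <- function(result, all_feature_ids, out_path = NULL,
                           separator = "|",
                           label = c("significant", "all", "none"),
                           size_range = c(1.5, 6), size_log = FALSE,
                           palette = NULL) {
  label <- match.arg(label)
  stopifnot(is.data.frame(result),
            all(c("features", "scores") %in% colnames(result)))
  if (is.null(palette)) palette <- default_palette()
  lev <- attr(result, "class_levels")
  if (is.null(lev)) lev <- c("reference class", "non-reference class")
  nodes <- layout_radial(build_lineage_tree(all_feature_ids, separator))
  idx <- match(nodes$id, result$features)
  nodes$score <- result$scores[idx]
  nodes$enriched <- ifelse(is.na(nodes$score), NA,
                           ifelse(nodes$score >= 0, lev[2], lev[1]))
  mag <- abs(nodes$score)
  if (size_log) mag <- log10(1 + mag)
  mx <- suppressWarnings(max(mag, na.rm = TRUE))
  if (!is.finite(mx) || mx == 0) mx <- 1
  nodes$size <- size_range[1] + (size_range[2] - size_range[1]) * mag / mx

  seg <- merge(nodes, nodes[, c("id", "x", "y")],
               by.x = "parent", by.y = "id", suffixes = c("", "_p"))
  sig <- nodes[!is.na(nodes$score), , drop = FALSE]
  g <- ggplot2::ggplot() +
    ggplot2::geom_segment(data = seg,
                          ggplot2::aes(x = .data$x_p, y = .data$y_p,
                                       xend = .data$x, yend = .data$y),
                          color = neutral_color(), linewidth = 0.3) +
    ggplot2::geom_point(data = nodes[is.na(nodes$score), , drop = FALSE],
                        ggplot2::aes(x = .data$x, y = .data$y),
                        color = neutral_color(), size = 0.8) +
    ggplot2::coord_equal() +
    ggplot2::theme_void()
  if (nrow(sig) > 0) {
    g <- g + ggplot2::geom_point(
      data = sig,
      ggplot2::aes(x = .data$x, y = .data$y, color = .data$enriched),
      size = sig$size) +
      ggplot2::scale_color_manual(
        values = stats::setNames(palette, lev), name = "enriched in")
  }
  lab_df <- switch(label, none = nodes[0, , drop = FALSE],
                   significant = sig, all = nodes[nodes$depth > 0, ,
                                                  drop = FALSE])
  if (nrow(lab_df) > 0) {
    g <- g + ggplot2::geom_text(
      data = lab_df,
      ggplot2::aes(x = .data$x, y = .data$y, label = .data$label),
      size = 2.5, vjust = -1)
  }
  out <- structure(list(plot = g, nodes = nodes), class = "cladogram_plot")
  if (!is.null(out_path)) save_plot_file(g, out_path)
  invisible(out)
}
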