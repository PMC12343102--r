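# Visualizations mirroring the standard panels of a ratiometric cutoff
# analysis: replicate-correlation scatter grid, per-rank TPR/FPR/TPR-FPR
# curves, ROC with the cutoff marked, and ORA bar charts. Plot functions
# only draw already-computed result objects; no statistics are computed
# here.

curve_palette <- c(TPR = "#1f77b4", FPR = "#ff7f0e", `TPR-FPR` = "#2ca02c")

#' Plot per-rank TPR, FPR, and TPR-FPR curves
#'
#' Three series against ranking position (TPR blue, FPR orange, TPR-FPR
#' green), with a vertical line at the cutoff rank.
#'
#' @param curve An `enrichment_curve` from [compute_curve()].
#' @param colors Named vector overriding the series colors.
#' @return A ggplot object.
#' @export
plot_enrichment_curves <- function(curve, colors = curve_palette) {
  stopifnot(inherits(curve, "enrichment_curve"))
  n <- length(curve$tpr)
  df <- data.frame(rank = rep(seq_len(n), 3L),
                   value = c(curve$tpr, curve$fpr, curve$diff),
                   series = factor(rep(c("TPR", "FPR", "TPR-FPR"), each = n),
                                   levels = c("TPR", "FPR", "TPR-FPR")))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$rank, y = .data$value,
                                   color = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = curve$cutoff_rank, linetype = "dashed",
                        color = "grey40") +
    ggplot2::scale_color_manual(values = colors) +
    ggplot2::labs(x = sprintf("%s ratio-based ranking", curve$column_name),
                  y = "rate", color = NULL,
                  title = sprintf("cutoff rank %d", curve$cutoff_rank)) +
    ggplot2::theme_classic()
}

#' Plot the ROC curve with AUC annotation and cutoff marker
#'
#' Step curve over (FPR, TPR), diagonal reference, `AUC = x.xx` annotation,
#' and a red dot at the cutoff position.
#'
#' @param curve An `enrichment_curve`.
#' @return A ggplot object.
#' @export
plot_roc <- function(curve) {
  stopifnot(inherits(curve, "enrichment_curve"))
  k <- curve$cutoff_rank
  cut_pt <- data.frame(fpr = curve$fpr[k], tpr = curve$tpr[k])
  ggplot2::ggplot(curve$roc_points, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted",
                         color = "grey60") +
    ggplot2::geom_path(color = "#1f77b4") +
    ggplot2::geom_point(data = cut_pt, color = "red", size = 2) +
    ggplot2::annotate("text", x = 0.65, y = 0.15,
                      label = sprintf("AUC = %.2f", curve$auc)) +
    ggplot2::labs(x = "False positive rate", y = "True positive rate",
                  title = curve$column_name) +
    ggplot2::coord_equal() +
    ggplot2::theme_classic()
}

#' Plot a pairwise correlation scatter grid
#'
#' Scatter of log2 ratios for every unordered column pair, faceted, with
#' the correlation coefficient annotated per panel.
#'
#' @param table A [ratio_table()].
#' @param corr A `correlation_matrix` from [pairwise_correlation()];
#'   computed with defaults if omitted.
#' @return A ggplot object.
#' @export
plot_correlation_grid <- function(table, corr = NULL) {
  stopifnot(inherits(table, "ratio_table"))
  if (is.null(corr)) corr <- pairwise_correlation(table)
  cols <- corr$column_names
  pieces <- list()
  for (i in seq_len(length(cols) - 1L)) {
    for (j in seq.int(i + 1L, length(cols))) {
      ok <- !is.na(table[[cols[i]]]) & !is.na(table[[cols[j]]])
      pieces[[length(pieces) + 1L]] <- data.frame(
        pair = sprintf("%s vs %s (r = %.2f)", cols[j], cols[i],
                       corr$coefficients[i, j]),
        x = log2(table[[cols[i]]][ok]), y = log2(table[[cols[j]]][ok]))
    }
  }
  df <- do.call(rbind, pieces)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point(size = 0.4, alpha = 0.4, color = "#1f77b4") +
    ggplot2::facet_wrap(~pair) +
    ggplot2::labs(x = "log2 ratio", y = "log2 ratio") +
    ggplot2::theme_bw()
}

#' Plot over-representation results as bars
#'
#' Terms sorted by significance, bar length = fold enrichment, fill encodes
#' the FDR-adjusted value.
#'
#' @param result An `ora_result` from [ora()].
#' @param top Number of top terms to show.
#' @return A ggplot object.
#' @export
plot_ora_bars <- function(result, top = 15L) {
  stopifnot(inherits(result, "ora_result"))
  df <- utils::head(as.data.frame(result), top)
  df$term <- factor(df$term_name, levels = rev(df$term_name))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$fold_enrichment, y = .data$term,
                                   fill = .data$fdr)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_gradient(low = "#d62728", high = "#aec7e8") +
    ggplot2::labs(x = "Fold enrichment", y = NULL, fill = "FDR") +
    ggplot2::theme_classic()
}

#' Plot rendering specification
#'
#' @param kind One of `"correlation_grid"`, `"enrichment_curves"`, `"roc"`,
#'   `"ora_bars"`.
#' @param source The already-computed result object the plot draws from
#'   (ratio table, enrichment curve, or ORA result).
#' @param path Output image path.
#' @param format `"png"`, `"svg"`, or `"pdf"`; default inferred from `path`.
#' @param dpi Raster resolution.
#' @param width,height Plot size in inches.
#' @return Object of class `plot_spec`.
#' @export
plot_spec <- function(kind = c("correlation_grid", "enrichment_curves", "roc",
                               "ora_bars"),
                      source, path, format = NULL, dpi = 150,
                      width = 6, height = 4.5) {
  kind <- match.arg(kind)
  if (is.null(format)) {
    format <- tolower(tools::file_ext(path))
    if (!format %in% c("png", "svg", "pdf")) format <- "png"
  }
  structure(list(kind = kind, source = source, path = path, format = format,
                 dpi = dpi, width = width, height = height),
            class = "plot_spec")
}

#' Render a plot specification to an image file
#'
#' @param spec A [plot_spec()].
#' @return The written path, invisibly.
#' @export
render_plot <- function(spec) {
  stopifnot(inherits(spec, "plot_spec"))
  p <- switch(spec$kind,
              correlation_grid = plot_correlation_grid(spec$source),
              enrichment_curves = plot_enrichment_curves(spec$source),
              roc = plot_roc(spec$source),
              ora_bars = plot_ora_bars(spec$source))
  device <- switch(spec$format,
                   svg = grDevices::svg,  # avoid optional svglite dependency
                   spec$format)
  ggplot2::ggsave(spec$path, plot = p, device = device, dpi = spec$dpi,
                  width = spec$width, height = spec$height)
  if (!file.exists(spec$path) || file.size(spec$path) == 0) {
    stop(sprintf("failed to write plot: %s", spec$path), call. = FALSE)
  }
  invisible(spec$path)
}
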