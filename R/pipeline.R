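# Pipeline driver: one call runs replicate QC, per-column cutoff analysis,
# intersection, top-N tables, optional ORA, plots, and result writing, and
# echoes the resolved configuration next to the outputs so every run is
# reproducible from its artifacts.

#' Build a pipeline run configuration
#'
#' @param input Path to the ratio table (CSV/TSV).
#' @param tp,fp Paths to the TP and FP reference lists.
#' @param outdir Output directory.
#' @param accession_column Accession column name or 1-based index.
#' @param ratio_cols Ratio columns to analyze; `NULL` (default) means all
#'   numeric non-accession columns.
#' @param delimiter Optional delimiter override for the input table.
#' @param top_n Rows in the per-column top-enriched tables.
#' @param tie_policy Cutoff tie-break, see [find_cutoff()].
#' @param missing_policy What a missing cell means for that column's cutoff:
#'   `"exclude"` (default) means a protein not quantified in a column cannot
#'   pass that column's cutoff and so drops out of the final intersection;
#'   `"pass"` treats it as passing (anti-conservative, provided for
#'   sensitivity analysis).
#' @param correlation_method QC estimator, see [pairwise_correlation()].
#' @param annotations Optional named list of annotation files (TSV/GMT) for
#'   ORA; names become namespaces.
#' @param background Optional path to a user background accession list for
#'   ORA; default background is all detected proteins.
#' @param plots Render figures (PNG) into `outdir`.
#' @param auc_warn AUC warning threshold: any column below it is flagged in
#'   the run summary as questionable enrichment (a warning tier, never an
#'   abort — interpretation guidance, not a gate).
#' @param policy An [accession_policy()].
#' @return Object of class `run_config` (a fully serializable list).
#' @export
run_config <- function(input, tp, fp, outdir,
                       accession_column = 1L, ratio_cols = NULL,
                       delimiter = NULL, top_n = 100L,
                       tie_policy = "last",
                       missing_policy = "exclude",
                       correlation_method = "pearson_log2",
                       annotations = NULL, background = NULL,
                       plots = TRUE, auc_warn = 0.7,
                       policy = accession_policy()) {
  structure(list(input = input, tp = tp, fp = fp, outdir = outdir,
                 accession_column = accession_column, ratio_cols = ratio_cols,
                 delimiter = delimiter, top_n = as.integer(top_n),
                 tie_policy = match.arg(tie_policy, c("last", "first")),
                 missing_policy = match.arg(missing_policy, c("exclude", "pass")),
                 correlation_method = match.arg(correlation_method,
                                                c("pearson_log2", "spearman")),
                 annotations = annotations, background = background,
                 plots = isTRUE(plots), auc_warn = as.numeric(auc_warn),
                 policy = unclass(policy)),
            class = "run_config")
}

#' Load a run configuration from YAML, with overrides
#'
#' @param path YAML file whose keys mirror [run_config()] arguments.
#' @param ... Overrides applied on top of the file values.
#' @return A `run_config`.
#' @export
load_run_config <- function(path, ...) {
  vals <- yaml::read_yaml(path)
  overrides <- list(...)
  vals[names(overrides)] <- overrides
  do.call(run_config, vals)
}

#' Run the full contaminant-filtering pipeline
#'
#' Executes: read inputs, pairwise replicate correlation (if >= 2 ratio
#' columns), per-column ranking / TPR-FPR curve / cutoff, intersection
#' across columns, per-column top-N tables, optional ORA of the final
#' proteome against the detected background, figure rendering, and result
#' writing. The resolved configuration and a run summary (per-column AUC,
#' cutoff rank, retained counts, final proteome size, quality warnings) are
#' written as YAML into the output directory.
#'
#' @param config A [run_config()].
#' @return List with `curves`, `result`, `correlation`, `ora`, `summary`,
#'   and `manifest`, invisibly.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  policy <- do.call(accession_policy, config$policy)
  table <- read_ratio_table(config$input, delimiter = config$delimiter,
                            accession_column = config$accession_column,
                            policy = policy)
  ref <- read_reference(config$tp, config$fp, policy = policy)
  cols <- config$ratio_cols
  if (is.null(cols)) cols <- ratio_columns(table)
  missing_cols <- setdiff(cols, ratio_columns(table))
  if (length(missing_cols) > 0L) {
    stop(sprintf("requested ratio columns absent from table: %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)

  corr <- NULL
  if (length(cols) >= 2L) {
    corr <- pairwise_correlation(table, method = config$correlation_method)
  }

  curves <- lapply(cols, function(cn) {
    analyze_column(table, cn, ref, tie_policy = config$tie_policy)
  })
  names(curves) <- cols
  retained <- lapply(curves, function(cv) apply_cutoff(cv$ranked, cv$cutoff_rank))
  if (config$missing_policy == "pass") {
    for (cn in cols) {
      retained[[cn]] <- union(retained[[cn]],
                              table$accession[is.na(table[[cn]])])
    }
  }
  result <- intersect_columns(retained)
  top_tables <- lapply(curves, function(cv) top_enriched(cv$ranked, config$top_n))

  ora_results <- NULL
  if (!is.null(config$annotations) && length(result$final_proteome) > 0L) {
    background <- if (is.null(config$background)) {
      table$accession
    } else {
      read_accession_list(config$background, policy)
    }
    ora_results <- lapply(names(config$annotations), function(ns) {
      ann <- read_annotations(config$annotations[[ns]], namespace = ns,
                              policy = policy)
      ora(base::intersect(result$final_proteome, background), background, ann)
    })
    names(ora_results) <- names(config$annotations)
  }

  manifest <- write_results(config$outdir, result, curves, top_tables)
  if (!is.null(ora_results)) {
    manifest$ora <- list()
    for (ns in names(ora_results)) {
      tab <- as.data.frame(ora_results[[ns]])
      tab$fold_enrichment <- fmt_num(tab$fold_enrichment)
      tab$p <- fmt_num(tab$p)
      tab$fdr <- fmt_num(tab$fdr)
      p <- file.path(config$outdir, sprintf("ora_%s.tsv", sanitize_filename(ns)))
      utils::write.table(tab, p, sep = "\t", quote = FALSE, row.names = FALSE)
      manifest$ora[[ns]] <- p
    }
  }
  if (!is.null(corr)) {
    p <- file.path(config$outdir, "correlation.tsv")
    cm <- as.data.frame(corr$coefficients)
    cm <- cbind(column = rownames(corr$coefficients), cm)
    cm[-1] <- lapply(cm[-1], fmt_num)
    utils::write.table(cm, p, sep = "\t", quote = FALSE, row.names = FALSE)
    manifest$correlation <- p
  }

  if (config$plots) {
    manifest$plots <- list()
    if (!is.null(corr)) {
      p <- file.path(config$outdir, "correlation_grid.png")
      render_plot(plot_spec("correlation_grid", table, p))
      manifest$plots$correlation_grid <- p
    }
    for (cn in cols) {
      p1 <- file.path(config$outdir, sprintf("curves_%s.png", sanitize_filename(cn)))
      render_plot(plot_spec("enrichment_curves", curves[[cn]], p1))
      p2 <- file.path(config$outdir, sprintf("roc_%s.png", sanitize_filename(cn)))
      render_plot(plot_spec("roc", curves[[cn]], p2))
      manifest$plots[[paste0("curves_", cn)]] <- p1
      manifest$plots[[paste0("roc_", cn)]] <- p2
    }
    if (!is.null(ora_results)) {
      for (ns in names(ora_results)) {
        p <- file.path(config$outdir, sprintf("ora_%s.png", sanitize_filename(ns)))
        render_plot(plot_spec("ora_bars", ora_results[[ns]], p))
        manifest$plots[[paste0("ora_", ns)]] <- p
      }
    }
  }

  aucs <- vapply(curves, function(cv) cv$auc, numeric(1))
  warnings_out <- character(0)
  low <- aucs < config$auc_warn
  if (any(low)) {
    warnings_out <- sprintf(
      "column %s: AUC %.3f below %.2f - enrichment questionable (near 0.5 suggests random capture; consider optimizing labeling/enrichment)",
      names(aucs)[low], aucs[low], config$auc_warn)
    for (w in warnings_out) warning(w, call. = FALSE)
  }
  summary <- list(
    n_proteins = nrow(table),
    ratio_columns = as.list(stats::setNames(lapply(cols, function(cn) {
      cv <- curves[[cn]]
      list(auc = cv$auc, cutoff_rank = cv$cutoff_rank,
           n_tp = cv$n_tp, n_fp = cv$n_fp,
           n_retained = length(result$per_column_retained[[cn]]))
    }), cols)),
    final_proteome_size = length(result$final_proteome),
    warnings = as.list(warnings_out))
  yaml::write_yaml(summary, file.path(config$outdir, "summary.yaml"))
  yaml::write_yaml(unclass(config), file.path(config$outdir, "config.yaml"))
  manifest$summary <- file.path(config$outdir, "summary.yaml")
  manifest$config <- file.path(config$outdir, "config.yaml")

  invisible(list(curves = curves, result = result, correlation = corr,
                 ora = ora_results, summary = summary, manifest = manifest))
}
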