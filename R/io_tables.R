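# Input/output layer: delimited ratio tables, plain-text reference lists, and
# result tables. All downstream computation consumes the containers built here.

#' Construct a ratio table
#'
#' A ratio table keys per-protein labeled-to-control enrichment ratios by
#' UniProt accession: one row per protein, one numeric column per
#' labeled-to-control ratio (e.g. per TMT channel pair). Ratios are positive
#' fold enrichments; `NA` marks a missing cell (that protein is simply absent
#' from that column's ranking).
#'
#' @param accessions Character vector of unique, normalized accessions.
#' @param values Data frame (or list) of numeric ratio columns, one row per
#'   accession. Values must be finite and positive, or `NA`.
#'
#' @return An object of class `ratio_table`: a data frame whose first column
#'   is `accession` followed by the ratio columns.
#' @export
ratio_table <- function(accessions, values) {
  accessions <- as.character(accessions)
  values <- as.data.frame(values, optional = TRUE)
  if (ncol(values) < 1L) stop("at least one ratio column required", call. = FALSE)
  if (nrow(values) != length(accessions)) {
    stop("accessions and values disagree in length", call. = FALSE)
  }
  if (anyDuplicated(accessions)) stop("duplicate accessions", call. = FALSE)
  for (j in seq_along(values)) {
    v <- values[[j]]
    if (!is.numeric(v)) stop("ratio columns must be numeric", call. = FALSE)
    bad <- !is.na(v) & (!is.finite(v) | v <= 0)
    if (any(bad)) {
      stop(sprintf("column '%s' holds %d non-positive or non-finite ratios; flag them NA",
                   names(values)[j], sum(bad)), call. = FALSE)
    }
  }
  out <- cbind(data.frame(accession = accessions, stringsAsFactors = FALSE), values)
  class(out) <- c("ratio_table", "data.frame")
  out
}

#' @export
print.ratio_table <- function(x, ...) {
  cat(sprintf("ratio_table: %d proteins x %d ratio columns (%s)\n",
              nrow(x), ncol(x) - 1L,
              paste(ratio_columns(x), collapse = ", ")))
  print(utils::head(as.data.frame(x), 6L))
  if (nrow(x) > 6L) cat(sprintf("... %d more rows\n", nrow(x) - 6L))
  invisible(x)
}

#' Ratio column names of a ratio table
#' @param table A [ratio_table()].
#' @return Character vector of ratio column names (file order preserved).
#' @export
ratio_columns <- function(table) {
  stopifnot(inherits(table, "ratio_table"))
  setdiff(names(table), "accession")
}

infer_delimiter <- function(path, delimiter = NULL) {
  if (!is.null(delimiter)) return(delimiter)
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

#' Read a delimited protein quantification table
#'
#' Reads a CSV/TSV with a header row, one accession column, and numeric
#' labeled-to-control ratio columns. Accessions are normalized under `policy`;
#' duplicates after normalization keep the first occurrence (each drop is
#' logged). Non-positive or unparseable cells are flagged missing (`NA`) with
#' a logged count; entirely non-numeric columns (e.g. gene symbols) are
#' dropped.
#'
#' @param path Path to the delimited file.
#' @param delimiter Field delimiter; default inferred from extension
#'   (`.csv` comma, otherwise tab).
#' @param accession_column Column holding the accessions, by name or 1-based
#'   index. Default: first column.
#' @param policy An [accession_policy()].
#'
#' @return A [ratio_table()].
#' @export
read_ratio_table <- function(path, delimiter = NULL, accession_column = 1L,
                             policy = accession_policy()) {
  if (!file.exists(path)) stop(sprintf("ratio table not found: %s", path), call. = FALSE)
  sep <- infer_delimiter(path, delimiter)
  raw <- data.table::fread(path, sep = sep, header = TRUE, data.table = FALSE,
                           colClasses = "character", showProgress = FALSE)
  if (nrow(raw) == 0L) stop("ratio table has no data rows", call. = FALSE)
  if (is.numeric(accession_column)) {
    if (accession_column < 1L || accession_column > ncol(raw)) {
      stop("accession column index out of range", call. = FALSE)
    }
    acc_name <- names(raw)[accession_column]
  } else {
    if (!accession_column %in% names(raw)) {
      stop(sprintf("accession column '%s' not in header", accession_column), call. = FALSE)
    }
    acc_name <- accession_column
  }
  acc <- normalize_accession(raw[[acc_name]], policy)

  candidates <- setdiff(names(raw), acc_name)
  vals <- list()
  n_flagged <- 0L
  for (nm in candidates) {
    v <- suppressWarnings(as.numeric(raw[[nm]]))
    if (all(is.na(v))) {
      message(sprintf("read_ratio_table: dropping non-numeric column '%s'", nm))
      next
    }
    bad <- !is.na(v) & (!is.finite(v) | v <= 0)
    bad <- bad | (is.na(v) & nzchar(trimws(raw[[nm]])) & !is.na(raw[[nm]]))
    n_flagged <- n_flagged + sum(bad | is.na(v))
    v[bad] <- NA_real_
    vals[[nm]] <- v
  }
  if (length(vals) == 0L) stop("no numeric ratio columns found", call. = FALSE)
  if (n_flagged > 0L) {
    message(sprintf("read_ratio_table: flagged %d missing/non-positive/unparseable cells",
                    n_flagged))
  }
  dup <- duplicated(acc)
  if (any(dup)) {
    for (a in unique(acc[dup])) {
      message(sprintf("read_ratio_table: duplicate accession '%s'; keeping first occurrence", a))
    }
    keep <- !dup
    acc <- acc[keep]
    vals <- lapply(vals, `[`, keep)
  }
  usable <- Reduce(`|`, lapply(vals, function(v) !is.na(v)))
  if (!any(usable)) stop("ratio table empty after filtering", call. = FALSE)
  ratio_table(acc, as.data.frame(vals, optional = TRUE))
}

fmt_num <- function(x, digits = 6L) {
  out <- formatC(x, digits = digits, format = "g")
  out[is.na(x)] <- "NA"
  out
}

#' Write a ratio table to delimited text
#'
#' Numeric cells are written with 6 significant digits; missing cells as `NA`.
#' Round trip: reading the written file back yields identical accession order,
#' column names, and values (at the written precision).
#'
#' @param table A [ratio_table()].
#' @param path Output path; delimiter inferred from extension unless given.
#' @param delimiter Optional delimiter override.
#' @return `path`, invisibly.
#' @export
write_ratio_table <- function(table, path, delimiter = NULL) {
  stopifnot(inherits(table, "ratio_table"))
  sep <- infer_delimiter(path, delimiter)
  out <- data.frame(accession = table$accession, stringsAsFactors = FALSE)
  for (nm in ratio_columns(table)) out[[nm]] <- fmt_num(table[[nm]])
  utils::write.table(out, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Construct a TP/FP reference set
#'
#' Two disjoint accession sets define the compartment ground truth: residents
#' of the target compartment (true positives, e.g. a curated surfaceome) and
#' of a contaminant compartment (false positives, e.g. intracellular
#' proteins).
#'
#' @param tp,fp Character vectors of accessions (normalized by the caller).
#' @param provenance Free-text label, e.g. `"mouse surfaceome"`.
#' @return Object of class `reference_set` with fields `tp`, `fp`,
#'   `provenance`.
#' @export
reference_set <- function(tp, fp, provenance = "") {
  tp <- unique(as.character(tp))
  fp <- unique(as.character(fp))
  if (length(tp) == 0L || length(fp) == 0L) {
    stop("reference error: both TP and FP sets must be non-empty", call. = FALSE)
  }
  both <- base::intersect(tp, fp)
  if (length(both) > 0L) {
    stop("TP and FP sets overlap; resolve conflicts before construction", call. = FALSE)
  }
  structure(list(tp = tp, fp = fp, provenance = as.character(provenance)),
            class = "reference_set")
}

#' @export
print.reference_set <- function(x, ...) {
  cat(sprintf("reference_set: %d TP / %d FP%s\n", length(x$tp), length(x$fp),
              if (nzchar(x$provenance)) paste0(" (", x$provenance, ")") else ""))
  invisible(x)
}

read_accession_list <- function(path, policy) {
  if (!file.exists(path)) stop(sprintf("reference file not found: %s", path), call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L) return(character(0))
  unique(normalize_accession(lines, policy))
}

#' Read TP and FP reference lists
#'
#' Each file holds one accession per line; lines starting with `#` are
#' comments. Accessions present in both files are conflicts: they are removed
#' from both sets and logged.
#'
#' @param tp_path,fp_path Paths to the true-positive and false-positive lists.
#' @param policy An [accession_policy()].
#' @param provenance Free-text label stored on the result.
#' @return A [reference_set()].
#' @export
read_reference <- function(tp_path, fp_path, policy = accession_policy(),
                           provenance = "") {
  tp <- read_accession_list(tp_path, policy)
  fp <- read_accession_list(fp_path, policy)
  both <- base::intersect(tp, fp)
  if (length(both) > 0L) {
    warning(sprintf("read_reference: %d accession(s) in both TP and FP, removed from both: %s",
                    length(both), paste(utils::head(both, 10L), collapse = ", ")),
            call. = FALSE)
    tp <- setdiff(tp, both)
    fp <- setdiff(fp, both)
  }
  if (length(tp) == 0L || length(fp) == 0L) {
    stop("reference error: a reference set is empty after loading", call. = FALSE)
  }
  reference_set(tp, fp, provenance)
}

sanitize_filename <- function(x) gsub("[^A-Za-z0-9._-]+", "_", x)

#' Write pipeline result tables
#'
#' Writes, under `outdir`: the final post-cutoff proteome (one accession per
#' line) plus a TSV of per-ratio pass/fail flags; one curve table per ratio
#' column (rank, accession, ratio, label, tpr, fpr, diff); one top-N table
#' per ratio column; and a YAML manifest of all written paths. Re-running
#' with identical inputs overwrites with identical bytes.
#'
#' @param outdir Output directory (created if needed).
#' @param result A `cutoff_result` from [intersect_columns()].
#' @param curves List of `enrichment_curve` objects from [compute_curve()].
#' @param top_tables Named list of per-ratio top-N data frames from
#'   [top_enriched()].
#' @return Named list manifest of written file paths, invisibly.
#' @export
write_results <- function(outdir, result, curves, top_tables) {
  stopifnot(inherits(result, "cutoff_result"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(outdir)) stop(sprintf("cannot create output directory: %s", outdir), call. = FALSE)
  manifest <- list()

  proteome_path <- file.path(outdir, "final_proteome.txt")
  writeLines(sort(result$final_proteome), proteome_path)
  manifest$final_proteome <- proteome_path

  all_acc <- sort(unique(unlist(result$per_column_retained, use.names = FALSE)))
  flags <- data.frame(accession = all_acc, stringsAsFactors = FALSE)
  for (cn in names(result$per_column_retained)) {
    flags[[cn]] <- ifelse(all_acc %in% result$per_column_retained[[cn]], "pass", "fail")
  }
  flags$final <- ifelse(all_acc %in% result$final_proteome, "pass", "fail")
  flags_path <- file.path(outdir, "pass_fail.tsv")
  utils::write.table(flags, flags_path, sep = "\t", quote = FALSE, row.names = FALSE)
  manifest$pass_fail <- flags_path

  manifest$curves <- list()
  for (cv in curves) {
    tab <- curve_table(cv)
    p <- file.path(outdir, sprintf("curve_%s.tsv", sanitize_filename(cv$column_name)))
    num <- vapply(tab, is.numeric, logical(1)) & !names(tab) %in% "rank"
    tab[num] <- lapply(tab[num], fmt_num)
    utils::write.table(tab, p, sep = "\t", quote = FALSE, row.names = FALSE)
    manifest$curves[[cv$column_name]] <- p
  }

  manifest$top <- list()
  for (cn in names(top_tables)) {
    tab <- top_tables[[cn]]
    tab$ratio <- fmt_num(tab$ratio)
    p <- file.path(outdir, sprintf("top_%s.tsv", sanitize_filename(cn)))
    utils::write.table(tab, p, sep = "\t", quote = FALSE, row.names = FALSE)
    manifest$top[[cn]] <- p
  }

  manifest_path <- file.path(outdir, "manifest.yaml")
  yaml::write_yaml(manifest, manifest_path)
  manifest$manifest <- manifest_path
  invisible(manifest)
}

#' Per-rank curve table for one ratio column
#'
#' @param curve An `enrichment_curve`.
#' @return Data frame with columns rank, accession, ratio, label, tpr, fpr,
#'   diff.
#' @export
curve_table <- function(curve) {
  stopifnot(inherits(curve, "enrichment_curve"))
  data.frame(rank = curve$ranked$rank,
             accession = curve$ranked$accession,
             ratio = curve$ranked$ratio,
             label = as.character(curve$ranked$label),
             tpr = curve$tpr, fpr = curve$fpr, diff = curve$diff,
             stringsAsFactors = FALSE)
}
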