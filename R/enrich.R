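# Local over-representation analysis: a hypergeometric (Fisher upper-tail)
# test of each annotation term in the post-cutoff proteome against the
# detected background, with Benjamini-Hochberg FDR control. This replaces
# any external annotation-server hand-off with an offline, user-supplied
# annotation collection (flat term -> accession sets; no ontology graph
# propagation).

#' Construct an annotation collection
#'
#' @param terms Named list: term id -> character vector of accessions (each
#'   non-empty). Optionally each element may carry a `"name"` attribute, or
#'   supply `term_names`.
#' @param namespace Free-text namespace label (e.g. "localization",
#'   "function", "pathway").
#' @param term_names Optional named character vector of human-readable term
#'   names.
#' @return Object of class `annotation_collection`.
#' @export
annotation_collection <- function(terms, namespace = "", term_names = NULL) {
  if (length(terms) == 0L) stop("no annotation terms", call. = FALSE)
  if (is.null(names(terms)) || any(!nzchar(names(terms)))) {
    stop("terms must be named by term id", call. = FALSE)
  }
  terms <- lapply(terms, function(x) unique(as.character(x)))
  if (any(vapply(terms, length, integer(1)) == 0L)) {
    stop("every term's accession set must be non-empty", call. = FALSE)
  }
  nm <- stats::setNames(names(terms), names(terms))
  if (!is.null(term_names)) nm[names(term_names)] <- term_names
  structure(list(terms = terms, term_names = nm, namespace = namespace),
            class = "annotation_collection")
}

#' Read an annotation collection from TSV or GMT
#'
#' TSV format: two columns, `term id <TAB> accession`, optional third column
#' with the term name, no header required (a header line whose second field
#' is not accession-like is tolerated). GMT format (`.gmt`): one term per
#' line, `term id <TAB> description <TAB> accession...`.
#'
#' @param path Input file.
#' @param namespace Namespace label stored on the collection.
#' @param policy [accession_policy()] applied to member accessions.
#' @return An [annotation_collection()].
#' @export
read_annotations <- function(path, namespace = "", policy = accession_policy()) {
  if (!file.exists(path)) stop(sprintf("annotation file not found: %s", path), call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  if (length(lines) == 0L) stop("empty annotation file", call. = FALSE)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  terms <- list()
  term_names <- character(0)
  if (grepl("\\.gmt$", path, ignore.case = TRUE)) {
    for (f in fields) {
      if (length(f) < 3L) next
      terms[[f[[1L]]]] <- normalize_accession(f[seq.int(3L, length(f))], policy)
      term_names[[f[[1L]]]] <- f[[2L]]
    }
  } else {
    for (f in fields) {
      if (length(f) < 2L) next
      id <- f[[1L]]
      terms[[id]] <- c(terms[[id]], normalize_accession(f[[2L]], policy))
      if (length(f) >= 3L && nzchar(f[[3L]])) term_names[[id]] <- f[[3L]]
    }
  }
  if (length(terms) == 0L) stop("no parsable annotation terms", call. = FALSE)
  annotation_collection(terms, namespace = namespace, term_names = term_names)
}

#' Over-representation analysis of a study set
#'
#' For each term with `K` annotated proteins in the background of size `N`,
#' and `k` of them among the `n` study proteins, computes the upper-tail
#' hypergeometric probability of observing at least `k` hits,
#' `fold_enrichment = (k/n) / (K/N)`, and Benjamini-Hochberg adjusted values
#' across all tested terms. Terms with no member in the background are
#' dropped (logged). Alpha thresholds are for reporting only; nothing is
#' filtered here.
#'
#' @param study Character vector of study accessions (e.g. the post-cutoff
#'   proteome); must be a subset of `background`.
#' @param background Character vector of background accessions (typically
#'   all detected proteins).
#' @param annotations An [annotation_collection()].
#' @return Object of class `ora_result`: data frame sorted by p with columns
#'   `term_id`, `term_name`, `k`, `n`, `K`, `N`, `fold_enrichment`, `p`,
#'   `fdr`.
#' @export
ora <- function(study, background, annotations) {
  stopifnot(inherits(annotations, "annotation_collection"))
  study <- unique(as.character(study))
  background <- unique(as.character(background))
  if (length(study) < 1L) stop("study set is empty", call. = FALSE)
  extra <- setdiff(study, background)
  if (length(extra) > 0L) {
    stop(sprintf("study set is not a subset of the background (%d foreign accessions)",
                 length(extra)), call. = FALSE)
  }
  n <- length(study)
  N <- length(background)
  rows <- lapply(names(annotations$terms), function(id) {
    members <- base::intersect(annotations$terms[[id]], background)
    K <- length(members)
    if (K == 0L) return(NULL)
    k <- length(base::intersect(members, study))
    p <- stats::phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
    data.frame(term_id = id, term_name = unname(annotations$term_names[[id]]),
               k = k, n = n, K = K, N = N,
               fold_enrichment = (k / n) / (K / N),
               p = p, stringsAsFactors = FALSE)
  })
  dropped <- sum(vapply(rows, is.null, logical(1)))
  if (dropped > 0L) {
    message(sprintf("ora: dropped %d term(s) with no member in the background", dropped))
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0L) stop("no term overlaps the background", call. = FALSE)
  out <- do.call(rbind, rows)
  out$fdr <- stats::p.adjust(out$p, method = "BH")
  out <- out[order(out$p, out$term_id), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("ora_result", "data.frame"))
}
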