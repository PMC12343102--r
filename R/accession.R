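# Identifier normalization: data tables and reference lists must key-match on
# UniProt accessions even when one side carries isoform suffixes or full
# FASTA-style headers.

#' Accession normalization policy
#'
#' Controls how raw protein identifiers are canonicalized before any
#' key-matching between quantification tables and reference lists.
#'
#' @param strip_isoform Remove a trailing isoform suffix (`"-2"` in
#'   `"P12345-2"`). Reference lists are typically gene-level; keeping isoform
#'   suffixes would silently zero the TP/FP hit counts.
#' @param parse_fasta_header Extract the accession from `db|ACC|NAME`-style
#'   tokens (e.g. `"sp|P12345|NAME_MOUSE"`).
#' @param case_fold Uppercase the accession.
#'
#' @return An object of class `accession_policy`.
#' @examples
#' normalize_accession("sp|P12345-2|NAME_MOUSE", accession_policy())
#' @export
accession_policy <- function(strip_isoform = TRUE, parse_fasta_header = TRUE,
                             case_fold = TRUE) {
  stopifnot(is.logical(strip_isoform), length(strip_isoform) == 1L,
            is.logical(parse_fasta_header), length(parse_fasta_header) == 1L,
            is.logical(case_fold), length(case_fold) == 1L)
  structure(list(strip_isoform = strip_isoform,
                 parse_fasta_header = parse_fasta_header,
                 case_fold = case_fold),
            class = "accession_policy")
}

#' Normalize protein accessions
#'
#' Vectorized canonicalization of raw identifier strings under an
#' [accession_policy()]. The operation is idempotent:
#' `normalize_accession(normalize_accession(x)) == normalize_accession(x)`.
#' With every policy flag off it reduces to whitespace stripping.
#'
#' @param raw Character vector of raw identifiers.
#' @param policy An [accession_policy()].
#'
#' @return Character vector of canonical accessions, never empty strings.
#' @export
normalize_accession <- function(raw, policy = accession_policy()) {
  stopifnot(inherits(policy, "accession_policy"))
  x <- trimws(as.character(raw))
  if (any(is.na(x) | !nzchar(x))) {
    stop("empty or missing accession after whitespace strip", call. = FALSE)
  }
  if (policy$parse_fasta_header) {
    has_bar <- grepl("|", x, fixed = TRUE)
    if (any(has_bar)) {
      x[has_bar] <- vapply(strsplit(x[has_bar], "|", fixed = TRUE), function(f) {
        f <- f[nzchar(f)]
        if (length(f) >= 2L) f[[2L]] else f[[1L]]
      }, character(1))
    }
  }
  if (policy$strip_isoform) {
    x <- sub("-[0-9]+$", "", x)
  }
  if (policy$case_fold) {
    x <- toupper(x)
  }
  if (any(!nzchar(x))) {
    stop("accession became empty under normalization policy", call. = FALSE)
  }
  x
}
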