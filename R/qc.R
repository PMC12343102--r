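# Replicate QC: pairwise correlation of ratio columns. Biological replicates
# of a successful labeling experiment should correlate strongly; a
# low-correlation pair flags a problematic channel before any cutoff is run.

#' Pairwise correlation of ratio columns
#'
#' Ratios are multiplicative fold changes, so the default estimator is the
#' Pearson correlation of log2-transformed ratios; `spearman` works on ranks
#' and is transform-invariant. Missing cells are handled pairwise-complete
#' (not listwise); the per-pair number of complete observations is reported
#' so low-overlap pairs stay visible. A pair with fewer than 3 complete
#' observations is reported as `NA` (undefined, not fabricated) with a
#' warning.
#'
#' @param table A [ratio_table()] with at least two ratio columns.
#' @param method `"pearson_log2"` (default) or `"spearman"`.
#' @return Object of class `correlation_matrix`: list with `column_names`,
#'   `coefficients` (symmetric, unit diagonal), `method`, and `n_complete`
#'   (matrix of per-pair complete-observation counts).
#' @export
pairwise_correlation <- function(table, method = c("pearson_log2", "spearman")) {
  stopifnot(inherits(table, "ratio_table"))
  method <- match.arg(method)
  cols <- ratio_columns(table)
  if (length(cols) < 2L) stop("need at least two ratio columns for QC", call. = FALSE)
  m <- as.matrix(as.data.frame(table)[cols])
  p <- length(cols)
  coef <- diag(1, p)
  ncomp <- matrix(0L, p, p, dimnames = list(cols, cols))
  diag(ncomp) <- colSums(!is.na(m))
  dimnames(coef) <- list(cols, cols)
  for (i in seq_len(p - 1L)) {
    for (j in seq.int(i + 1L, p)) {
      ok <- !is.na(m[, i]) & !is.na(m[, j])
      ncomp[i, j] <- ncomp[j, i] <- sum(ok)
      if (sum(ok) < 3L) {
        warning(sprintf("pairwise_correlation: <3 complete observations for %s vs %s; undefined",
                        cols[i], cols[j]), call. = FALSE)
        r <- NA_real_
      } else if (method == "pearson_log2") {
        r <- stats::cor(log2(m[ok, i]), log2(m[ok, j]), method = "pearson")
      } else {
        r <- stats::cor(m[ok, i], m[ok, j], method = "spearman")
      }
      coef[i, j] <- coef[j, i] <- r
    }
  }
  structure(list(column_names = cols, coefficients = coef,
                 method = method, n_complete = ncomp),
            class = "correlation_matrix")
}

#' @export
print.correlation_matrix <- function(x, ...) {
  cat(sprintf("correlation_matrix (%s):\n", x$method))
  print(round(x$coefficients, 3))
  invisible(x)
}
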