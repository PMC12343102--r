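# Core computation: rank proteins by labeled-to-control ratio, scan the
# ranking against TP/FP references, locate the TPR-FPR-maximum cutoff,
# compute the ROC/AUC, and intersect retained sets across ratio columns.
#
# Definitions, for one ratio column ranked in descending ratio order with
# n_tp reference true positives and n_fp reference false positives detected:
#   tpr[k] = #TP among top k / n_tp
#   fpr[k] = #FP among top k / n_fp
#   diff[k] = tpr[k] - fpr[k]
# Unannotated proteins occupy ranks but enter neither numerator nor
# denominator; they are retained or discarded purely by position.

#' Rank one ratio column against a reference set
#'
#' Sorts detected proteins by the chosen ratio column in descending order
#' (stable: ties keep input-row order), dropping proteins whose cell is
#' missing in this column, and labels each entry `TP`, `FP`, or
#' `UNANNOTATED` by reference membership.
#'
#' @param table A [ratio_table()].
#' @param column Ratio column name.
#' @param ref A [reference_set()].
#' @return Object of class `ranked_column`: a data frame with columns
#'   `rank`, `accession`, `ratio`, `label` and attributes `column_name`,
#'   `n_tp`, `n_fp`.
#' @export
rank_column <- function(table, column, ref) {
  stopifnot(inherits(table, "ratio_table"), inherits(ref, "reference_set"))
  if (!column %in% ratio_columns(table)) {
    stop(sprintf("column '%s' not in ratio table", column), call. = FALSE)
  }
  v <- table[[column]]
  keep <- !is.na(v)
  acc <- table$accession[keep]
  v <- v[keep]
  ord <- order(-v)  # radix sort: stable, ties keep input-row order
  acc <- acc[ord]
  v <- v[ord]
  label <- rep("UNANNOTATED", length(acc))
  label[acc %in% ref$tp] <- "TP"
  label[acc %in% ref$fp] <- "FP"
  n_tp <- sum(label == "TP")
  n_fp <- sum(label == "FP")
  if (n_tp == 0L || n_fp == 0L) {
    stop(sprintf("reference does not overlap data in column '%s' (%d TP, %d FP detected)",
                 column, n_tp, n_fp), call. = FALSE)
  }
  out <- data.frame(rank = seq_along(acc), accession = acc, ratio = v,
                    label = factor(label, levels = c("TP", "FP", "UNANNOTATED")),
                    stringsAsFactors = FALSE)
  structure(out, class = c("ranked_column", "data.frame"),
            column_name = column, n_tp = n_tp, n_fp = n_fp)
}

#' Find the TPR-FPR-maximum cutoff rank
#'
#' Returns a 1-based rank at which `diff = tpr - fpr` attains its maximum.
#' When the maximum is attained at several ranks, `tie_policy = "last"`
#' (default) takes the deepest such rank, retaining more proteins at
#' identical criterion value; `"first"` takes the shallowest.
#'
#' @param diff Numeric vector of per-rank TPR-FPR values.
#' @param tie_policy `"last"` or `"first"`.
#' @param tol Absolute tolerance for treating two diff values as tied
#'   (guards against floating-point noise in equal rationals).
#' @return Integer cutoff rank.
#' @export
find_cutoff <- function(diff, tie_policy = c("last", "first"), tol = 1e-9) {
  tie_policy <- match.arg(tie_policy)
  if (length(diff) == 0L) stop("empty diff sequence", call. = FALSE)
  m <- max(diff)
  at_max <- which(diff >= m - tol)
  if (tie_policy == "last") max(at_max) else min(at_max)
}

#' ROC curve and AUC for a ranked column
#'
#' The ROC is traced over (FPR, TPR) while scanning the ranking from the
#' top, with all entries sharing an identical ratio value processed as a
#' single block (one ROC segment), and the area taken by the trapezoidal
#' rule. This makes the AUC independent of tie order and equal to the
#' Mann-Whitney probability
#' \eqn{P(r_{TP} > r_{FP}) + \frac{1}{2} P(r_{TP} = r_{FP})} over all TP x FP
#' pairs. Unannotated entries contribute nothing and do not affect the AUC.
#'
#' @param ranked A `ranked_column` from [rank_column()].
#' @return List with `auc` (in `[0, 1]`) and `roc_points` (data frame of
#'   `fpr`, `tpr`, starting at (0,0) and ending at (1,1)).
#' @export
compute_auc <- function(ranked) {
  stopifnot(inherits(ranked, "ranked_column"))
  n_tp <- attr(ranked, "n_tp")
  n_fp <- attr(ranked, "n_fp")
  is_tp <- ranked$label == "TP"
  is_fp <- ranked$label == "FP"
  # one block per distinct ratio value, in ranked (descending) order
  block <- cumsum(!duplicated(ranked$ratio))
  tp_inc <- tapply(as.numeric(is_tp), block, sum)
  fp_inc <- tapply(as.numeric(is_fp), block, sum)
  tpr <- c(0, cumsum(tp_inc) / n_tp)
  fpr <- c(0, cumsum(fp_inc) / n_fp)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1L) + utils::tail(tpr, -1L)) / 2)
  list(auc = auc,
       roc_points = data.frame(fpr = as.numeric(fpr), tpr = as.numeric(tpr)))
}

#' Compute the enrichment curve for a ranked column
#'
#' Produces the per-rank TPR, FPR, and TPR-FPR arrays, the cutoff rank
#' (per [find_cutoff()]), and the ROC/AUC (per [compute_auc()]).
#'
#' @param ranked A `ranked_column` from [rank_column()].
#' @param tie_policy Cutoff tie-break, see [find_cutoff()].
#' @return Object of class `enrichment_curve`: list with `column_name`,
#'   `tpr`, `fpr`, `diff`, `cutoff_rank`, `auc`, `roc_points`, `n_tp`,
#'   `n_fp`, and the `ranked` input.
#' @export
compute_curve <- function(ranked, tie_policy = c("last", "first")) {
  stopifnot(inherits(ranked, "ranked_column"))
  tie_policy <- match.arg(tie_policy)
  n_tp <- attr(ranked, "n_tp")
  n_fp <- attr(ranked, "n_fp")
  cum_tp <- cumsum(ranked$label == "TP")
  cum_fp <- cumsum(ranked$label == "FP")
  tpr <- cum_tp / n_tp
  fpr <- cum_fp / n_fp
  d <- tpr - fpr
  # exact argmax on integer scores, immune to floating-point rounding
  score <- cum_tp * n_fp - cum_fp * n_tp
  at_max <- which(score == max(score))
  cutoff <- if (tie_policy == "last") max(at_max) else min(at_max)
  roc <- compute_auc(ranked)
  structure(list(column_name = attr(ranked, "column_name"),
                 tpr = tpr, fpr = fpr, diff = d,
                 cutoff_rank = as.integer(cutoff),
                 auc = roc$auc, roc_points = roc$roc_points,
                 n_tp = n_tp, n_fp = n_fp, ranked = ranked),
            class = "enrichment_curve")
}

#' @export
print.enrichment_curve <- function(x, ...) {
  cat(sprintf("enrichment_curve '%s': %d proteins (%d TP, %d FP), AUC = %.3f, cutoff rank = %d\n",
              x$column_name, nrow(x$ranked), x$n_tp, x$n_fp, x$auc, x$cutoff_rank))
  invisible(x)
}

#' Retain proteins at or above a cutoff rank
#'
#' Any protein ranked at or above the cutoff position is retained,
#' regardless of its annotation (TP, FP, or unannotated) — the mechanism by
#' which genuinely translocated proteins with contaminant-compartment
#' annotations survive the filter.
#'
#' @param ranked A `ranked_column`.
#' @param cutoff_rank 1-based rank; ranks `1..cutoff_rank` inclusive are
#'   retained.
#' @return Character vector of retained accessions.
#' @export
apply_cutoff <- function(ranked, cutoff_rank) {
  stopifnot(inherits(ranked, "ranked_column"))
  if (length(cutoff_rank) != 1L || is.na(cutoff_rank) ||
      cutoff_rank < 1L || cutoff_rank > nrow(ranked)) {
    stop("cutoff rank out of range", call. = FALSE)
  }
  ranked$accession[seq_len(cutoff_rank)]
}

#' Intersect retained sets across ratio columns
#'
#' The final proteome keeps only proteins that passed the cutoff of every
#' ratio column, which further removes contaminants. An empty intersection
#' is a valid (logged) outcome.
#'
#' @param retained Named list of per-column retained accession vectors.
#' @return Object of class `cutoff_result` with `per_column_retained` and
#'   `final_proteome`.
#' @export
intersect_columns <- function(retained) {
  if (length(retained) < 1L) stop("at least one retained set required", call. = FALSE)
  if (is.null(names(retained)) || any(!nzchar(names(retained)))) {
    stop("retained sets must be named by column", call. = FALSE)
  }
  final <- Reduce(base::intersect, retained)
  if (length(final) == 0L) {
    warning("final proteome is empty: no protein passed the cutoff of all ratios",
            call. = FALSE)
  }
  structure(list(per_column_retained = lapply(retained, unique),
                 final_proteome = unique(final)),
            class = "cutoff_result")
}

#' @export
print.cutoff_result <- function(x, ...) {
  sizes <- vapply(x$per_column_retained, length, integer(1))
  cat("cutoff_result:\n")
  for (cn in names(sizes)) cat(sprintf("  %s: %d retained\n", cn, sizes[[cn]]))
  cat(sprintf("  final proteome (intersection): %d\n", length(x$final_proteome)))
  invisible(x)
}

#' Top enriched proteins of a ranked column
#'
#' @param ranked A `ranked_column`.
#' @param n Number of entries (default 100); truncated to the column length.
#' @return Data frame with `rank`, `accession`, `ratio` in rank order.
#' @export
top_enriched <- function(ranked, n = 100L) {
  stopifnot(inherits(ranked, "ranked_column"))
  if (n < 1L) stop("n must be >= 1", call. = FALSE)
  k <- min(as.integer(n), nrow(ranked))
  data.frame(rank = ranked$rank[seq_len(k)],
             accession = ranked$accession[seq_len(k)],
             ratio = ranked$ratio[seq_len(k)],
             stringsAsFactors = FALSE)
}

#' One-call cutoff analysis for a single ratio column
#'
#' Convenience wrapper: [rank_column()] then [compute_curve()].
#'
#' @inheritParams rank_column
#' @inheritParams compute_curve
#' @return An `enrichment_curve`.
#' @export
analyze_column <- function(table, column, ref, tie_policy = c("last", "first")) {
  compute_curve(rank_column(table, column, ref), tie_policy = match.arg(tie_policy))
}
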