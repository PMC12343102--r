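# Synthetic benchmark generator. The enriched mode emulates the statistical
# structure the ratiometric method assumes: target-compartment proteins carry
# multiplicatively larger labeled-to-control ratios than contaminants, with
# log-normal spread and independent per-column replicate noise. The failed
# mode is the negative control: ratios drawn independently of the TP/FP
# labels, so TPR/FPR/ROC all track the diagonal and AUC concentrates at 0.5.

#' Synthetic dataset configuration
#'
#' Two-component log2-ratio model. Each protein draws a latent log2 ratio:
#' TP rows from Normal(`mu_tp`, `sigma`), FP rows from Normal(`mu_fp`,
#' `sigma`), unannotated rows from a 50:50 mixture of the two. Each of the
#' `n_columns` ratio columns adds independent Normal(0, `replicate_sd`)
#' noise, and ratios are emitted as `2^(latent + noise)` (hence positive).
#' With `failed = TRUE` every row draws from the FP component regardless of
#' its label.
#'
#' Defaults state a realistic cell-surface labeling experiment: four
#' labeled-to-control ratio columns (two labeled x two control channels),
#' a detected proteome with as many unannotated proteins as referenced
#' ones, and a TP/FP separation of 1.15 log2 units at unit spread — the
#' normal-overlap relation AUC = Phi(delta / (sigma*sqrt(2))) then puts the
#' per-column AUC near 0.79, the quality level of a good published surface
#' labeling run.
#'
#' @param n_tp,n_fp,n_unannotated Row counts per group (`n_tp`, `n_fp` >= 1).
#' @param mu_tp,mu_fp Mean latent log2 ratios of the two components.
#' @param sigma Within-group latent log2 spread (> 0).
#' @param n_columns Number of ratio columns.
#' @param replicate_sd Per-column log2 noise (>= 0).
#' @param failed If `TRUE`, labels are independent of ratios.
#' @param seed Integer RNG seed; generation is deterministic per seed.
#' @return Object of class `synth_config`.
#' @export
synth_config <- function(n_tp = 500L, n_fp = 500L, n_unannotated = 1000L,
                         mu_tp = 1.15, mu_fp = 0, sigma = 1,
                         n_columns = 4L, replicate_sd = 0.25,
                         failed = FALSE, seed = 1L) {
  cfg <- list(n_tp = as.integer(n_tp), n_fp = as.integer(n_fp),
              n_unannotated = as.integer(n_unannotated),
              mu_tp = as.numeric(mu_tp), mu_fp = as.numeric(mu_fp),
              sigma = as.numeric(sigma), n_columns = as.integer(n_columns),
              replicate_sd = as.numeric(replicate_sd),
              failed = isTRUE(failed), seed = as.integer(seed))
  if (cfg$n_tp < 1L || cfg$n_fp < 1L || cfg$n_unannotated < 0L) {
    stop("need n_tp >= 1, n_fp >= 1, n_unannotated >= 0", call. = FALSE)
  }
  if (!is.finite(cfg$sigma) || cfg$sigma <= 0) stop("sigma must be > 0", call. = FALSE)
  if (!is.finite(cfg$replicate_sd) || cfg$replicate_sd < 0) {
    stop("replicate_sd must be >= 0", call. = FALSE)
  }
  if (cfg$n_columns < 1L) stop("need at least one ratio column", call. = FALSE)
  if (is.na(cfg$seed)) stop("seed must be an integer", call. = FALSE)
  structure(cfg, class = "synth_config")
}

# run expr under a local RNG stream without disturbing the caller's state
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Generate a synthetic ratio table, reference set, and truth table
#'
#' @param config A [synth_config()].
#' @return List with `table` (a [ratio_table()]), `reference` (a
#'   [reference_set()] containing exactly the TP/FP row accessions), and
#'   `truth` (data frame of `accession`, `group`, `latent` log2 ratio).
#' @examples
#' sim <- synth_generate(synth_config(n_tp = 50, n_fp = 50, n_unannotated = 20,
#'                                    n_columns = 2, seed = 7))
#' analyze_column(sim$table, "R1", sim$reference)
#' @export
synth_generate <- function(config = synth_config()) {
  stopifnot(inherits(config, "synth_config"))
  n <- config$n_tp + config$n_fp + config$n_unannotated
  group <- rep(c("TP", "FP", "UNANNOTATED"),
               c(config$n_tp, config$n_fp, config$n_unannotated))
  acc <- sprintf("SYN%05d", seq_len(n))
  with_local_seed(config$seed, {
    if (config$failed) {
      latent <- stats::rnorm(n, config$mu_fp, config$sigma)
    } else {
      mu <- ifelse(group == "TP", config$mu_tp, config$mu_fp)
      unk <- group == "UNANNOTATED"
      if (any(unk)) {
        mu[unk] <- ifelse(stats::runif(sum(unk)) < 0.5, config$mu_tp, config$mu_fp)
      }
      latent <- stats::rnorm(n, mu, config$sigma)
    }
    vals <- lapply(seq_len(config$n_columns), function(j) {
      2^(latent + stats::rnorm(n, 0, config$replicate_sd))
    })
  })
  names(vals) <- paste0("R", seq_len(config$n_columns))
  list(table = ratio_table(acc, as.data.frame(vals)),
       reference = reference_set(acc[group == "TP"], acc[group == "FP"],
                                 provenance = sprintf("synthetic (seed %d%s)",
                                                      config$seed,
                                                      if (config$failed) ", failed mode" else "")),
       truth = data.frame(accession = acc, group = group, latent = latent,
                          stringsAsFactors = FALSE))
}

#' Subsample a reference set
#'
#' Draws uniformly random subsets of the TP and FP lists at the requested
#' fractions (deterministic per seed). Used to probe robustness of the
#' cutoff analysis to incomplete reference coverage.
#'
#' @param ref A [reference_set()].
#' @param fraction_tp,fraction_fp Fractions in (0, 1]; subset sizes are
#'   `round(fraction * n)` and must be non-zero.
#' @param seed Integer RNG seed.
#' @return A [reference_set()].
#' @export
subsample_reference <- function(ref, fraction_tp = 1, fraction_fp = 1, seed = 1L) {
  stopifnot(inherits(ref, "reference_set"))
  for (f in c(fraction_tp, fraction_fp)) {
    if (!is.finite(f) || f <= 0 || f > 1) stop("fractions must be in (0, 1]", call. = FALSE)
  }
  k_tp <- round(fraction_tp * length(ref$tp))
  k_fp <- round(fraction_fp * length(ref$fp))
  if (k_tp < 1L || k_fp < 1L) {
    stop("subsampling fraction yields an empty reference set", call. = FALSE)
  }
  with_local_seed(seed, {
    tp <- if (k_tp == length(ref$tp)) ref$tp else sample(ref$tp, k_tp)
    fp <- if (k_fp == length(ref$fp)) ref$fp else sample(ref$fp, k_fp)
  })
  reference_set(tp, fp, provenance = sprintf("%s [subsampled %.2g/%.2g, seed %d]",
                                             ref$provenance, fraction_tp, fraction_fp,
                                             as.integer(seed)))
}

#' Write a synthetic dataset to disk
#'
#' Emits the same CSV/TSV and reference-list formats that
#' [read_ratio_table()] and [read_reference()] consume, plus the truth table
#' as TSV.
#'
#' @param sim Result of [synth_generate()].
#' @param outdir Output directory (created if needed).
#' @return Named list of written paths, invisibly.
#' @export
write_synth <- function(sim, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(table = file.path(outdir, "ratios.csv"),
                tp = file.path(outdir, "reference_tp.txt"),
                fp = file.path(outdir, "reference_fp.txt"),
                truth = file.path(outdir, "truth.tsv"))
  write_ratio_table(sim$table, paths$table)
  writeLines(sim$reference$tp, paths$tp)
  writeLines(sim$reference$fp, paths$fp)
  truth <- sim$truth
  truth$latent <- fmt_num(truth$latent)
  utils::write.table(truth, paths$truth, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(paths)
}
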