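# Independent oracles and fixture builders, kept deliberately naive so they
# stay independent of the code paths they check.

# Mann-Whitney AUC by brute force over all TP x FP pairs:
# P(r_TP > r_FP) + 0.5 * P(r_TP = r_FP)
mw_auc_brute <- function(ratios, labels) {
  tp <- ratios[labels == "TP"]
  fp <- ratios[labels == "FP"]
  total <- 0
  for (a in tp) for (b in fp) {
    total <- total + if (a > b) 1 else if (a == b) 0.5 else 0
  }
  total / (length(tp) * length(fp))
}

# Per-rank TPR/FPR by direct cumulative counting on an already-sorted label
# sequence.
curve_brute <- function(labels) {
  n_tp <- sum(labels == "TP")
  n_fp <- sum(labels == "FP")
  tpr <- numeric(length(labels))
  fpr <- numeric(length(labels))
  ct <- 0L; cf <- 0L
  for (k in seq_along(labels)) {
    if (labels[k] == "TP") ct <- ct + 1L
    if (labels[k] == "FP") cf <- cf + 1L
    tpr[k] <- ct / n_tp
    fpr[k] <- cf / n_fp
  }
  list(tpr = tpr, fpr = fpr)
}

# Upper-tail hypergeometric probability by exhaustive enumeration of all
# draws of n from N (term = elements 1..K); exact integer counting.
hyper_tail_brute <- function(k, K, N, n) {
  draws <- utils::combn(N, n)
  hits <- colSums(draws <= K)
  sum(hits >= k) / ncol(draws)
}

# Random small instance with ties, at least one TP and one FP.
random_instance <- function(n_max = 50L) {
  n <- sample(2:n_max, 1L)
  ratios <- sample(seq(0.5, 5, by = 0.5), n, replace = TRUE)  # forces ties
  repeat {
    labels <- sample(c("TP", "FP", "UNANNOTATED"), n, replace = TRUE)
    if (any(labels == "TP") && any(labels == "FP")) break
  }
  acc <- sprintf("X%04d", seq_len(n))
  list(table = ratio_table(acc, data.frame(R1 = ratios)),
       ref = reference_set(acc[labels == "TP"], acc[labels == "FP"]),
       ratios = ratios, labels = labels, acc = acc)
}

# The worked 5-protein toy shared by several tests.
toy_fixture <- function() {
  tab <- ratio_table(c("P1", "P2", "P3", "P4", "P5"),
                     data.frame(R1 = c(5, 4, 3, 2, 1)))
  list(table = tab,
       ref = reference_set(c("P1", "P3"), c("P2", "P5")))
}
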