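test_that("rank_column sorts descending, labels by reference, counts TP/FP", {
  fx <- toy_fixture()
  rk <- rank_column(fx$table, "R1", fx$ref)
  expect_equal(rk$accession, c("P1", "P2", "P3", "P4", "P5"))
  expect_equal(as.character(rk$label), c("TP", "FP", "TP", "UNANNOTATED", "FP"))
  expect_equal(attr(rk, "n_tp"), 2L)
  expect_equal(attr(rk, "n_fp"), 2L)
})

test_that("rank_column is a stable sort and skips missing cells", {
  tab <- ratio_table(c("A", "B", "C", "D"),
                     data.frame(R1 = c(2, 3, 3, NA), R2 = c(1, 2, 3, 4)))
  ref <- reference_set("A", "D")
  rk2 <- rank_column(tab, "R2", ref)
  expect_equal(rk2$accession, c("D", "C", "B", "A"))
  ref2 <- reference_set("A", "B")
  rk <- rank_column(tab, "R1", ref2)
  expect_equal(rk$accession, c("B", "C", "A"))  # B before C: tie keeps row order
  expect_false("D" %in% rk$accession)
})

test_that("rank_column errors when the reference does not overlap the data", {
  tab <- ratio_table(c("A", "B"), data.frame(R1 = c(2, 1)))
  expect_error(rank_column(tab, "R1", reference_set("Z1", "B")),
               "reference does not overlap")
  expect_error(rank_column(tab, "R1", reference_set("A", "Z2")),
               "reference does not overlap")
  expect_error(rank_column(tab, "R9", reference_set("A", "B")), "not in ratio table")
})

test_that("compute_curve reproduces hand-enumerated TPR/FPR/diff", {
  fx <- toy_fixture()
  cv <- compute_curve(rank_column(fx$table, "R1", fx$ref))
  expect_equal(cv$tpr, c(0.5, 0.5, 1, 1, 1))
  expect_equal(cv$fpr, c(0, 0.5, 0.5, 0.5, 1))
  expect_equal(cv$diff, c(0.5, 0, 0.5, 0.5, 0))

  tab <- ratio_table(c("A", "B", "C", "D"), data.frame(R1 = 4:1))
  cv2 <- compute_curve(rank_column(tab, "R1", reference_set(c("A", "B"), c("C", "D"))))
  expect_equal(cv2$tpr, c(0.5, 1, 1, 1))
  expect_equal(cv2$fpr, c(0, 0, 0.5, 1))
  expect_equal(cv2$diff, c(0.5, 1, 0.5, 0))
  expect_equal(cv2$cutoff_rank, 2L)
  expect_equal(cv2$auc, 1.0)

  tab3 <- ratio_table(c("A", "B"), data.frame(R1 = c(2, 1)))
  cv3 <- compute_curve(rank_column(tab3, "R1", reference_set("B", "A")))
  expect_equal(cv3$diff, c(-1, 0))
  expect_equal(cv3$cutoff_rank, 2L)  # maximum is 0, still a valid cutoff
  expect_equal(cv3$auc, 0)
})

test_that("find_cutoff honors tie policy", {
  expect_equal(find_cutoff(c(0.5, 0, 0.5, 0.5, 0), "last"), 4L)
  expect_equal(find_cutoff(c(0.5, 0, 0.5, 0.5, 0), "first"), 1L)
  expect_equal(find_cutoff(c(0.5, 1, 0.5, 0)), 2L)
  expect_error(find_cutoff(numeric(0)), "empty")
})

test_that("compute_auc handles ties as half-credit (Mann-Whitney)", {
  tab <- ratio_table(c("A", "B"), data.frame(R1 = c(3, 3)))
  expect_equal(compute_auc(rank_column(tab, "R1", reference_set("A", "B")))$auc, 0.5)
  fx <- toy_fixture()
  roc <- compute_auc(rank_column(fx$table, "R1", fx$ref))
  expect_equal(roc$auc, 0.75)
  expect_equal(roc$roc_points[1, ], data.frame(fpr = 0, tpr = 0))
  expect_equal(unlist(roc$roc_points[nrow(roc$roc_points), ]),
               c(fpr = 1, tpr = 1))
})

test_that("compute_auc equals the brute-force pairwise statistic on random instances", {
  set.seed(7)
  for (i in 1:200) {
    inst <- random_instance()
    rk <- rank_column(inst$table, "R1", inst$ref)
    expect_equal(compute_auc(rk)$auc,
                 mw_auc_brute(inst$ratios, inst$labels), tolerance = 1e-12)
  }
})

test_that("curve invariants hold on random instances", {
  set.seed(8)
  for (i in 1:50) {
    inst <- random_instance()
    cv <- compute_curve(rank_column(inst$table, "R1", inst$ref))
    expect_true(all(diff(cv$tpr) >= 0) && all(diff(cv$fpr) >= 0))
    expect_equal(cv$tpr[length(cv$tpr)], 1)
    expect_equal(cv$fpr[length(cv$fpr)], 1)
    expect_equal(cv$diff, cv$tpr - cv$fpr)
    expect_true(all(cv$diff[cv$cutoff_rank] >= cv$diff - 1e-12))
    expect_true(cv$auc >= 0 && cv$auc <= 1)
    expect_length(apply_cutoff(cv$ranked, cv$cutoff_rank), cv$cutoff_rank)
  }
})

test_that("apply_cutoff retains ranks 1..k inclusive, regardless of annotation", {
  fx <- toy_fixture()
  rk <- rank_column(fx$table, "R1", fx$ref)
  retained <- apply_cutoff(rk, 4L)
  expect_equal(retained, c("P1", "P2", "P3", "P4"))
  expect_true("P4" %in% retained)  # unannotated protein above cutoff survives
  expect_equal(apply_cutoff(rk, 1L), "P1")
  expect_length(apply_cutoff(rk, 5L), 5L)
  expect_error(apply_cutoff(rk, 0L), "out of range")
  expect_error(apply_cutoff(rk, 6L), "out of range")
})

test_that("intersect_columns takes the set intersection and keeps per-column sets", {
  res <- intersect_columns(list(A = c("P1", "P2", "P3"), B = c("P2", "P3", "P4")))
  expect_setequal(res$final_proteome, c("P2", "P3"))
  expect_true(all(res$final_proteome %in% res$per_column_retained$A))
  expect_true(all(res$final_proteome %in% res$per_column_retained$B))

  single <- intersect_columns(list(A = c("P1", "P2")))
  expect_setequal(single$final_proteome, c("P1", "P2"))

  expect_warning(empty <- intersect_columns(list(A = "P1", B = "P2")),
                 "empty")
  expect_length(empty$final_proteome, 0L)
})

test_that("top_enriched truncates without padding", {
  fx <- toy_fixture()
  rk <- rank_column(fx$table, "R1", fx$ref)
  expect_equal(nrow(top_enriched(rk, 5)), 5L)
  expect_equal(nrow(top_enriched(rk, 100)), 5L)
  top1 <- top_enriched(rk, 1)
  expect_equal(top1$accession, "P1")
  expect_error(top_enriched(rk, 0), ">= 1")
})

test_that("results are invariant under strictly increasing ratio transforms", {
  set.seed(9)
  transforms <- list(exp = exp, cube = function(x) x^3, scale10 = function(x) 10 * x)
  for (i in 1:20) {
    inst <- random_instance()
    base_cv <- compute_curve(rank_column(inst$table, "R1", inst$ref))
    base_ret <- apply_cutoff(base_cv$ranked, base_cv$cutoff_rank)
    for (f in transforms) {
      t_tab <- ratio_table(inst$acc, data.frame(R1 = f(inst$ratios)))
      cv <- compute_curve(rank_column(t_tab, "R1", inst$ref))
      expect_identical(cv$ranked$accession, base_cv$ranked$accession)
      expect_equal(cv$tpr, base_cv$tpr)
      expect_equal(cv$fpr, base_cv$fpr)
      expect_identical(cv$cutoff_rank, base_cv$cutoff_rank)
      expect_equal(cv$auc, base_cv$auc, tolerance = 1e-12)
      expect_identical(apply_cutoff(cv$ranked, cv$cutoff_rank), base_ret)
    }
  }
})
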