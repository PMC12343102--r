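test_that("synth_config validates its parameters", {
  expect_s3_class(synth_config(), "synth_config")
  expect_error(synth_config(n_tp = 0), "n_tp")
  expect_error(synth_config(sigma = 0), "sigma")
  expect_error(synth_config(replicate_sd = -1), "replicate_sd")
  expect_error(synth_config(n_columns = 0), "column")
})

test_that("generation is deterministic per seed and leaves the caller's RNG alone", {
  cfg <- synth_config(n_tp = 30, n_fp = 30, n_unannotated = 10, seed = 99)
  a <- synth_generate(cfg)
  b <- synth_generate(cfg)
  expect_identical(a, b)
  c <- synth_generate(synth_config(n_tp = 30, n_fp = 30, n_unannotated = 10,
                                   seed = 100))
  expect_false(identical(a$table, c$table))

  set.seed(1); before <- runif(1)
  set.seed(1); invisible(synth_generate(cfg)); after <- runif(1)
  expect_identical(before, after)
})

test_that("generated tables satisfy the ratio-table contract and reference the right rows", {
  cfg <- synth_config(n_tp = 25, n_fp = 15, n_unannotated = 10, n_columns = 3,
                      seed = 4)
  sim <- synth_generate(cfg)
  expect_s3_class(sim$table, "ratio_table")
  expect_equal(nrow(sim$table), 50L)
  expect_equal(length(ratio_columns(sim$table)), 3L)
  expect_true(all(as.matrix(as.data.frame(sim$table)[-1]) > 0))
  expect_setequal(sim$reference$tp, sim$truth$accession[sim$truth$group == "TP"])
  expect_setequal(sim$reference$fp, sim$truth$accession[sim$truth$group == "FP"])
  expect_length(sim$reference$tp, 25L)
})

test_that("written synthetic datasets read back through the io layer", {
  sim <- synth_generate(synth_config(n_tp = 20, n_fp = 20, n_unannotated = 5,
                                     n_columns = 2, seed = 12))
  out <- withr::local_tempdir()
  paths <- write_synth(sim, out)
  tab <- read_ratio_table(paths$table)
  ref <- read_reference(paths$tp, paths$fp)
  expect_identical(tab$accession, sim$table$accession)
  expect_setequal(ref$tp, sim$reference$tp)
  cv <- analyze_column(tab, "R1", ref)
  expect_s3_class(cv, "enrichment_curve")
  # byte-identical re-emission (determinism contract)
  out2 <- withr::local_tempdir()
  paths2 <- write_synth(synth_generate(synth_config(n_tp = 20, n_fp = 20,
                                                    n_unannotated = 5,
                                                    n_columns = 2, seed = 12)),
                        out2)
  expect_identical(readLines(paths2$table), readLines(paths$table))
})

test_that("AUC grows monotonically with the TP/FP separation (parameter recovery)", {
  deltas <- c(0.25, 0.75, 1.5, 3)
  mean_auc <- vapply(deltas, function(d) {
    mean(vapply(1:5, function(s) {
      sim <- synth_generate(synth_config(n_tp = 150, n_fp = 150,
                                         n_unannotated = 50, mu_tp = d,
                                         n_columns = 1, replicate_sd = 0,
                                         seed = 1000 + s))
      analyze_column(sim$table, "R1", sim$reference)$auc
    }, numeric(1)))
  }, numeric(1))
  expect_false(is.unsorted(mean_auc))
})

test_that("extreme separation approaches perfect classification", {
  # delta = 10 sigma, no replicate noise: normal-overlap AUC = Phi(10/sqrt(2))
  sim <- synth_generate(synth_config(n_tp = 100, n_fp = 100, n_unannotated = 0,
                                     mu_tp = 10, sigma = 1, replicate_sd = 0,
                                     n_columns = 1, seed = 2))
  expect_gte(analyze_column(sim$table, "R1", sim$reference)$auc, 0.999)
})

test_that("failed mode decouples ratios from labels", {
  aucs <- vapply(1:5, function(s) {
    sim <- synth_generate(synth_config(n_tp = 500, n_fp = 500,
                                       n_unannotated = 0, n_columns = 1,
                                       failed = TRUE, seed = s))
    analyze_column(sim$table, "R1", sim$reference)$auc
  }, numeric(1))
  expect_true(all(aucs > 0.4 & aucs < 0.6))
})

test_that("subsample_reference draws deterministic subsets of the right size", {
  sim <- synth_generate(synth_config(n_tp = 1000, n_fp = 400,
                                     n_unannotated = 0, seed = 3))
  ref <- sim$reference
  expect_identical(subsample_reference(ref, 1, 1, seed = 1)[c("tp", "fp")],
                   ref[c("tp", "fp")])
  sub <- subsample_reference(ref, 0.1, 0.5, seed = 1)
  expect_length(sub$tp, 100L)
  expect_length(sub$fp, 200L)
  expect_true(all(sub$tp %in% ref$tp))
  expect_identical(subsample_reference(ref, 0.1, 0.5, seed = 1)$tp, sub$tp)
  sub2 <- subsample_reference(ref, 0.1, 0.5, seed = 2)
  expect_length(sub2$tp, 100L)
  expect_false(identical(sort(sub$tp), sort(sub2$tp)))
  expect_error(subsample_reference(ref, 0.0001, 1, seed = 1), "empty")
  expect_error(subsample_reference(ref, 1.5, 1, seed = 1), "fractions")
})
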