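test_that("confusion matrix counts true/predicted pairs", {
  cm <- confusion(c(0L, 1L), c(0L, 1L), 2)
  expect_identical(unname(diag(unclass(cm))), c(1L, 1L))
  expect_identical(sum(cm), 2L)
  cm2 <- confusion(c(0L, 0L), c(1L, 1L), 2)
  expect_identical(unclass(cm2)[1, 2], 2L)
  expect_identical(sum(unclass(cm2)[-3]), 0L)  # no other mass
  cm0 <- confusion(integer(), integer(), 3)
  expect_true(all(cm0 == 0L))
  expect_error(confusion(c(0L, 5L), c(0L, 1L), 2), "out of range")
  expect_error(confusion(0L, c(0L, 1L), 2), "equal length")
})

test_that("metrics match the hand-worked two-class example", {
  cm <- matrix(c(8, 1, 2, 9), 2, 2,
               dimnames = list(c("pos", "neg"), c("pos", "neg")))
  rep <- metrics_from_confusion(cm)
  expect_equal(rep$overall_accuracy, 0.85)
  expect_equal(rep$per_class$sensitivity[1], 0.8)
  expect_equal(rep$per_class$specificity[1], 0.9)
  expect_equal(rep$per_class$precision[1], 8 / 9)
  expect_equal(rep$per_class$f_measure[1],
               2 * (8 / 9) * 0.8 / ((8 / 9) + 0.8))
  expect_equal(rep$per_class$f_measure[1], 0.8421053, tolerance = 1e-7)
  # two-class symmetry: class-0 sensitivity is class-1 specificity
  expect_equal(rep$per_class$sensitivity[1], rep$per_class$specificity[2])
  expect_error(metrics_from_confusion(matrix(0, 2, 2)), "empty")
})

test_that("perfect and degenerate confusion matrices follow the conventions", {
  perfect <- metrics_from_confusion(diag(c(5L, 3L, 2L)))
  expect_equal(perfect$overall_accuracy, 1)
  expect_equal(perfect$macro_sensitivity, 1)
  expect_equal(perfect$macro_specificity, 1)
  expect_equal(perfect$macro_f_measure, 1)
  # class with zero true and zero predicted: 0/0 -> 0 with a flag
  cm <- matrix(0L, 3, 3); cm[1, 1] <- 5L; cm[2, 2] <- 5L
  rep <- metrics_from_confusion(cm)
  expect_true(rep$per_class$undefined[3])
  expect_equal(rep$per_class$precision[3], 0)
  expect_equal(rep$per_class$f_measure[3], 0)
  expect_equal(rep$per_class$specificity[3], 1)
})

test_that("metrics agree with an independent reference on random matrices", {
  set.seed(44)
  for (i in 1:100) {
    K <- sample(2:6, 1)
    cm <- matrix(stats::rpois(K * K, 3), K, K)
    if (sum(cm) == 0) cm[1, 1] <- 1
    got <- metrics_from_confusion(cm)
    want <- ref_metrics(cm)
    expect_equal(got$overall_accuracy, want$acc, tolerance = 1e-12)
    expect_equal(got$per_class$sensitivity, unname(want$per[, "sens"]),
                 tolerance = 1e-12)
    expect_equal(got$per_class$specificity, unname(want$per[, "spec"]),
                 tolerance = 1e-12)
    expect_equal(got$per_class$f_measure, unname(want$per[, "f"]),
                 tolerance = 1e-12)
    expect_equal(got$macro_f_measure, want$macro_f, tolerance = 1e-12)
  }
})

test_that("metrics are invariant under class permutation", {
  set.seed(9)
  cm <- matrix(stats::rpois(16, 4), 4, 4,
               dimnames = list(letters[1:4], letters[1:4]))
  perm <- c(3, 1, 4, 2)
  rep1 <- metrics_from_confusion(cm)
  rep2 <- metrics_from_confusion(cm[perm, perm])
  expect_equal(rep1$overall_accuracy, rep2$overall_accuracy)
  expect_equal(rep1$macro_sensitivity, rep2$macro_sensitivity)
  expect_equal(rep1$per_class$f_measure[perm], rep2$per_class$f_measure)
  # micro identity: overall accuracy is the summed per-class TP over total
  expect_equal(rep1$overall_accuracy, sum(diag(cm)) / sum(cm))
})

test_that("evaluate_model scores a fitted network on held-out data", {
  fm <- separable_fm(8)
  m <- bpnn(fm, 4, bpnn_config(hidden_sizes_grid = 4, max_epochs = 200,
                               seed = 2))
  rep <- evaluate_model(m, fm)  # memorization bound on its own train set
  expect_equal(rep$overall_accuracy, 1.0)
  # row order cannot matter
  perm <- sample(nrow(fm$values))
  fmp <- feature_matrix(fm$values[perm, ], fm$labels[perm], fm$class_names)
  repp <- evaluate_model(m, fmp)
  expect_equal(repp$confusion, rep$confusion)
  expect_equal(repp$overall_accuracy, rep$overall_accuracy)
})

test_that("evaluation reports persist as JSON plus a confusion table", {
  cm <- confusion(c(0L, 1L, 1L), c(0L, 1L, 0L), 2, c("A", "B"))
  rep <- metrics_from_confusion(cm)
  stem <- file.path(withr::local_tempdir(), "ev")
  write_eval_report(rep, stem)
  back <- jsonlite::fromJSON(paste0(stem, ".report.json"))
  expect_equal(back$overall_accuracy, rep$overall_accuracy)
  tab <- utils::read.table(paste0(stem, ".confusion.tsv"), sep = "\t",
                           header = TRUE, row.names = 1)
  expect_equal(unname(as.matrix(tab)), unname(unclass(cm)) + 0L)
})
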