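tok2 <- function(tokens, labels) {
  structure(list(tokens = tokens, label = labels,
                 label_set = sort(unique(labels))),
            class = "tokenized_corpus")
}

test_that("vocabulary enumerates requested n-gram orders lexicographically", {
  tk <- tok2(list(c("a", "b"), c("b", "a")), c("x", "y"))
  v <- build_vocabulary(tk, c(1, 2))
  expect_identical(v$terms, c("a", "a b", "b", "b a"))
  expect_identical(unname(v$index[v$terms]), seq_along(v$terms))
  expect_identical(build_vocabulary(tok2(list(c("x", "x", "x")), "a"), 1)$terms,
                   "x")
  # a 2-token document contributes no trigrams
  expect_error(build_vocabulary(tok2(list(c("p", "q")), "a"), 3),
               "empty vocabulary")
  expect_error(build_vocabulary(tok2(list(character()), "a"), 1),
               "empty vocabulary")
})

test_that("count vectorization matches occurrence counts, OOV ignored", {
  tk <- tok2(list(c("a", "b", "a"), character(), c("zz", "zz")),
             c("x", "y", "x"))
  v <- build_vocabulary(tok2(list(c("a", "b")), "x"), 1)
  m <- vectorize_counts(tk, v, 1)
  expect_identical(unname(m$values[1, ]), c(2, 1))
  expect_identical(unname(m$values[2, ]), c(0, 0))
  expect_identical(unname(m$values[3, ]), c(0, 0))  # fully OOV
  expect_identical(m$class_names, c("x", "y"))
  expect_identical(m$labels, c(0L, 1L, 0L))
})

test_that("row sums equal in-vocabulary token totals", {
  set.seed(7)
  toks <- replicate(8, sample(letters[1:5], sample(3:9, 1), TRUE),
                    simplify = FALSE)
  tk <- tok2(toks, rep(c("A", "B"), 4))
  v <- build_vocabulary(tk, 1)
  m <- vectorize_counts(tk, v, 1)
  expect_equal(unname(rowSums(m$values)),
               vapply(toks, function(t) sum(t %in% v$terms), numeric(1)))
})

test_that("tfidf weighting follows the smoothed closed form", {
  tk <- tok2(list(c("a", "b"), c("a"), c("a")), c("x", "y", "x"))
  v <- build_vocabulary(tk, 1)
  m <- tfidf_weight(vectorize_counts(tk, v, 1))
  N <- 3
  expect_equal(unname(m$values[1, "a"]), 1 * (1 + log(N / (1 + 3))))
  expect_equal(unname(m$values[1, "b"]), 1 * (1 + log(N / (1 + 1))))
  expect_equal(unname(m$values[2, "b"]), 0)  # zero counts stay zero
  single <- tfidf_weight(vectorize_counts(tok2(list("a"), "x"), v, 1))
  expect_equal(unname(single$values[1, "a"]), 1 + log(1 / 2))
})

test_that("resampling balances classes exactly", {
  fm <- feature_matrix(matrix(seq_len(8), ncol = 2),
                       c("A", "A", "A", "B"))
  up <- resample_classes(fm, "oversample", seed = 3)
  expect_identical(as.integer(table(up$labels)), c(3L, 3L))
  down <- resample_classes(fm, "undersample", seed = 3)
  expect_identical(as.integer(table(down$labels)), c(1L, 1L))
  # oversampling never invents rows; undersampling never duplicates
  key <- function(m) apply(m$values, 1, paste, collapse = ",")
  expect_true(all(key(up) %in% key(fm)))
  expect_false(any(duplicated(key(down))))
  expect_error(
    resample_classes(feature_matrix(matrix(1, 1, 1), 0L, c("A", "B")),
                     "oversample"),
    "'B'")
})

test_that("the published class imbalance oversamples to the majority count", {
  counts <- c(134, 36, 74, 122, 2, 52)  # one-tenth scale
  lab <- rep(paste0("c", 1:6), times = counts)
  fm <- feature_matrix(matrix(stats::runif(length(lab) * 2), ncol = 2), lab)
  up <- resample_classes(fm, "oversample", seed = 1)
  expect_identical(as.integer(table(up$labels)), rep(134L, 6))
  down <- resample_classes(fm, "undersample", seed = 1)
  expect_identical(as.integer(table(down$labels)), rep(2L, 6))
})

test_that("stratified split holds out the right number per class", {
  lab <- rep(c("A", "B"), each = 50)
  fm <- feature_matrix(matrix(stats::runif(200), ncol = 2), lab)
  sp <- stratified_split(fm, 0.2, seed = 4)
  expect_identical(as.integer(table(sp$test$labels)), c(10L, 10L))
  expect_identical(nrow(sp$train$values) + nrow(sp$test$values), 100L)
  # tiny classes keep at least one test row
  fm5 <- feature_matrix(matrix(stats::runif(20), ncol = 2),
                        rep(c("A", "B"), each = 5))
  sp5 <- stratified_split(fm5, 0.2, seed = 4)
  expect_identical(as.integer(table(sp5$test$labels)), c(1L, 1L))
  # determinism
  sp2 <- stratified_split(fm, 0.2, seed = 4)
  expect_identical(sp$test_rows, sp2$test_rows)
  expect_error(stratified_split(
    feature_matrix(matrix(1:3, 3, 1), c("A", "A", "B")), 0.2, 1),
    "fewer than 2")
})

test_that("dropping the minority class removes it and recodes labels", {
  fm <- feature_matrix(matrix(1:12, ncol = 2),
                       c("A", "A", "A", "B", "C", "C"))
  out <- drop_minority_class(fm)
  expect_identical(out$class_names, c("A", "C"))
  expect_identical(nrow(out$values), 5L)
  expect_identical(out$labels, c(0L, 0L, 0L, 1L, 1L))
})

test_that("feature matrices persist through the triplet text format", {
  fm <- separable_fm(4)
  stem <- file.path(withr::local_tempdir(), "fm")
  write_feature_matrix(fm, stem)
  back <- read_feature_matrix(stem)
  expect_equal(back$values, fm$values)
  expect_identical(back$labels, fm$labels)
  expect_identical(back$class_names, fm$class_names)
})
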