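# n-gram vocabulary, bag-of-n-grams matrices, class resampling and the
# stratified train/test split.

#' Build an n-gram vocabulary
#'
#' Collects every n-gram of the requested orders occurring in at least
#' one document. N-grams are token sequences joined by a single space and
#' never span documents. The term ordering is lexicographic, which makes
#' feature matrices bit-identical across runs and platforms.
#'
#' @param tokenized a `tokenized_corpus` from [clean_corpus()], or a bare
#'   list of token vectors.
#' @param ngram_orders integer subset of `c(1, 2, 3)`.
#' @return an object of class `vocabulary`: list with `terms` (ordered
#'   character vector) and `index` (named integer vector, term -> 1-based
#'   column).
#' @export
build_vocabulary <- function(tokenized, ngram_orders = 1L) {
  toks <- if (inherits(tokenized, "tokenized_corpus")) tokenized$tokens
          else tokenized
  fail_if(length(toks) < 1L, "need at least one document")
  ngram_orders <- sort(unique(as.integer(ngram_orders)))
  fail_if(!all(ngram_orders %in% 1:3), "ngram_orders must be within {1,2,3}")
  terms <- unique(unlist(lapply(toks, doc_ngrams, orders = ngram_orders),
                         use.names = FALSE))
  fail_if(length(terms) == 0L,
          paste("empty vocabulary: every document is empty after cleaning;",
                "relax the common/rare thresholds or the stop-word list"))
  terms <- sort(terms, method = "radix")
  structure(list(terms = terms,
                 index = stats::setNames(seq_along(terms), terms)),
            class = "vocabulary")
}

# all n-grams of the requested orders for one document's token vector
doc_ngrams <- function(tk, orders) {
  out <- character()
  L <- length(tk)
  for (n in orders) {
    if (L < n) next
    out <- c(out, if (n == 1L) tk else
      vapply(seq_len(L - n + 1L), function(i)
        paste(tk[i:(i + n - 1L)], collapse = " "), character(1)))
  }
  out
}

#' @export
print.vocabulary <- function(x, ...) {
  cat(sprintf("<vocabulary> %d terms\n", length(x$terms)))
  invisible(x)
}

#' Construct a documents-by-features count matrix
#'
#' Entry (d, t) is the number of occurrences of vocabulary term t in
#' document d; terms absent from the vocabulary are ignored, so fully
#' out-of-vocabulary (or empty) documents yield all-zero rows. Labels are
#' integer-coded 0..K-1 in sorted class-name order.
#'
#' @param tokenized a `tokenized_corpus` (labels required).
#' @param vocab a [build_vocabulary()] result.
#' @param ngram_orders orders used to expand each document; should match
#'   the orders the vocabulary was built with.
#' @return an object of class `feature_matrix`: list with `values`
#'   (numeric matrix, docs x features), `labels` (integer 0-based codes),
#'   `class_names`, `feature_names`.
#' @export
vectorize_counts <- function(tokenized, vocab, ngram_orders = 1L) {
  stopifnot(inherits(tokenized, "tokenized_corpus"),
            inherits(vocab, "vocabulary"))
  ngram_orders <- sort(unique(as.integer(ngram_orders)))
  n_doc <- length(tokenized$tokens)
  n_feat <- length(vocab$terms)
  values <- matrix(0, nrow = n_doc, ncol = n_feat,
                   dimnames = list(NULL, vocab$terms))
  for (d in seq_len(n_doc)) {
    grams <- doc_ngrams(tokenized$tokens[[d]], ngram_orders)
    if (length(grams) == 0L) next
    idx <- vocab$index[grams]
    idx <- idx[!is.na(idx)]
    if (length(idx) == 0L) next
    tab <- table(idx)
    values[d, as.integer(names(tab))] <- as.numeric(tab)
  }
  feature_matrix(values, tokenized$label, tokenized$label_set)
}

#' Assemble a feature matrix object
#'
#' @param values numeric docs-by-features matrix with nonnegative
#'   entries.
#' @param label character labels (length = rows) or integer 0-based codes.
#' @param class_names ordered class names; required when `label` is
#'   integer codes.
#' @return a `feature_matrix` object.
#' @export
feature_matrix <- function(values, label, class_names = NULL) {
  values <- as.matrix(values)
  fail_if(any(values < 0), "feature values must be nonnegative")
  if (is.null(colnames(values)))
    colnames(values) <- paste0("f", seq_len(ncol(values)))
  if (is.character(label)) {
    if (is.null(class_names)) class_names <- sort(unique(label), method = "radix")
    codes <- match(label, class_names) - 1L
    fail_if(anyNA(codes), "label outside class_names")
  } else {
    fail_if(is.null(class_names), "class_names required with coded labels")
    codes <- as.integer(label)
    fail_if(any(codes < 0L | codes >= length(class_names)),
            "label code out of range")
  }
  fail_if(nrow(values) != length(codes),
          "row count must equal label count")
  structure(list(values = values, labels = codes,
                 class_names = as.character(class_names),
                 feature_names = colnames(values)),
            class = "feature_matrix")
}

#' @export
dim.feature_matrix <- function(x) dim(x$values)

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> %d documents x %d features, %d classes\n",
              nrow(x$values), ncol(x$values), length(x$class_names)))
  invisible(x)
}

# subset rows of a feature_matrix, keeping metadata
fm_rows <- function(x, i) {
  feature_matrix(x$values[i, , drop = FALSE], x$labels[i], x$class_names)
}

#' Reweight counts by TF-IDF
#'
#' Smoothed inverse document frequency: each count is multiplied by
#' `1 + ln(N / (1 + df_t))` where N is the number of documents and df_t
#' the number of documents containing term t. Zero counts stay zero and
#' the factor is always positive, so nonnegativity is preserved.
#'
#' @param x a `feature_matrix` of raw counts.
#' @return a `feature_matrix` of TF-IDF weights.
#' @export
tfidf_weight <- function(x) {
  stopifnot(inherits(x, "feature_matrix"))
  N <- nrow(x$values)
  df <- colSums(x$values > 0)
  idf <- 1 + log(N / (1 + df))
  feature_matrix(sweep(x$values, 2L, idf, `*`), x$labels, x$class_names)
}

#' Balance class counts by resampling rows
#'
#' `oversample` draws rows of each minority class with replacement until
#' every class matches the majority count; `undersample` draws rows of
#' each majority class without replacement down to the minority count.
#' Either way the output class counts are exactly equal. Oversampling
#' never drops an input row; undersampling never duplicates one.
#'
#' @param x a `feature_matrix`; every class must have at least one row.
#' @param mode `"oversample"` or `"undersample"`.
#' @param seed integer seed; the same seed reproduces the same resample.
#' @return a `feature_matrix` with balanced classes.
#' @export
resample_classes <- function(x, mode = c("oversample", "undersample"),
                             seed = 1L) {
  stopifnot(inherits(x, "feature_matrix"))
  mode <- match.arg(mode)
  counts <- tabulate(x$labels + 1L, nbins = length(x$class_names))
  empty <- which(counts == 0L)
  fail_if(length(empty) > 0L,
          sprintf("class '%s' has no rows", x$class_names[empty[1L]]))
  target <- if (mode == "oversample") max(counts) else min(counts)
  with_seed(seed, {
    keep <- unlist(lapply(seq_along(x$class_names) - 1L, function(k) {
      rows <- which(x$labels == k)
      if (mode == "oversample") {
        if (length(rows) >= target) rows
        else c(rows, rows[sample.int(length(rows), target - length(rows),
                                     replace = TRUE)])
      } else {
        if (length(rows) == target) rows
        else sort(rows[sample.int(length(rows), target)])
      }
    }), use.names = FALSE)
    fm_rows(x, keep)
  })
}

#' Stratified train/test split
#'
#' Holds out `round(class_count * test_fraction)` rows per class (at
#' least 1), sampled without replacement under the seed; the remainder is
#' the training set. Train and test rows are disjoint and their union is
#' the input, so class proportions are preserved to within a row.
#'
#' @param x a `feature_matrix`; every class needs at least 2 rows.
#' @param test_fraction held-out fraction (default 0.2, the usual
#'   one-fifth evaluation split).
#' @param seed integer seed.
#' @return list with elements `train` and `test`, both `feature_matrix`,
#'   plus `test_rows` (the held-out row indices of `x`).
#' @export
stratified_split <- function(x, test_fraction = 0.2, seed = 1L) {
  stopifnot(inherits(x, "feature_matrix"))
  fail_if(!(test_fraction > 0 && test_fraction < 1),
          "test_fraction must be in (0, 1)")
  counts <- tabulate(x$labels + 1L, nbins = length(x$class_names))
  bad <- which(counts < 2L & counts > 0L)
  fail_if(length(bad) > 0L,
          sprintf("class '%s' has fewer than 2 rows; cannot split",
                  x$class_names[bad[1L]]))
  with_seed(seed, {
    test_idx <- unlist(lapply(seq_along(x$class_names) - 1L, function(k) {
      rows <- which(x$labels == k)
      if (length(rows) == 0L) return(integer())
      n_test <- max(1L, round(length(rows) * test_fraction))
      n_test <- min(n_test, length(rows) - 1L)  # keep >=1 training row
      sort(rows[sample.int(length(rows), n_test)])
    }), use.names = FALSE)
    train_idx <- setdiff(seq_len(nrow(x$values)), test_idx)
    list(train = fm_rows(x, train_idx), test = fm_rows(x, test_idx),
         test_rows = test_idx)
  })
}

#' Drop the smallest class from a feature matrix
#'
#' Imbalanced corpora are sometimes analysed both with and without the
#' minority class; this removes the class with the fewest rows (ties:
#' first in class-name order) and recodes the remaining labels.
#'
#' @param x a `feature_matrix`.
#' @return a `feature_matrix` without the minority class.
#' @export
drop_minority_class <- function(x) {
  stopifnot(inherits(x, "feature_matrix"))
  counts <- tabulate(x$labels + 1L, nbins = length(x$class_names))
  drop <- which.min(counts)
  keep_rows <- which(x$labels != (drop - 1L))
  keep_classes <- x$class_names[-drop]
  feature_matrix(x$values[keep_rows, , drop = FALSE],
                 x$class_names[x$labels[keep_rows] + 1L], keep_classes)
}

#' Persist / load a feature matrix as sparse-triplet text
#'
#' The matrix is written as a `(row, col, value)` triplet file with
#' sidecar files for labels, class names and feature names, all plain
#' text, so any tool can consume it.
#'
#' @param x a `feature_matrix`.
#' @param stem path stem; files `<stem>.mtx.tsv`, `<stem>.labels.txt`,
#'   `<stem>.classes.txt`, `<stem>.features.txt` are produced.
#' @return `stem`, invisibly.
#' @export
write_feature_matrix <- function(x, stem) {
  stopifnot(inherits(x, "feature_matrix"))
  nz <- which(x$values != 0, arr.ind = TRUE)
  trip <- data.frame(row = nz[, 1L], col = nz[, 2L],
                     value = x$values[nz])
  trip <- trip[order(trip$row, trip$col), , drop = FALSE]
  utils::write.table(cbind(dims = c(nrow(x$values), ncol(x$values), nrow(trip))),
                     paste0(stem, ".shape.txt"),
                     row.names = FALSE, col.names = FALSE)
  utils::write.table(trip, paste0(stem, ".mtx.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  writeLines(as.character(x$labels), paste0(stem, ".labels.txt"))
  writeLines(x$class_names, paste0(stem, ".classes.txt"))
  writeLines(x$feature_names, paste0(stem, ".features.txt"))
  invisible(stem)
}

#' @rdname write_feature_matrix
#' @export
read_feature_matrix <- function(stem) {
  shape <- as.integer(readLines(paste0(stem, ".shape.txt")))
  trip <- utils::read.table(paste0(stem, ".mtx.tsv"), sep = "\t",
                            header = TRUE)
  feats <- readLines(paste0(stem, ".features.txt"))
  values <- matrix(0, shape[1L], shape[2L], dimnames = list(NULL, feats))
  values[cbind(trip$row, trip$col)] <- trip$value
  feature_matrix(values,
                 as.integer(readLines(paste0(stem, ".labels.txt"))),
                 readLines(paste0(stem, ".classes.txt")))
}
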