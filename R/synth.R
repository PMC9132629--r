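# Seeded synthetic corpus generator. Stands in for the unavailable
# patient-emotion corpus: six imbalanced emotion classes, documents built
# from class-specific keyword pools mixed with a shared Zipf background
# vocabulary and numeric tokens, plus optional label noise.

TABLE1_CLASSES <- c("Angry", "Sad", "Fear", "Excited", "Bored", "Happy")
TABLE1_COUNTS  <- c(1343L, 358L, 742L, 1215L, 22L, 522L)

#' Synthetic corpus specification
#'
#' Describes the statistical structure of a generated corpus. Defaults
#' emulate the reference emotion corpus: six classes at its published
#' imbalance, documents of a few dozen tokens in which roughly a third of
#' the tokens come from the document's class keyword pool, the rest from
#' a shared Zipf-weighted background vocabulary with a sprinkling of
#' digit-string tokens, and a small label-noise rate.
#'
#' @param class_names ordered class names.
#' @param class_counts documents per class (same length).
#' @param keywords_per_class planted discriminative keywords per class;
#'   pools are disjoint across classes so ground truth is unambiguous.
#' @param keyword_rate probability a token is drawn from the document's
#'   class pool.
#' @param background_vocab_size size of the shared background vocabulary.
#' @param numeric_token_rate probability a token is a random digit
#'   string; `keyword_rate + numeric_token_rate` must be at most 1.
#' @param doc_length_mean,doc_length_min document length is
#'   `doc_length_min` plus a Poisson draw with mean
#'   `doc_length_mean - doc_length_min`.
#' @param label_noise_rate probability a document's label is reassigned
#'   uniformly over all classes, in \[0, 1).
#' @param seed integer seed.
#' @return an object of class `synth_spec`.
#' @export
synth_spec <- function(class_names = TABLE1_CLASSES,
                       class_counts = TABLE1_COUNTS,
                       keywords_per_class = 5L,
                       keyword_rate = 0.35,
                       background_vocab_size = 500L,
                       numeric_token_rate = 0.05,
                       doc_length_mean = 60,
                       doc_length_min = 5L,
                       label_noise_rate = 0.05,
                       seed = 1L) {
  fail_if(length(class_names) != length(class_counts),
          "class_names and class_counts must align")
  fail_if(any(class_counts < 1L), "class counts must be positive")
  fail_if(keyword_rate + numeric_token_rate > 1,
          "keyword_rate + numeric_token_rate must be <= 1")
  fail_if(!(label_noise_rate >= 0 && label_noise_rate < 1),
          "label_noise_rate must be in [0, 1)")
  fail_if(doc_length_min < 1L || doc_length_mean < doc_length_min,
          "need doc_length_mean >= doc_length_min >= 1")
  structure(list(class_names = as.character(class_names),
                 class_counts = as.integer(class_counts),
                 keywords_per_class = as.integer(keywords_per_class),
                 keyword_rate = keyword_rate,
                 background_vocab_size = as.integer(background_vocab_size),
                 numeric_token_rate = numeric_token_rate,
                 doc_length_mean = doc_length_mean,
                 doc_length_min = as.integer(doc_length_min),
                 label_noise_rate = label_noise_rate,
                 seed = as.integer(seed)),
            class = "synth_spec")
}

#' Default specification at the published class proportions
#'
#' Class counts are the published six-class counts
#' (1343, 358, 742, 1215, 22, 522 for Angry, Sad, Fear, Excited, Bored,
#' Happy) scaled by `scale`, rounded, and floored at 2 documents so every
#' class remains splittable.
#'
#' @param scale fraction in (0, 1].
#' @param ... further arguments passed to [synth_spec()].
#' @return a `synth_spec`.
#' @examples
#' default_table1_spec(0.1)$class_counts  # 134 36 74 122 2 52
#' @export
default_table1_spec <- function(scale = 1.0, ...) {
  fail_if(!(scale > 0 && scale <= 1), "scale must be in (0, 1]")
  synth_spec(class_counts = pmax(2L, as.integer(round(scale * TABLE1_COUNTS))),
             ...)
}

# deterministic keyword pool for one class: pure alphabetic tokens that
# survive punctuation stripping untouched
class_keywords <- function(class_name, keywords_per_class) {
  base <- gsub("[^a-z]", "", tolower(class_name))
  paste0(base, "kw", letters[seq_len(keywords_per_class)])
}

# Shared background vocabulary (bgaaa, bgaab, ...), Zipf-weighted by
# rank. The alphabet omits k and w so no background word can contain the
# "kw" marker that identifies planted keywords.
background_vocab <- function(size) {
  alph <- setdiff(letters, c("k", "w"))
  idx <- seq_len(size) - 1L
  paste0("bg",
         alph[idx %/% 576L + 1L],
         alph[(idx %/% 24L) %% 24L + 1L],
         alph[idx %% 24L + 1L])
}

#' Generate a synthetic labeled corpus
#'
#' Each document's tokens are drawn i.i.d.: with probability
#' `keyword_rate` uniformly from its class's keyword pool, with
#' probability `numeric_token_rate` a random 1-4 digit string, otherwise
#' from the shared background vocabulary with Zipf (1/rank) weights.
#' Document lengths are shifted Poisson. After generation each label is
#' independently reassigned uniformly over all classes with probability
#' `label_noise_rate`. Fully reproducible under `spec$seed`.
#'
#' @param spec a [synth_spec()].
#' @return a [corpus()] whose pre-noise class counts equal
#'   `spec$class_counts` exactly.
#' @export
generate_corpus <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  K <- length(spec$class_names)
  pools <- lapply(spec$class_names, class_keywords,
                  keywords_per_class = spec$keywords_per_class)
  bg <- background_vocab(spec$background_vocab_size)
  bg_w <- 1 / seq_along(bg)
  with_seed(spec$seed, {
    labels <- rep(spec$class_names, times = spec$class_counts)
    n <- length(labels)
    texts <- character(n)
    lens <- spec$doc_length_min +
      stats::rpois(n, spec$doc_length_mean - spec$doc_length_min)
    for (d in seq_len(n)) {
      L <- lens[d]
      pool <- pools[[match(labels[d], spec$class_names)]]
      u <- stats::runif(L)
      tok <- character(L)
      kw <- u < spec$keyword_rate
      num <- !kw & u < spec$keyword_rate + spec$numeric_token_rate
      oth <- !kw & !num
      if (any(kw))
        tok[kw] <- pool[sample.int(length(pool), sum(kw), replace = TRUE)]
      if (any(num))
        tok[num] <- vapply(seq_len(sum(num)), function(i)
          paste(sample(0:9, sample.int(4L, 1L), replace = TRUE),
                collapse = ""), character(1))
      if (any(oth))
        tok[oth] <- bg[sample.int(length(bg), sum(oth),
                                  replace = TRUE, prob = bg_w)]
      texts[d] <- paste(tok, collapse = " ")
    }
    if (spec$label_noise_rate > 0) {
      flip <- stats::runif(n) < spec$label_noise_rate
      if (any(flip))
        labels[flip] <- spec$class_names[sample.int(K, sum(flip),
                                                    replace = TRUE)]
    }
    corpus(texts, labels)
  })
}

#' Vocabulary indices of the planted keywords
#'
#' The generator's ground truth for feature-recovery experiments: the
#' (1-based) column indices of every planted keyword unigram that made it
#' into the given vocabulary. Keywords filtered out during cleaning (for
#' example, rarer than the rare-term threshold) are simply absent.
#'
#' @param spec the [synth_spec()] the corpus came from.
#' @param vocab a [build_vocabulary()] result.
#' @return integer vector of vocabulary column indices.
#' @export
ground_truth_features <- function(spec, vocab) {
  stopifnot(inherits(spec, "synth_spec"), inherits(vocab, "vocabulary"))
  kws <- unlist(lapply(spec$class_names, class_keywords,
                       keywords_per_class = spec$keywords_per_class),
                use.names = FALSE)
  idx <- vocab$index[kws]
  sort(as.integer(idx[!is.na(idx)]))
}
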