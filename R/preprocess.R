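# Five-step cleaning chain: lowercase -> strip punctuation -> tokenize ->
# stop words -> common terms -> rare terms. Order is fixed so the two
# frequency filters operate on stop-word-free text.

#' Lowercase a text
#'
#' First cleaning step: case folding, so "Happy" and "happy" are one term.
#' Idempotent.
#' @param text character vector.
#' @return character vector of the same length.
#' @export
to_lowercase <- function(text) tolower(text)

#' Replace punctuation with spaces
#'
#' Every punctuation character becomes a single space rather than being
#' deleted, so adjacent words never fuse ("end.start" tokenizes to two
#' tokens, "don't" to `don t`). Idempotent.
#' @param text character vector.
#' @return character vector with punctuation blanked.
#' @export
strip_punctuation <- function(text) gsub("[[:punct:]]", " ", text)

#' Tokenize on whitespace
#'
#' Splits on runs of whitespace; never yields empty tokens.
#' @param text a single string.
#' @return character vector of tokens (possibly empty).
#' @export
tokenize <- function(text) {
  if (is.na(text) || !nzchar(trimws(text))) return(character())
  strsplit(trimws(text), "[[:space:]]+")[[1]]
}

#' Remove stop words from a token sequence
#'
#' Function words ("the", "is", ...) carry little emotional signal; tokens
#' present in the list are dropped, order of the rest preserved.
#' @param tokens character vector of lowercase tokens.
#' @param stopword_list character vector (treated as a set).
#' @return filtered token vector.
#' @export
remove_stopwords <- function(tokens, stopword_list) {
  tokens[!(tokens %in% stopword_list)]
}

#' The packaged English stop-word list
#'
#' A standard English function-word list shipped as a plain-text resource
#' (one token per line) so no download is needed at run time. Users may
#' supply their own list to [clean_config()] instead.
#' @return character vector of stop words.
#' @export
default_stopwords <- function() {
  path <- system.file("extdata", "stopwords_en.txt", package = "emodrop")
  if (!nzchar(path)) path <- file.path("inst", "extdata", "stopwords_en.txt")
  readLines(path, warn = FALSE)
}

#' Remove corpus-wide common terms
#'
#' Drops every token whose document frequency (fraction of documents that
#' contain it at least once) strictly exceeds `common_df_threshold`.
#' Terms shared by nearly all documents separate nothing and only add
#' vocabulary overlap.
#'
#' @param corpus_tokens list of token vectors, one per document.
#' @param common_df_threshold fraction in (0, 1]; at the boundary 1.0
#'   nothing is ever removed (df cannot exceed 1).
#' @return list of filtered token vectors, same length and order.
#' @export
remove_common_terms <- function(corpus_tokens, common_df_threshold = 0.90) {
  fail_if(length(corpus_tokens) < 1L, "need at least one document")
  fail_if(!(common_df_threshold > 0 && common_df_threshold <= 1),
          "common_df_threshold must be in (0, 1]")
  n_docs <- length(corpus_tokens)
  df <- table(unlist(lapply(corpus_tokens, unique), use.names = FALSE)) / n_docs
  common <- names(df)[as.numeric(df) > common_df_threshold]
  if (length(common) == 0L) return(corpus_tokens)
  lapply(corpus_tokens, function(tk) tk[!(tk %in% common)])
}

#' Remove corpus-wide rare terms
#'
#' Drops every token whose total occurrence count across the corpus is
#' below `rare_min_count`. The default of 3 removes terms appearing just
#' once or twice — rare enough that noise overwhelms their signal.
#'
#' @param corpus_tokens list of token vectors, one per document.
#' @param rare_min_count integer >= 1; with 1, nothing is removed.
#' @return list of filtered token vectors, same length and order.
#' @export
remove_rare_terms <- function(corpus_tokens, rare_min_count = 3L) {
  fail_if(rare_min_count < 1L, "rare_min_count must be >= 1")
  if (rare_min_count == 1L) return(corpus_tokens)
  cnt <- table(unlist(corpus_tokens, use.names = FALSE))
  rare <- names(cnt)[as.numeric(cnt) < rare_min_count]
  if (length(rare) == 0L) return(corpus_tokens)
  lapply(corpus_tokens, function(tk) tk[!(tk %in% rare)])
}

#' Cleaning configuration
#'
#' Bundles the tunable parameters of the cleaning chain. Any step can be
#' disabled; by default all five run.
#'
#' @param stopword_list character vector; defaults to the packaged
#'   English list.
#' @param common_df_threshold document-frequency cutoff in (0, 1] for
#'   common-term removal (default 0.90).
#' @param rare_min_count minimum total corpus count to keep a term
#'   (default 3: terms seen once or twice are dropped).
#' @param steps_enabled named logical vector switching individual steps;
#'   names among `lowercase`, `punctuation`, `stopwords`, `common`,
#'   `rare`.
#' @return an object of class `clean_config`.
#' @export
clean_config <- function(stopword_list = default_stopwords(),
                         common_df_threshold = 0.90,
                         rare_min_count = 3L,
                         steps_enabled = c(lowercase = TRUE,
                                           punctuation = TRUE,
                                           stopwords = TRUE,
                                           common = TRUE, rare = TRUE)) {
  fail_if(!(common_df_threshold > 0 && common_df_threshold <= 1),
          "common_df_threshold must be in (0, 1]")
  fail_if(rare_min_count < 1L, "rare_min_count must be >= 1")
  steps <- c(lowercase = TRUE, punctuation = TRUE, stopwords = TRUE,
             common = TRUE, rare = TRUE)
  steps[names(steps_enabled)] <- steps_enabled
  structure(list(stopword_list = as.character(stopword_list),
                 common_df_threshold = common_df_threshold,
                 rare_min_count = as.integer(rare_min_count),
                 steps_enabled = steps),
            class = "clean_config")
}

#' Clean a corpus into tokenized documents
#'
#' Applies, in order: lowercase, punctuation stripping, whitespace
#' tokenization, stop-word removal, common-term removal (document
#' frequency above threshold), rare-term removal (total count below
#' threshold). Documents that end up empty are retained as empty token
#' vectors so labels stay aligned with the original class counts. The
#' chain is idempotent on its own output.
#'
#' @param x a [corpus()].
#' @param config a [clean_config()].
#' @return an object of class `tokenized_corpus`: list with `tokens`
#'   (list of character vectors), `label` (character vector) and
#'   `label_set`.
#' @export
clean_corpus <- function(x, config = clean_config()) {
  stopifnot(inherits(x, "corpus"), inherits(config, "clean_config"))
  txt <- x$text
  on_ <- config$steps_enabled
  if (on_[["lowercase"]])   txt <- to_lowercase(txt)
  if (on_[["punctuation"]]) txt <- strip_punctuation(txt)
  toks <- lapply(txt, tokenize)
  if (on_[["stopwords"]])
    toks <- lapply(toks, remove_stopwords, stopword_list = config$stopword_list)
  if (on_[["common"]] && length(toks) >= 1L)
    toks <- remove_common_terms(toks, config$common_df_threshold)
  if (on_[["rare"]])
    toks <- remove_rare_terms(toks, config$rare_min_count)
  structure(list(tokens = toks, label = x$label, label_set = x$label_set),
            class = "tokenized_corpus")
}

#' @export
length.tokenized_corpus <- function(x) length(x$tokens)

#' @export
print.tokenized_corpus <- function(x, ...) {
  cat(sprintf("<tokenized_corpus> %d documents, %d classes, %d tokens\n",
              length(x), length(x$label_set),
              sum(lengths(x$tokens))))
  invisible(x)
}
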