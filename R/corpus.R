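#' Construct a labeled text corpus
#'
#' A corpus is the pipeline's input container: an ordered set of documents,
#' each a raw (uncleaned) text with a non-empty emotion class label. The
#' label set is the sorted unique set of labels present.
#'
#' @param text character vector of raw document texts (may contain empty
#'   strings).
#' @param label character vector of class labels, same length as `text`;
#'   every label must be non-empty.
#' @return an object of class `corpus`: a list with elements `text`,
#'   `label` (character vectors) and `label_set` (sorted unique labels).
#' @examples
#' corpus(c("happy day", "so sad"), c("Happy", "Sad"))
#' @export
corpus <- function(text = character(), label = character()) {
  text <- as.character(text)
  label <- as.character(label)
  fail_if(length(text) != length(label),
          "text and label must have the same length")
  fail_if(any(is.na(label)) || any(!nzchar(label)),
          "every document label must be a non-empty string")
  text[is.na(text)] <- ""
  structure(
    list(text = text, label = label,
         label_set = sort(unique(label), method = "radix")),
    class = "corpus"
  )
}

#' @export
length.corpus <- function(x) length(x$text)

#' @export
print.corpus <- function(x, ...) {
  cat(sprintf("<corpus> %d documents, %d classes\n", length(x),
              length(x$label_set)))
  if (length(x$label_set)) {
    d <- class_distribution(x)
    cat(paste(sprintf("  %-12s %d", names(d), d), collapse = "\n"), "\n")
  }
  invisible(x)
}

#' Read a labeled corpus from disk
#'
#' Two plain-text formats are supported: `"delimited"` (CSV dialect with
#' quoting, one header row) and `"record_per_line"` (JSON lines, one
#' object per line). Document order in the file is preserved.
#'
#' @param path file to read.
#' @param format_tag `"delimited"` or `"record_per_line"`.
#' @param text_field,label_field names of the two required fields.
#' @return a [corpus()].
#' @seealso [write_corpus()]
#' @export
read_corpus <- function(path, format_tag = c("delimited", "record_per_line"),
                        text_field = "text", label_field = "label") {
  format_tag <- match.arg(format_tag)
  fail_if(!file.exists(path), sprintf("file not found: %s", path))
  if (format_tag == "delimited") {
    if (file.size(path) == 0L) return(corpus())
    df <- utils::read.csv(path, stringsAsFactors = FALSE,
                          colClasses = "character", check.names = FALSE)
    if (nrow(df) == 0L && !all(c(text_field, label_field) %in% names(df)))
      return(corpus())
    for (f in c(text_field, label_field))
      fail_if(!f %in% names(df),
              sprintf("format error: field '%s' absent from %s", f, path))
    bad <- which(is.na(df[[label_field]]) | !nzchar(df[[label_field]]))
    fail_if(length(bad) > 0L,
            sprintf("format error: record %d is missing field '%s'",
                    bad[1L], label_field))
    txt <- df[[text_field]]
    txt[is.na(txt)] <- ""
    corpus(txt, df[[label_field]])
  } else {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    if (length(lines) == 0L) return(corpus())
    txt <- character(length(lines)); lab <- character(length(lines))
    for (i in seq_along(lines)) {
      rec <- jsonlite::fromJSON(lines[[i]])
      fail_if(!text_field %in% names(rec),
              sprintf("format error: record %d is missing field '%s'",
                      i, text_field))
      fail_if(!label_field %in% names(rec) || !nzchar(rec[[label_field]]),
              sprintf("format error: record %d is missing field '%s'",
                      i, label_field))
      txt[i] <- rec[[text_field]]; lab[i] <- rec[[label_field]]
    }
    corpus(txt, lab)
  }
}

#' Write a corpus to disk
#'
#' Inverse of [read_corpus()]: a write followed by a read reproduces the
#' texts, labels and document order exactly. Embedded delimiters and
#' quotes survive via CSV quoting / JSON escaping.
#'
#' @param x a [corpus()].
#' @param path destination file.
#' @param format_tag `"delimited"` or `"record_per_line"`.
#' @param text_field,label_field field names to emit.
#' @return `path`, invisibly.
#' @export
write_corpus <- function(x, path,
                         format_tag = c("delimited", "record_per_line"),
                         text_field = "text", label_field = "label") {
  stopifnot(inherits(x, "corpus"))
  format_tag <- match.arg(format_tag)
  if (format_tag == "delimited") {
    df <- data.frame(a = x$text, b = x$label, stringsAsFactors = FALSE)
    names(df) <- c(text_field, label_field)
    utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
  } else {
    con <- file(path, "w"); on.exit(close(con))
    for (i in seq_along(x$text)) {
      rec <- stats::setNames(list(x$text[i], x$label[i]),
                             c(text_field, label_field))
      writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE), con)
    }
  }
  invisible(path)
}

#' Class distribution of a corpus
#'
#' Per-class document counts, in sorted class order; the counts always sum
#' to the number of documents. Mirrors the kind of class-imbalance table
#' that motivates resampling (one emotion class can outnumber another by
#' a factor of sixty in real patient-emotion corpora).
#'
#' @param x a [corpus()].
#' @return named integer vector of counts (empty for an empty corpus).
#' @export
class_distribution <- function(x) {
  stopifnot(inherits(x, "corpus"))
  if (length(x) == 0L) return(stats::setNames(integer(), character()))
  tab <- table(factor(x$label, levels = x$label_set))
  stats::setNames(as.integer(tab), names(tab))
}

#' Corpus-level descriptive statistics
#'
#' Counts computed on the raw, uncleaned texts with whitespace
#' tokenization (the inventory one reports about a dataset before any
#' modeling): total words, total characters (including internal
#' whitespace), digit-only tokens, and globally-unique uni/bi/trigrams.
#' N-grams are taken within documents only — they never span a document
#' boundary — while uniqueness is global across the corpus.
#'
#' @param x a [corpus()].
#' @param numeric_pattern regex defining a "numeric" token; the default
#'   matches digits-only tokens (no sign, no decimal point).
#' @return an object of class `corpus_stats`: a named list with counts
#'   `n_documents`, `n_words`, `n_characters`, `n_numerics`,
#'   `n_unique_unigrams`, `n_unique_bigrams`, `n_unique_trigrams`.
#' @examples
#' corpus_stats(corpus("a b a", "x"))  # 3 words, 5 chars, 2/2/1 n-grams
#' @export
corpus_stats <- function(x, numeric_pattern = "^[0-9]+$") {
  stopifnot(inherits(x, "corpus"))
  toks <- lapply(x$text, tokenize)
  ngrams <- function(tt, n) {
    unlist(lapply(tt, function(tk) {
      L <- length(tk)
      if (L < n) return(character())
      if (n == 1L) return(tk)
      vapply(seq_len(L - n + 1L), function(i)
        paste(tk[i:(i + n - 1L)], collapse = " "), character(1))
    }), use.names = FALSE)
  }
  uni <- ngrams(toks, 1L)
  structure(list(
    n_documents       = length(x),
    n_words           = length(uni),
    n_characters      = sum(nchar(x$text)),
    n_numerics        = sum(grepl(numeric_pattern, uni)),
    n_unique_unigrams = length(unique(uni)),
    n_unique_bigrams  = length(unique(ngrams(toks, 2L))),
    n_unique_trigrams = length(unique(ngrams(toks, 3L)))
  ), class = "corpus_stats")
}

#' @export
print.corpus_stats <- function(x, ...) {
  keys <- c(n_documents = "Documents", n_words = "Number of words",
            n_characters = "Characters", n_numerics = "Numerics",
            n_unique_unigrams = "Unique unigrams",
            n_unique_bigrams = "Unique bigrams",
            n_unique_trigrams = "Unique trigrams")
  for (k in names(keys))
    cat(sprintf("%-17s %d\n", keys[[k]], x[[k]]))
  invisible(x)
}

#' Write corpus statistics as a machine-readable report
#'
#' @param stats a `corpus_stats` object.
#' @param path destination JSON file.
#' @return `path`, invisibly.
#' @export
write_corpus_stats <- function(stats, path) {
  stopifnot(inherits(stats, "corpus_stats"))
  jsonlite::write_json(unclass(stats), path, auto_unbox = TRUE)
  invisible(path)
}
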