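# End-to-end orchestration: clean -> vectorize -> split -> resample
# (training rows only) -> IWD feature selection -> BPNN hidden-size
# selection and training -> one-shot evaluation on the held-out split.
# A single global seed fans out into per-stage seeds (stage_seed), so the
# whole run — and any stage in isolation — is reproducible.

pipeline_fields <- c("input_path", "input_format", "text_field",
                     "label_field", "synth", "clean", "ngram_orders",
                     "weighting", "resample_mode", "test_fraction",
                     "drop_minority_class", "use_iwd", "iwd", "bpnn",
                     "out_dir", "seed")

#' Pipeline configuration
#'
#' Collects every stage's parameters. Input is either a corpus file
#' (`input_path` + `input_format`) or a synthetic-corpus specification
#' (`synth`); exactly one must be given when the pipeline runs.
#'
#' @param input_path corpus file, or `NULL`.
#' @param input_format `"delimited"` or `"record_per_line"`.
#' @param text_field,label_field record field names.
#' @param synth a [synth_spec()] (or argument list for one), or `NULL`.
#' @param clean a [clean_config()] or argument list.
#' @param ngram_orders n-gram orders for the modeling vocabulary.
#' @param weighting `"counts"` (default) or `"tfidf"`.
#' @param resample_mode `"oversample"`, `"undersample"` or `"none"`;
#'   applied to training rows only, after the split, so duplicated rows
#'   can never leak into the test set.
#' @param test_fraction held-out fraction (default 0.2).
#' @param drop_minority_class drop the smallest class before modeling.
#' @param use_iwd run the water-drop feature selection; with `FALSE` the
#'   model uses all features.
#' @param iwd an [iwd_params()] or argument list.
#' @param bpnn a [bpnn_config()] or argument list.
#' @param out_dir directory for persisted artifacts, or `NULL` to skip
#'   persistence.
#' @param seed single global seed; all stage seeds derive from it.
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(input_path = NULL,
                            input_format = "delimited",
                            text_field = "text", label_field = "label",
                            synth = NULL,
                            clean = clean_config(),
                            ngram_orders = 1L,
                            weighting = c("counts", "tfidf"),
                            resample_mode = "oversample",
                            test_fraction = 0.2,
                            drop_minority_class = FALSE,
                            use_iwd = TRUE,
                            iwd = iwd_params(),
                            bpnn = bpnn_config(),
                            out_dir = NULL,
                            seed = 1L) {
  weighting <- match.arg(weighting)
  fail_if(!resample_mode %in% c("oversample", "undersample", "none"),
          "resample_mode must be oversample, undersample or none")
  fail_if(!(test_fraction > 0 && test_fraction < 1),
          "test_fraction must be in (0, 1)")
  fail_if(!all(ngram_orders %in% 1:3), "ngram_orders must be within {1,2,3}")
  if (is.list(synth) && !inherits(synth, "synth_spec"))
    synth <- do.call(synth_spec, synth)
  if (is.list(clean) && !inherits(clean, "clean_config"))
    clean <- do.call(clean_config, clean)
  if (is.list(iwd) && !inherits(iwd, "iwd_params"))
    iwd <- do.call(iwd_params, iwd)
  if (is.list(bpnn) && !inherits(bpnn, "bpnn_config"))
    bpnn <- do.call(bpnn_config, bpnn)
  fail_if(!is.null(synth) && !inherits(synth, "synth_spec"),
          "synth must be a synth_spec or argument list")
  structure(list(input_path = input_path, input_format = input_format,
                 text_field = text_field, label_field = label_field,
                 synth = synth, clean = clean,
                 ngram_orders = sort(unique(as.integer(ngram_orders))),
                 weighting = weighting, resample_mode = resample_mode,
                 test_fraction = test_fraction,
                 drop_minority_class = isTRUE(drop_minority_class),
                 use_iwd = isTRUE(use_iwd), iwd = iwd, bpnn = bpnn,
                 out_dir = out_dir, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Validate a raw pipeline configuration
#'
#' Accepts a JSON file path, a JSON string, or a plain named list.
#' Unknown keys are rejected (no silent ignore), every invariant is
#' checked by the stage constructors, and the fully defaulted
#' configuration is returned.
#'
#' @param raw path, JSON string, or named list.
#' @return a [pipeline_config()]; invalid input raises an error naming
#'   the offending field(s).
#' @export
validate_config <- function(raw) {
  if (is.character(raw) && length(raw) == 1L) {
    raw <- if (file.exists(raw)) jsonlite::fromJSON(raw, simplifyVector = TRUE)
           else jsonlite::fromJSON(raw, simplifyVector = TRUE)
  }
  fail_if(!is.list(raw), "configuration must be a named list or JSON object")
  unknown <- setdiff(names(raw), pipeline_fields)
  fail_if(length(unknown) > 0L,
          sprintf("unknown configuration key(s): %s",
                  paste(unknown, collapse = ", ")))
  do.call(pipeline_config, raw)
}

#' Run the full emotion-classification pipeline
#'
#' Stage order: load or generate the corpus; clean; build the n-gram
#' vocabulary and count (or TF-IDF) matrix; optionally drop the minority
#' class; stratified 80/20 split; resample the training rows; IWD
#' feature selection on the training matrix; hidden-size selection and
#' final BPNN; single evaluation on the untouched test split. With an
#' `out_dir`, every intermediate artifact (cleaned corpus, vocabulary,
#' matrices, selected subset, convergence trace, model, RMSE history,
#' confusion matrix, report, the echoed configuration) is persisted as
#' plain text, so every number in the report is recomputable. Identical
#' configuration and seed give byte-identical persisted reports.
#'
#' @param config a [pipeline_config()].
#' @param quiet suppress per-stage progress messages.
#' @return an object of class `pipeline_result`: list with `report` (an
#'   `eval_report`), `model`, `selection` (`iwd_result` or `NULL`),
#'   `hidden_table`, `vocabulary`, `config`, `timings`.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  fail_if(is.null(config$input_path) && is.null(config$synth),
          "stage input: provide input_path or a synth spec")
  t0 <- proc.time()[["elapsed"]]
  timings <- list()
  say <- function(...) if (!quiet) message(sprintf(...))
  tick <- function(stage) {
    t1 <- proc.time()[["elapsed"]]
    timings[[stage]] <<- t1 - t0
    t0 <<- t1
  }
  run_stage <- function(stage, expr) {
    out <- tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
           call. = FALSE))
    tick(stage)
    out
  }

  crp <- run_stage("input", {
    if (!is.null(config$synth)) {
      sp <- config$synth
      sp$seed <- stage_seed(config$seed, "corpus")
      say("generating synthetic corpus (%d docs)", sum(sp$class_counts))
      generate_corpus(sp)
    } else {
      say("reading corpus from %s", config$input_path)
      read_corpus(config$input_path, config$input_format,
                  config$text_field, config$label_field)
    }
  })

  tokenized <- run_stage("clean", clean_corpus(crp, config$clean))
  say("cleaned: %d documents, %d tokens", length(tokenized),
      sum(lengths(tokenized$tokens)))

  fm <- run_stage("vectorize", {
    vocab <- build_vocabulary(tokenized, config$ngram_orders)
    m <- vectorize_counts(tokenized, vocab, config$ngram_orders)
    if (config$weighting == "tfidf") m <- tfidf_weight(m)
    attr(m, "vocab") <- vocab
    m
  })
  vocab <- attr(fm, "vocab")
  say("vectorized: %d x %d", nrow(fm$values), ncol(fm$values))

  if (config$drop_minority_class)
    fm <- run_stage("drop_minority", drop_minority_class(fm))

  split <- run_stage("split",
    stratified_split(fm, config$test_fraction,
                     stage_seed(config$seed, "split")))
  train <- split$train; test <- split$test
  say("split: %d train / %d test", nrow(train$values), nrow(test$values))

  if (config$resample_mode != "none") {
    train <- run_stage("resample",
      resample_classes(train, config$resample_mode,
                       stage_seed(config$seed, "resample")))
    say("resampled (%s): %d training rows", config$resample_mode,
        nrow(train$values))
  }

  selection <- NULL
  if (config$use_iwd) {
    ip <- config$iwd
    ip$seed <- stage_seed(config$seed, "iwd")
    selection <- run_stage("iwd_select", iwd_select(train, ip))
    say("IWD selected %d / %d features (fitness %.4f)",
        length(selection$indices), selection$n_features, selection$fitness)
    train <- fm_rows_cols(train, selection$indices)
    test <- fm_rows_cols(test, selection$indices)
  }

  bp <- config$bpnn
  bp$seed <- stage_seed(config$seed, "bpnn")
  hs <- run_stage("hidden_size", select_hidden_size(train, bp))
  model <- hs$models[[as.character(hs$best)]]
  say("hidden size %d chosen (validation RMSE %.4f)", hs$best,
      min(hs$table$val_rmse))

  report <- run_stage("evaluate", evaluate_model(model, test))
  say("test accuracy %.4f, macro F %.4f", report$overall_accuracy,
      report$macro_f_measure)

  result <- structure(list(report = report, model = model,
                           selection = selection, hidden_table = hs$table,
                           vocabulary = vocab, config = config,
                           timings = timings),
                      class = "pipeline_result")
  if (!is.null(config$out_dir))
    run_stage("persist", persist_pipeline(result, crp, tokenized, train,
                                          test, config$out_dir))
  result
}

# column subset of a feature matrix (keeps labels)
fm_rows_cols <- function(x, cols) {
  feature_matrix(x$values[, cols, drop = FALSE], x$labels, x$class_names)
}

persist_pipeline <- function(result, crp, tokenized, train, test, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(out_dir, ...)
  write_corpus(crp, p("corpus.csv"), "delimited")
  write_corpus(corpus(vapply(tokenized$tokens, paste, character(1),
                             collapse = " "),
                      tokenized$label),
               p("cleaned.csv"), "delimited")
  writeLines(result$vocabulary$terms, p("vocabulary.txt"))
  write_feature_matrix(train, p("train"))
  write_feature_matrix(test, p("test"))
  if (!is.null(result$selection)) write_iwd_result(result$selection, p("iwd"))
  else writeLines("all", p("iwd.subset.tsv"))
  write_bpnn(result$model, p("model.json"))
  utils::write.table(result$model$history, p("rmse_history.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(result$hidden_table, p("hidden_sizes.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  write_eval_report(result$report, p("final"))
  cfg <- result$config
  cfg$clean$stopword_list <- NULL  # bulky; the packaged list is implied
  jsonlite::write_json(rapply(unclass(cfg), unclass, how = "replace"),
                       p("config_echo.json"), auto_unbox = TRUE,
                       digits = NA, null = "null", force = TRUE)
  invisible(out_dir)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("Emotion-classification pipeline result\n")
  if (!is.null(x$selection))
    cat(sprintf("  features: %d of %d (IWD, fitness %.4f)\n",
                length(x$selection$indices), x$selection$n_features,
                x$selection$fitness))
  else cat("  features: all (IWD bypassed)\n")
  cat(sprintf("  hidden size: %d\n", x$model$n_hidden))
  print(x$report)
  invisible(x)
}

#' @export
summary.pipeline_result <- function(object, ...) {
  print(object)
  cat("Stage timings (s):\n")
  print(round(unlist(object$timings), 2))
  invisible(object)
}
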