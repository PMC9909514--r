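#' Prepare a modelling dataset from a cohort
#'
#' Runs every recording through cleaning (noise gating, voice activity
#' detection, trimming), then extracts both representations used by the
#' models: utterance-level MFCC statistics for the classical baselines and
#' fixed-size log-Mel segments for the CNN. Recordings flagged low quality
#' are excluded. Audio is processed one recording at a time so arbitrarily
#' large cohorts fit in memory.
#'
#' @param cohort a [cohort_config()] (the cohort is synthesized on the
#'   fly), or a list with `manifest` and `audio_dir` pointing at WAV files
#'   with a `path` column in the manifest
#' @param spectro a [spectro_config()]
#' @param mfcc_cfg an [mfcc_config()]
#' @param arch the [cnn_architecture()] the segments are meant for
#' @param max_segments_per_participant cap on segments per recording used
#'   for CNN *training* (evenly spaced across the utterance); `Inf` keeps
#'   all
#' @param max_eval_segments_per_participant cap on segments stored for
#'   validation and test scoring; more evaluation segments give steadier
#'   participant-level averages at negligible cost
#' @param min_speech_s low-quality exclusion threshold (seconds of speech)
#' @param preprocess_args list of extra arguments for
#'   [preprocess_recording()]
#' @return a `speech_dataset`: `manifest` (retained rows), `features`
#'   (matrix aligned with the manifest), `segments` (named list keyed
#'   `participant|task`), `arch`, `dropped` (excluded manifest rows)
#' @export
prepare_dataset <- function(cohort, spectro = spectro_config(),
                            mfcc_cfg = mfcc_config(),
                            arch = cnn_architecture(),
                            max_segments_per_participant = 4,
                            max_eval_segments_per_participant = 12,
                            min_speech_s = 2, preprocess_args = list()) {
  store_cap <- max(max_segments_per_participant,
                   max_eval_segments_per_participant)
  process_one <- function(rec) {
    clean <- do.call(preprocess_recording,
                     c(list(rec, min_speech_s = min_speech_s),
                       preprocess_args))
    if (isTRUE(attr(clean, "low_quality")))
      return(list(dropped = TRUE))
    lm <- logmel(clean, spectro)
    segs <- segment_logmel(lm, spectro, participant_id = rec$participant_id,
                           task = rec$task,
                           label = as.numeric(rec$group == "MDD"))
    if (is.finite(store_cap) && length(segs) > store_cap) {
      keep <- unique(round(seq(1, length(segs), length.out = store_cap)))
      segs <- segs[keep]
    }
    co <- mfcc(clean, mfcc_cfg)
    list(dropped = FALSE, segments = segs, features = summarize_mfcc(co),
         log = attr(clean, "log"))
  }
  if (inherits(cohort, "cohort_config")) {
    gen <- generate_cohort(cohort, process = process_one)
    manifest <- gen$manifest
    results <- gen$recordings
  } else {
    manifest <- cohort$manifest
    paths <- file.path(cohort$audio_dir %||% ".", manifest$path)
    missing <- !file.exists(paths)
    if (any(missing)) {
      msg <- paste("missing audio:",
                   paste(utils::head(manifest$path[missing], 10),
                         collapse = ", "))
      if (mean(missing) > 0.1)
        stop(msg, " (", sum(missing), " of ", length(paths),
             " files; aborting)")
      warning(msg, " (skipped)")
    }
    results <- vector("list", nrow(manifest))
    for (i in seq_len(nrow(manifest))) {
      if (missing[i]) {
        results[[i]] <- list(dropped = TRUE)
        next
      }
      w <- read_wav(paths[i])
      rec <- audio_rec(w$samples, w$sample_rate,
                       manifest$participant_id[i], manifest$group[i],
                       manifest$task[i])
      results[[i]] <- process_one(rec)
    }
  }
  dropped <- vapply(results, function(r) isTRUE(r$dropped), logical(1))
  kept <- which(!dropped)
  plog <- data.frame(
    participant_id = manifest$participant_id, task = manifest$task,
    input_s = vapply(results, function(r)
      if (is.null(r$log)) NA_real_ else r$log$input_s, numeric(1)),
    speech_s = vapply(results, function(r)
      if (is.null(r$log)) NA_real_ else r$log$speech_s, numeric(1)),
    dropped = dropped, stringsAsFactors = FALSE)
  features <- do.call(rbind, lapply(results[kept], `[[`, "features"))
  segments <- lapply(results[kept], `[[`, "segments")
  names(segments) <- paste(manifest$participant_id[kept],
                           manifest$task[kept], sep = "|")
  structure(list(manifest = manifest[kept, , drop = FALSE],
                 features = features, segments = segments, arch = arch,
                 train_segment_cap = max_segments_per_participant,
                 processing_log = plog,
                 dropped = manifest[dropped, , drop = FALSE]),
            class = "speech_dataset")
}

#' @export
print.speech_dataset <- function(x, ...) {
  cat(sprintf("<speech_dataset> %d recordings (%d dropped), %d segments, %d features\n",
              nrow(x$manifest), nrow(x$dropped),
              sum(lengths(x$segments)), ncol(x$features)))
  invisible(x)
}

#' Assemble a fully materialized run configuration
#'
#' One auditable object holding every tunable of the pipeline. All defaults
#' are filled in on construction so no implicit defaults exist downstream.
#'
#' @param cohort a [cohort_config()]
#' @param spectro a [spectro_config()]
#' @param augment an [augment_config()] (or `NULL` to disable)
#' @param mfcc an [mfcc_config()]
#' @param arch a [cnn_architecture()]
#' @param train a [train_config()]
#' @param models models to evaluate
#' @param n_folds cross-validation folds
#' @param max_segments_per_participant segment cap, see [prepare_dataset()]
#' @param seed root seed for the whole run
#' @param out_dir artifact directory
#' @return a `run_config` list
#' @export
run_config <- function(cohort = cohort_config(), spectro = spectro_config(),
                       augment = augment_config(), mfcc = mfcc_config(),
                       arch = cnn_architecture(), train = train_config(),
                       models = c("cnn", "svm_linear", "lda", "knn", "rf"),
                       n_folds = 10, max_segments_per_participant = 4,
                       seed = 1L, out_dir = tempfile("depspeech_run_")) {
  structure(list(cohort = cohort, spectro = spectro, augment = augment,
                 mfcc = mfcc, arch = arch, train = train, models = models,
                 n_folds = n_folds,
                 max_segments_per_participant = max_segments_per_participant,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "run_config")
}

# stable hash of a config: canonical YAML of alphabetically sorted fields
config_hash <- function(cfg) {
  canon <- function(x) {
    if (is.list(x)) {
      x <- lapply(x, canon)
      if (!is.null(names(x))) x <- x[order(names(x))]
    }
    x
  }
  txt <- yaml::as.yaml(canon(rapply(unclass(cfg), identity, how = "list")))
  f <- tempfile()
  writeLines(txt, f)
  on.exit(unlink(f))
  unname(tools::md5sum(f))
}

#' Synthesize a cohort to disk
#'
#' Writes one WAV per participant-task plus a manifest (CSV and JSONL) and
#' a YAML snapshot of the generating configuration.
#'
#' @param config a [run_config()] or [cohort_config()]
#' @param out_dir output directory (created if missing)
#' @return the manifest data frame, invisibly
#' @export
cmd_simulate <- function(config, out_dir = NULL) {
  cc <- if (inherits(config, "run_config")) config$cohort else config
  stopifnot(inherits(cc, "cohort_config"))
  out_dir <- out_dir %||%
    (if (inherits(config, "run_config")) config$out_dir else
       stop("out_dir required"))
  dir.create(file.path(out_dir, "audio"), recursive = TRUE,
             showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create output directory: ", out_dir)
  writer <- function(rec) {
    fn <- sprintf("%s_%s.wav", rec$participant_id, rec$task)
    write_wav(rec$samples, file.path(out_dir, "audio", fn),
              rec$sample_rate, bit_depth = 16L)
    fn
  }
  gen <- generate_cohort(cc, process = writer)
  manifest <- gen$manifest
  manifest$path <- file.path("audio", unlist(gen$recordings))
  write.csv(manifest, file.path(out_dir, "manifest.csv"), row.names = FALSE)
  jsonl <- file(file.path(out_dir, "manifest.jsonl"), "w")
  for (i in seq_len(nrow(manifest)))
    writeLines(jsonlite::toJSON(as.list(manifest[i, ]), auto_unbox = TRUE),
               jsonl)
  close(jsonl)
  yaml::write_yaml(rapply(unclass(cc), identity, how = "list"),
                   file.path(out_dir, "cohort_config.yaml"))
  invisible(manifest)
}

#' Execute the full pipeline and write its artifacts
#'
#' Synthesizes (or loads) the cohort, prepares features and segments, runs
#' the cross-validated experiment and writes fold metrics, the summary
#' table, and the resolved configuration to the run directory.
#'
#' @param config a [run_config()]
#' @param dataset optional pre-built [prepare_dataset()] result (skips
#'   synthesis)
#' @return the `evaluation_report`, invisibly
#' @export
cmd_run <- function(config, dataset = NULL) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  if (is.null(dataset)) {
    dataset <- prepare_dataset(
      config$cohort, config$spectro, config$mfcc, config$arch,
      config$max_segments_per_participant)
  }
  report <- run_experiment(dataset, config$models, config$n_folds,
                           seed = config$seed, train = config$train,
                           augment_cfg = config$augment)
  write.csv(report$fold_metrics,
            file.path(config$out_dir, "fold_metrics.csv"), row.names = FALSE)
  write.csv(report$summary, file.path(config$out_dir, "summary.csv"),
            row.names = FALSE)
  if (!is.null(report$roc_points))
    write.csv(report$roc_points, file.path(config$out_dir, "roc_points.csv"),
              row.names = FALSE)
  if (!is.null(dataset$processing_log)) {
    con <- file(file.path(config$out_dir, "preprocess_log.jsonl"), "w")
    for (i in seq_len(nrow(dataset$processing_log)))
      writeLines(jsonlite::toJSON(as.list(dataset$processing_log[i, ]),
                                  auto_unbox = TRUE), con)
    close(con)
  }
  con <- file(file.path(config$out_dir, "run_log.jsonl"), "w")
  fm <- report$fold_metrics
  for (i in seq_len(nrow(fm))) {
    entry <- c(list(time = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
               as.list(fm[i, ]))
    writeLines(jsonlite::toJSON(entry, auto_unbox = TRUE, digits = NA), con)
  }
  close(con)
  snap <- rapply(unclass(config)[setdiff(names(unclass(config)), "out_dir")],
                 identity, how = "list")
  snap$config_hash <- config_hash(config)
  yaml::write_yaml(snap, file.path(config$out_dir, "run_config.yaml"))
  jsonlite::write_json(
    list(summary = report$summary, n_failures = report$n_failures,
         seed = config$seed, config_hash = snap$config_hash),
    file.path(config$out_dir, "report.json"), auto_unbox = TRUE, digits = NA)
  invisible(report)
}

#' Render an evaluation report as mean (SD) tables
#'
#' @param report an `evaluation_report`, or a path to a `fold_metrics.csv`
#'   written by [cmd_run()]
#' @param out_dir optional directory for `report_table.csv` and
#'   `report_table.md`
#' @return character vector of markdown lines, invisibly; the table is
#'   printed
#' @export
cmd_report <- function(report, out_dir = NULL) {
  fm <- if (inherits(report, "evaluation_report")) report$fold_metrics
        else if (is.data.frame(report)) report
        else if (is.character(report)) read.csv(report)
        else stop("format error: expected a report or a fold-metrics path")
  if (is.null(fm) || nrow(fm) == 0) {
    message("no folds to report")
    return(invisible(character(0)))
  }
  tab <- report_table(fm)
  fmt <- function(m, s) sprintf("%.2f (%.2f)", 100 * m, 100 * s)
  md <- c("| Task | Model | Level | Accuracy | Precision | Recall | F1 | AUC |",
          "|---|---|---|---|---|---|---|---|")
  for (i in seq_len(nrow(tab))) {
    r <- tab[i, ]
    md <- c(md, sprintf("| %s | %s | %s | %s | %s | %s | %s | %.3f |",
                        r$task, r$model, r$level,
                        fmt(r$accuracy_mean, r$accuracy_sd),
                        fmt(r$precision_mean, r$precision_sd),
                        fmt(r$recall_mean, r$recall_sd),
                        fmt(r$f1_mean, r$f1_sd), r$auc_mean))
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write.csv(tab, file.path(out_dir, "report_table.csv"), row.names = FALSE)
    writeLines(md, file.path(out_dir, "report_table.md"))
  }
  writeLines(md)
  invisible(md)
}
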