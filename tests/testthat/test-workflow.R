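tiny_cohort <- function(seed = 31, n = 8) {
  cohort_config(n_participants = n, tasks = list(vowel = c(6, 0.5)),
                variability_gap = 2, seed = seed)
}

test_that("WAV files round-trip in both supported encodings", {
  x <- round(sin(2 * pi * 440 * (0:8000) / 8000) * 0.8, 6)
  f16 <- withr::local_tempfile(fileext = ".wav")
  write_wav(x, f16, 8000, bit_depth = 16L)
  got16 <- read_wav(f16)
  expect_equal(got16$sample_rate, 8000)
  expect_lt(max(abs(got16$samples - x)), 1 / 32767)
  f32 <- withr::local_tempfile(fileext = ".wav")
  write_wav(x, f32, 8000, bit_depth = 32L)
  got32 <- read_wav(f32)
  expect_lt(max(abs(got32$samples - x)), 1e-7)
})

test_that("cmd_simulate writes a complete, reproducible cohort", {
  dir_a <- withr::local_tempdir()
  dir_b <- withr::local_tempdir()
  cc <- cohort_config(n_participants = 3,
                      tasks = list(vowel = c(3, 0.2), digit = c(3, 0.2)),
                      seed = 8)
  man <- cmd_simulate(cc, dir_a)
  expect_equal(nrow(man), 6)
  expect_true(file.exists(file.path(dir_a, "manifest.csv")))
  expect_true(file.exists(file.path(dir_a, "manifest.jsonl")))
  expect_true(file.exists(file.path(dir_a, "cohort_config.yaml")))
  expect_true(all(file.exists(file.path(dir_a, man$path))))
  w <- read_wav(file.path(dir_a, man$path[1]))
  expect_equal(w$sample_rate, 44100)
  cmd_simulate(cc, dir_b)
  sums_a <- tools::md5sum(file.path(dir_a, man$path))
  sums_b <- tools::md5sum(file.path(dir_b, man$path))
  expect_equal(unname(sums_a), unname(sums_b))
})

test_that("datasets rebuilt from written WAV files match in-memory ones", {
  dir <- withr::local_tempdir()
  cc <- tiny_cohort(n = 4)
  man <- cmd_simulate(cc, dir)
  ds_disk <- prepare_dataset(list(manifest = man, audio_dir = dir),
                             max_segments_per_participant = 2)
  ds_mem <- prepare_dataset(cc, max_segments_per_participant = 2)
  expect_equal(nrow(ds_disk$manifest), nrow(ds_mem$manifest))
  # 16-bit quantization perturbs features only slightly
  expect_equal(ds_disk$features, ds_mem$features, tolerance = 0.05)
})

test_that("the end-to-end run writes a coherent report", {
  out <- withr::local_tempdir()
  cfg <- run_config(cohort = tiny_cohort(),
                    models = c("svm_linear", "rf"), n_folds = 2,
                    max_segments_per_participant = 2, seed = 5,
                    out_dir = out)
  rep <- cmd_run(cfg)
  expect_s3_class(rep, "evaluation_report")
  expect_equal(nrow(rep$fold_metrics), 4)  # 2 models x 2 folds
  expect_true(all(rep$fold_metrics$level == "participant"))
  expect_true(all(rep$fold_metrics$accuracy >= 0 &
                    rep$fold_metrics$accuracy <= 1))
  expect_true(file.exists(file.path(out, "fold_metrics.csv")))
  expect_true(file.exists(file.path(out, "summary.csv")))
  expect_true(file.exists(file.path(out, "run_config.yaml")))
  expect_true(file.exists(file.path(out, "report.json")))
  md <- cmd_report(rep, out)
  expect_true(any(grepl("svm_linear", md)))
  expect_true(file.exists(file.path(out, "report_table.md")))
  tab <- read.csv(file.path(out, "report_table.csv"))
  expect_equal(nrow(tab), 2)
  # baselines-only runs contain no CNN rows
  expect_false("cnn" %in% rep$fold_metrics$model)
})

test_that("reports can be re-rendered from their CSV artifacts", {
  fm <- data.frame(task = "vowel", model = "rf", fold = 1:3,
                   level = "participant", n = 2,
                   accuracy = c(1, 0.5, 1), precision = 1, recall = 1,
                   f1 = 1, auc = c(1, 0.75, 1))
  f <- withr::local_tempfile(fileext = ".csv")
  write.csv(fm, f, row.names = FALSE)
  md <- cmd_report(f)
  expect_true(any(grepl("83.33", md)))
  expect_message(cmd_report(fm[0, ]), "no folds")
})

test_that("config hashes are stable under key reordering", {
  a <- run_config(seed = 3, out_dir = "x")
  b <- run_config(seed = 3, out_dir = "x")
  b$cohort <- b$cohort[rev(seq_along(b$cohort))]
  class(b$cohort) <- "cohort_config"
  expect_equal(depspeech:::config_hash(a), depspeech:::config_hash(b))
  c2 <- run_config(seed = 4, out_dir = "x")
  expect_false(depspeech:::config_hash(a) == depspeech:::config_hash(c2))
})

test_that("runs leave an audit trail of logs and ROC points", {
  out <- withr::local_tempdir()
  cfg <- run_config(cohort = tiny_cohort(seed = 77),
                    models = c("svm_linear", "lda"), n_folds = 2,
                    max_segments_per_participant = 2, seed = 6,
                    out_dir = out)
  rep <- cmd_run(cfg)
  expect_true(file.exists(file.path(out, "preprocess_log.jsonl")))
  expect_true(file.exists(file.path(out, "run_log.jsonl")))
  run_lines <- readLines(file.path(out, "run_log.jsonl"))
  expect_length(run_lines, nrow(rep$fold_metrics))  # one line per fold/model
  first <- jsonlite::fromJSON(run_lines[1])
  expect_true(all(c("time", "task", "model", "fold", "accuracy") %in%
                    names(first)))
  plog <- jsonlite::stream_in(file(file.path(out, "preprocess_log.jsonl")),
                              verbose = FALSE)
  expect_equal(nrow(plog), 8)
  expect_true(all(plog$speech_s <= plog$input_s))
  if (!is.null(rep$roc_points)) {
    expect_true(file.exists(file.path(out, "roc_points.csv")))
    roc <- read.csv(file.path(out, "roc_points.csv"))
    expect_true(all(roc$fpr >= 0 & roc$fpr <= 1))
    expect_true(all(roc$tpr >= 0 & roc$tpr <= 1))
  }
})

test_that("missing audio files are tolerated up to a 10% budget", {
  dir <- withr::local_tempdir()
  cc <- cohort_config(n_participants = 12, tasks = list(vowel = c(6, 0.3)),
                      seed = 9)
  man <- cmd_simulate(cc, dir)
  file.remove(file.path(dir, man$path[1]))
  expect_warning(
    ds <- prepare_dataset(list(manifest = man, audio_dir = dir),
                          max_segments_per_participant = 1),
    "missing audio")
  expect_equal(nrow(ds$manifest), 11)
  file.remove(file.path(dir, man$path[2:3]))
  expect_error(
    prepare_dataset(list(manifest = man, audio_dir = dir),
                    max_segments_per_participant = 1),
    "aborting")
})
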