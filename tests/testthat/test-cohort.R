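short_tasks <- list(vowel = c(5, 0.5))

test_that("generate_cohort produces one recording per participant per task", {
  cc <- cohort_config(n_participants = 20, mdd_fraction = 0.5,
                      tasks = list(passage = c(4, 0.3)), seed = 7)
  out <- generate_cohort(cc, process = function(r) r$group)
  expect_equal(nrow(out$manifest), 20)
  expect_equal(sum(out$manifest$group == "MDD"), 10)
  expect_equal(sum(out$manifest$group == "HC"), 10)
  expect_equal(unlist(out$recordings), out$manifest$group,
               ignore_attr = TRUE)
})

test_that("identical config and seed give bit-identical waveforms", {
  cc <- cohort_config(n_participants = 3, tasks = short_tasks, seed = 42)
  a <- generate_cohort(cc)
  b <- generate_cohort(cc)
  for (i in seq_along(a$recordings))
    expect_identical(a$recordings[[i]]$samples, b$recordings[[i]]$samples)
  expect_identical(a$manifest, b$manifest)
})

test_that("waveforms respect the amplitude contract", {
  cc <- cohort_config(n_participants = 4, tasks = short_tasks, seed = 3)
  out <- generate_cohort(cc)
  for (rec in out$recordings) {
    expect_true(all(abs(rec$samples) <= 1))
    expect_equal(max(abs(rec$samples)), 0.9, tolerance = 1e-12)
    expect_equal(duration(rec), length(rec$samples) / rec$sample_rate)
  }
})

test_that("a 30 s utterance with pauses contains a quiet internal interval", {
  cp <- default_class_params()
  rec <- synthesize_utterance(11, cp$mdd,
                              list(duration = 30, pause_rate = 3.5))
  sr <- rec$sample_rate
  win <- round(0.05 * sr)
  starts <- seq(round(1 * sr), length(rec$samples) - win, by = round(0.025 * sr))
  rms_db <- vapply(starts, function(s) {
    10 * log10(mean(rec$samples[s:(s + win - 1)]^2))
  }, numeric(1))
  quiet <- rle(rms_db < -50)
  runs_ms <- quiet$lengths[quiet$values] * 25
  expect_true(any(runs_ms >= 200))
})

test_that("steady-vowel pitch matches an autocorrelation oracle", {
  cp <- default_class_params()$mdd
  cp$f0_mean <- 150
  cp$f0_wander_sd <- 0
  rec <- synthesize_utterance(5, cp,
                              list(duration = 3, pause_rate = 0),
                              sample_rate = 16000)
  voiced <- rec$samples[round(1.2 * 16000):round(2.2 * 16000)]
  f0 <- oracle_pitch(voiced, 16000)
  expect_lt(abs(f0 - 150) / 150, 0.02)
})

test_that("invalid configurations are rejected", {
  expect_error(cohort_config(n_participants = 0), "invalid config")
  expect_error(cohort_config(tasks = list()), "invalid config")
  expect_error(cohort_config(n_participants = 10, mdd_fraction = 0),
               "both classes")
  expect_error(cohort_config(tasks = list(vowel = c(0.3, 0))),
               "noise_head_s")
  bad <- default_class_params()$mdd
  bad$f0_mean <- 30
  expect_error(synthesize_utterance(1, bad, list(duration = 2)),
               "f0_mean")
  expect_error(synthesize_utterance(1, default_class_params()$mdd,
                                    list(duration = -1)), "duration")
})

test_that("per-task durations track the configured distribution", {
  cc <- cohort_config(n_participants = 30, tasks = list(vowel = c(6, 1)),
                      seed = 9)
  out <- generate_cohort(cc, process = function(r) duration(r))
  d <- unlist(out$recordings)
  expect_lt(abs(mean(d) - 6), 2 * 1)
  expect_equal(d, out$manifest$duration_s, tolerance = 1e-9)
})

test_that("a null variability gap leaves class RMS indistinguishable", {
  cc <- cohort_config(n_participants = 50, tasks = list(vowel = c(4, 0.4)),
                      variability_gap = 0, seed = 13)
  out <- generate_cohort(cc, process = function(r) sqrt(mean(r$samples^2)))
  v <- unlist(out$recordings)
  grp <- out$manifest$group
  p <- suppressWarnings(ks.test(v[grp == "MDD"], v[grp == "HC"]))$p.value
  expect_gt(p, 0.01)
})

test_that("spectral variability contrast grows monotonically with the gap", {
  diffs <- vapply(c(0, 0.5, 1, 2), function(gap) {
    cc <- cohort_config(n_participants = 50,
                        tasks = list(vowel = c(6, 0.5)),
                        variability_gap = gap, seed = 11)
    out <- generate_cohort(cc, process = function(r) {
      variability_trace(mfcc(r))$summary
    })
    v <- unlist(out$recordings)
    grp <- out$manifest$group
    mean(v[grp == "HC"]) - mean(v[grp == "MDD"])
  }, numeric(1))
  expect_true(all(diff(diffs) > 0))
})
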