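#' Audio recording container
#'
#' A mono waveform with participant metadata. Amplitudes live in `[-1, 1]`.
#'
#' @param samples numeric amplitude vector
#' @param sample_rate sampling rate (Hz)
#' @param participant_id opaque participant identifier
#' @param group class label, `"MDD"` or `"HC"` (or `NA` for unlabelled audio)
#' @param task reading task, one of `"vowel"`, `"digit"`, `"passage"`
#' @return an object of class `audio_rec`
#' @export
audio_rec <- function(samples, sample_rate, participant_id = NA_character_,
                      group = NA_character_, task = NA_character_) {
  stopifnot(is.numeric(samples), sample_rate > 0)
  structure(
    list(samples = as.numeric(samples), sample_rate = sample_rate,
         participant_id = participant_id, group = group, task = task),
    class = "audio_rec")
}

#' @export
print.audio_rec <- function(x, ...) {
  cat(sprintf("<audio_rec> %s/%s [%s] %.2f s @ %d Hz\n",
              x$participant_id, x$task, x$group, duration(x), x$sample_rate))
  invisible(x)
}

#' Duration of a recording in seconds
#' @param rec an [audio_rec()]
#' @return seconds
#' @export
duration <- function(rec) length(rec$samples) / rec$sample_rate

# evaluate expr under a fixed RNG seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# fixed integer hash of (root seed, stream index), kept below 2^31
derive_seed <- function(root, index) {
  as.integer((as.numeric(root) * 48271 + as.numeric(index) * 69621 + 11) %%
               2147483629)
}

#' Default per-class voice parameters
#'
#' Both classes share the same fundamental and amplitude-modulation depth;
#' they differ in how much the pitch and the formant centres wander over
#' time (controls more variable, the depressed-like class monotonous). The
#' wander values are per-10-ms-step standard deviations of a mean-reverting
#' random walk.
#'
#' @return a list with `mdd` and `hc` parameter lists
#' @export
default_class_params <- function() {
  list(
    mdd = list(f0_mean = 140, f0_wander_sd = 0.4,
               formant_wander_sd = 2, amplitude_mod_depth = 0.12),
    hc  = list(f0_mean = 140, f0_wander_sd = 1.6,
               formant_wander_sd = 8, amplitude_mod_depth = 0.12))
}

#' Synthetic cohort configuration
#'
#' Defines the generative conditions for a surrogate read-speech cohort:
#' cohort composition, per-task durations, recording format, pauses, noise
#' floor, and the class contrast in prosodic/spectral variability.
#'
#' @param n_participants number of speakers (>= 2)
#' @param mdd_fraction fraction of speakers in the MDD-like class
#' @param tasks named list of tasks; each entry is `c(mean, sd)` duration in
#'   seconds. Defaults: vowel 14 (4) s, digit 15 (5) s, passage 80 (13) s.
#' @param sample_rate sampling rate in Hz
#' @param noise_head_s seconds of noise-only audio at the start of every
#'   recording (must exceed the noise-profile window used downstream)
#' @param pause_rate expected pauses per 10 s of speech; read speech
#'   carries breath and phrase pauses every few seconds, so the default
#'   leaves roughly 15-20% of each utterance quiet
#' @param class_params per-class voice parameters, see
#'   [default_class_params()]
#' @param variability_gap scalar >= 0 scaling the control-minus-MDD
#'   difference in pitch and formant wander; 0 makes the classes
#'   generatively identical
#' @param noise_floor_db broadband background level (dBFS RMS)
#' @param seed root integer seed; per-participant streams are derived from it
#' @return a `cohort_config` list
#' @export
cohort_config <- function(n_participants = 60, mdd_fraction = 0.5,
                          tasks = list(vowel = c(14, 4), digit = c(15, 5),
                                       passage = c(80, 13)),
                          sample_rate = 44100, noise_head_s = 0.6,
                          pause_rate = 3.5, class_params = default_class_params(),
                          variability_gap = 1, noise_floor_db = -60,
                          seed = 1L) {
  if (length(tasks) == 0) stop("invalid config: at least one task is required")
  if (n_participants < 2) stop("invalid config: need >= 2 participants")
  if (mdd_fraction < 0 || mdd_fraction > 1)
    stop("invalid config: mdd_fraction must be in [0, 1]")
  n_mdd <- round(mdd_fraction * n_participants)
  if (n_mdd < 1 || n_mdd > n_participants - 1)
    stop("invalid config: both classes must be non-empty")
  if (!all(names(tasks) %in% c("vowel", "digit", "passage")))
    stop("invalid config: tasks must be among vowel, digit, passage")
  tasks <- lapply(tasks, function(t) as.numeric(unlist(t)))
  for (t in tasks) {
    if (length(t) < 2 || any(!is.finite(t)))
      stop("invalid config: each task needs a (mean, sd) duration pair")
    if (t[1] <= noise_head_s)
      stop("invalid config: task duration must exceed noise_head_s")
  }
  if (variability_gap < 0) stop("invalid config: variability_gap must be >= 0")
  structure(list(
    n_participants = n_participants, mdd_fraction = mdd_fraction,
    tasks = tasks, sample_rate = sample_rate, noise_head_s = noise_head_s,
    pause_rate = pause_rate, class_params = class_params,
    variability_gap = variability_gap, noise_floor_db = noise_floor_db,
    seed = as.integer(seed)), class = "cohort_config")
}

# class parameters with the variability gap applied: the control class sits
# at mdd + gap * (hc - mdd) for the two wander parameters
effective_class_params <- function(cp, gap) {
  hc <- cp$mdd
  hc$f0_mean <- cp$hc$f0_mean
  hc$amplitude_mod_depth <- cp$hc$amplitude_mod_depth
  hc$f0_wander_sd <- cp$mdd$f0_wander_sd +
    gap * (cp$hc$f0_wander_sd - cp$mdd$f0_wander_sd)
  hc$formant_wander_sd <- cp$mdd$formant_wander_sd +
    gap * (cp$hc$formant_wander_sd - cp$mdd$formant_wander_sd)
  list(mdd = cp$mdd, hc = hc)
}

# mean-reverting (OU-like) random walk, one value per block
ou_walk <- function(n, step_sd, theta = 0.02) {
  if (n == 0) return(numeric(0))
  z <- numeric(n)
  if (n == 1) return(z)
  eps <- rnorm(n, 0, step_sd)
  for (i in 2:n) z[i] <- (1 - theta) * z[i - 1] + eps[i]
  z
}

#' Synthesize one read-speech utterance
#'
#' Source-filter surrogate for a clinical recording: a harmonic source with
#' a slowly wandering fundamental is passed through three resonators whose
#' centre frequencies drift over time, amplitude-modulated at a syllabic
#' rate, interrupted by pauses, prefixed with a noise-only head, and mixed
#' with a stationary broadband noise floor. The result is peak-normalized
#' to 0.9.
#'
#' @param participant_seed integer seed for this utterance's random stream
#' @param class_params single-class voice parameters (`f0_mean`,
#'   `f0_wander_sd`, `formant_wander_sd`, `amplitude_mod_depth`)
#' @param task_spec list with `duration` (s), `pause_rate` (per 10 s) and
#'   optionally `task` name
#' @param sample_rate sampling rate in Hz
#' @param noise_head_s leading noise-only seconds
#' @param noise_floor_db broadband noise RMS level (dBFS)
#' @return an [audio_rec()]
#' @export
synthesize_utterance <- function(participant_seed, class_params, task_spec,
                                 sample_rate = 44100, noise_head_s = 0.6,
                                 noise_floor_db = -60) {
  dur <- task_spec$duration
  if (is.null(dur) || dur <= 0) stop("invalid config: non-positive duration")
  if (sample_rate <= 0) stop("invalid config: non-positive sample_rate")
  f0m <- class_params$f0_mean
  if (f0m <= 60 || f0m >= 400)
    stop("invalid config: f0_mean must lie in (60, 400) Hz")
  with_seed(participant_seed, {
    n <- round(dur * sample_rate)
    block <- max(1L, round(0.010 * sample_rate))   # 10 ms parameter blocks
    nb <- ceiling(n / block)
    # pitch contour: mean-reverting walk around f0_mean
    f0_blocks <- f0m + ou_walk(nb, class_params$f0_wander_sd)
    f0_blocks <- pmax(pmin(f0_blocks, 395), 65)
    f0 <- rep(f0_blocks, each = block)[seq_len(n)]
    src <- cpp_harmonic_source(f0, sample_rate, fmax = 4000)
    # three drifting formants; per-speaker base positions
    base <- c(600, 1200, 2600) * exp(rnorm(3, 0, 0.06))
    drift <- vapply(seq_len(3),
                    function(i) ou_walk(nb, class_params$formant_wander_sd),
                    numeric(nb))
    centers <- sweep(matrix(drift, nrow = nb), 2, base, "+")
    centers <- pmax(pmin(centers, sample_rate / 2 - 500), 250)
    voiced <- cpp_tv_resonators(src, centers, c(90, 120, 200), block,
                                sample_rate)
    # syllabic-rate amplitude modulation
    f_am <- runif(1, 2.5, 4.5)
    tsec <- (seq_len(n) - 1) / sample_rate
    env <- 1 + class_params$amplitude_mod_depth *
      sin(2 * pi * f_am * tsec + runif(1, 0, 2 * pi))
    # speech gate: silent head, then speech with pauses
    gate <- rep(1, n)
    head_n <- min(n, round(noise_head_s * sample_rate))
    gate[seq_len(head_n)] <- 0
    speech_s <- dur - noise_head_s
    pr <- task_spec$pause_rate
    if (!is.null(pr) && pr > 0 && speech_s > 2) {
      n_pause <- max(1L, stats::rpois(1, pr * speech_s / 10))
      starts <- sort(runif(n_pause, noise_head_s + 0.5, dur - 1))
      lens <- runif(n_pause, 0.3, 0.7)
      for (i in seq_len(n_pause)) {
        a <- round(starts[i] * sample_rate)
        b <- min(n, a + round(lens[i] * sample_rate))
        gate[a:b] <- 0
      }
    }
    # 30 ms cosine ramps at gate edges
    ramp_n <- round(0.03 * sample_rate)
    edges <- which(diff(gate) != 0)
    sm_gate <- gate
    for (e in edges) {
      lo <- max(1, e - ramp_n %/% 2); hi <- min(n, e + ramp_n %/% 2)
      span <- lo:hi
      tgt <- gate[hi]; from <- gate[lo]
      sm_gate[span] <- from + (tgt - from) *
        (1 - cos(pi * seq(0, 1, length.out = length(span)))) / 2
    }
    speech <- voiced * env * sm_gate
    pk <- max(abs(speech))
    if (pk > 0) speech <- speech / pk
    x <- speech + rnorm(n, 0, amp_from_db(noise_floor_db))
    pk <- max(abs(x))
    if (pk > 0) x <- x / pk * 0.9
    audio_rec(x, sample_rate, task = task_spec$task %||% NA_character_)
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Generate a synthetic read-speech cohort
#'
#' One recording per participant per configured task, plus a manifest.
#' Identical `config` (including its `seed`) yields bit-identical output.
#'
#' @param config a [cohort_config()]
#' @param process optional function applied to each recording as it is
#'   generated; when supplied, the returned `recordings` list holds the
#'   function's results instead of raw audio (keeps large cohorts out of
#'   memory)
#' @return a list with `recordings` and a `manifest` data frame
#'   (`participant_id`, `group`, `task`, `duration_s`)
#' @export
generate_cohort <- function(config, process = NULL) {
  stopifnot(inherits(config, "cohort_config"))
  n <- config$n_participants
  n_mdd <- round(config$mdd_fraction * n)
  groups <- rep(c("MDD", "HC"), c(n_mdd, n - n_mdd))
  ids <- sprintf("P%03d", seq_len(n))
  cp <- effective_class_params(config$class_params, config$variability_gap)
  task_names <- names(config$tasks)
  rows <- list(); recs <- list(); k <- 0L
  for (i in seq_len(n)) {
    cls <- if (groups[i] == "MDD") cp$mdd else cp$hc
    for (j in seq_along(task_names)) {
      k <- k + 1L
      sd_stream <- derive_seed(config$seed, (i - 1L) * 16L + j)
      dur <- with_seed(derive_seed(config$seed, (i - 1L) * 16L + 8L + j), {
        max(config$noise_head_s + 2,
            rnorm(1, config$tasks[[j]][1], config$tasks[[j]][2]))
      })
      rec <- synthesize_utterance(
        sd_stream, cls,
        list(duration = dur, pause_rate = config$pause_rate,
             task = task_names[j]),
        config$sample_rate, config$noise_head_s, config$noise_floor_db)
      rec$participant_id <- ids[i]
      rec$group <- groups[i]
      rows[[k]] <- data.frame(participant_id = ids[i], group = groups[i],
                              task = task_names[j], duration_s = duration(rec),
                              stringsAsFactors = FALSE)
      recs[[k]] <- if (is.null(process)) rec else process(rec)
    }
  }
  list(recordings = recs, manifest = do.call(rbind, rows))
}
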