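# Synthetic lung-sound corpus generator.
#
# Each class carries the acoustic signature reported for real lung sounds:
#   normal        - energy concentrated below 100 Hz with a steep fall-off
#                   between 100 and 200 Hz;
#   continuous    - wheeze: a musical (tonal) component with fundamental in
#                   80-1600 Hz lasting longer than 250 ms, over normal breath;
#   discontinuous - crackle: 3-15 explosive damped transients, each shorter
#                   than 20 ms, with content inside 100-2000 Hz;
#   unknown       - environmental interference (vocal-like harmonics or
#                   broadband equipment noise) masking the breath sound.
# Every clip is a deterministic function of (seed, class, index), so corpora
# are reproducible and order-independent.

#' Synthesis configuration
#'
#' @param n_per_class Clips per class (>= 1).
#' @param clip_seconds Clip duration in seconds (> 0.3 so a >250 ms wheeze
#'   fits; default 1.25).
#' @param sample_rate Sampling rate in Hz (default 4000).
#' @param snr_db Class-signature-to-background ratio in dB (default 15).
#'   For the unknown class this is the interference-to-breath ratio, so the
#'   breath component sits `snr_db` below the interference.
#' @param seed Integer master seed; per-clip sub-seeds are derived from
#'   (seed, class, index).
#' @return A `synth_config` list.
#' @export
synth_config <- function(n_per_class = 200, clip_seconds = 1.25,
                         sample_rate = 4000, snr_db = 15, seed = 1L) {
  if (n_per_class < 1) stop("n_per_class must be >= 1")
  if (clip_seconds <= 0.3) stop("clip_seconds must exceed 0.3 s")
  if (!is.finite(snr_db)) stop("snr_db must be finite")
  structure(list(n_per_class = as.integer(n_per_class),
                 clip_seconds = clip_seconds,
                 sample_rate = sample_rate,
                 snr_db = snr_db, seed = as.integer(seed)),
            class = "synth_config")
}

# Deterministic sub-seed from (master seed, class id, clip index); modular
# LCG-style mixing keeps everything below 2^31.
clip_seed <- function(seed, class_id, index) {
  m <- 2147483647
  a <- (abs(as.numeric(seed)) %% m)
  a <- (a * 48271 + class_id * 69621) %% m
  a <- (a * 16807 + index * 8191) %% m
  as.integer(a)
}

with_clip_seed <- function(config, class_label, index, fn) {
  class_id <- match(class_label, lung_classes())
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(clip_seed(config$seed, class_id, index))
  fn()
}

# Low-passed Gaussian noise with a breathing amplitude envelope: flat power
# below ~90 Hz, (f/90)^-6 power roll-off above, which keeps >50% of the
# energy below 100 Hz and puts the 200-300 Hz band >20 dB under 0-100 Hz.
breath_noise <- function(n, sr, rms_target = 0.08) {
  f <- (seq_len(n) - 1) / n * sr
  f <- pmin(f, sr - f)                       # two-sided frequency axis
  H <- ifelse(f <= 90, 1, (pmax(f, 1e-9) / 90)^-3)
  X <- fft(rnorm(n)) * H
  x <- Re(fft(X, inverse = TRUE)) / n
  t <- (seq_len(n) - 1) / sr
  fb <- runif(1, 0.15, 0.4)
  env <- 0.7 + 0.3 * sin(2 * pi * fb * t + runif(1, 0, 2 * pi))
  x <- x * env
  x / sqrt(mean(x^2)) * rms_target
}

rms <- function(x) sqrt(mean(x^2))

finalize_clip <- function(x, config, label, index, log) {
  peak <- max(abs(x))
  if (peak > 0.95) x <- x * (0.95 / peak)
  clip <- audio_clip(x, config$sample_rate, label,
                     source_id = sprintf("synth:%s:%d", label, index))
  attr(clip, "synthesis") <- log
  clip
}

#' Generate a normal (vesicular) breath-sound clip
#'
#' @param config A [synth_config()].
#' @param index Clip index (1-based); with the config seed it fully
#'   determines the waveform.
#' @return An [audio_clip()] labelled `"normal"`, with a `"synthesis"`
#'   attribute logging the generator parameters.
#' @export
gen_normal <- function(config, index) {
  with_clip_seed(config, "normal", index, function() {
    n <- round(config$clip_seconds * config$sample_rate)
    x <- breath_noise(n, config$sample_rate)
    finalize_clip(x, config, "normal", index,
                  list(class = "normal", index = index))
  })
}

#' Generate a continuous-sound (wheeze) clip
#'
#' A tonal component with fundamental drawn uniformly from 80-1600 Hz,
#' lasting 0.3-0.9 s (always > 250 ms), with one weak harmonic and slight
#' frequency drift, superimposed on a normal breath background at the
#' configured SNR.
#'
#' @inheritParams gen_normal
#' @return An [audio_clip()] labelled `"continuous"`; the `"synthesis"`
#'   attribute logs `f0_hz`, `duration_s`, `onset_s` and the SNR.
#' @export
gen_wheeze <- function(config, index) {
  with_clip_seed(config, "continuous", index, function() {
    sr <- config$sample_rate
    n <- round(config$clip_seconds * sr)
    bg <- breath_noise(n, sr)
    f0 <- runif(1, 80, 1600)
    dur <- runif(1, 0.30, min(0.90, config$clip_seconds - 0.12))
    onset <- runif(1, 0.05, config$clip_seconds - dur - 0.05)
    i0 <- round(onset * sr) + 1L
    m <- round(dur * sr)
    t <- (seq_len(m) - 1) / sr
    drift <- 1 + 0.008 * sin(2 * pi * t / dur)
    phase <- 2 * pi * cumsum(f0 * drift) / sr
    tone <- sin(phase) + 0.25 * sin(2 * phase)
    ramp <- pmin(1, pmin(t, dur - t) / 0.03)    # 30 ms raised ramps
    tone <- tone * ramp
    tone <- tone / rms(tone) * rms(bg) * 10^(config$snr_db / 20)
    x <- bg
    x[i0:(i0 + m - 1L)] <- x[i0:(i0 + m - 1L)] + tone
    finalize_clip(x, config, "continuous", index,
                  list(class = "continuous", index = index, f0_hz = f0,
                       duration_s = dur, onset_s = onset,
                       snr_db = config$snr_db))
  })
}

#' Generate a discontinuous-sound (crackle) clip
#'
#' 3-15 exponentially damped sinusoid bursts (decay constants 1.5-5 ms, so
#' the envelope stays above half-maximum for well under 20 ms) with carrier
#' frequencies in 250-1800 Hz, spread over a normal breath background.
#'
#' @inheritParams gen_normal
#' @return An [audio_clip()] labelled `"discontinuous"`; the `"synthesis"`
#'   attribute logs per-burst times, carriers and decay constants.
#' @export
gen_crackle <- function(config, index) {
  with_clip_seed(config, "discontinuous", index, function() {
    sr <- config$sample_rate
    n <- round(config$clip_seconds * sr)
    bg <- breath_noise(n, sr)
    n_b <- sample(3:15, 1)
    span0 <- 0.05
    span1 <- config$clip_seconds - 0.08
    spacing <- (span1 - span0) / n_b
    jitter <- runif(n_b, -0.25, 0.25)
    times <- span0 + (seq_len(n_b) - 0.5 + jitter) * spacing
    taus <- runif(n_b, 0.0015, 0.005)
    fcs <- runif(n_b, 250, 1800)
    # each burst's rms over its own support sits snr_db above the background
    target_rms <- rms(bg) * 10^(config$snr_db / 20) * runif(n_b, 0.8, 1.2)
    x <- bg
    for (b in seq_len(n_b)) {
      m <- round(8 * taus[b] * sr)
      i0 <- round(times[b] * sr) + 1L
      if (i0 + m - 1L > n) m <- n - i0 + 1L
      t <- (seq_len(m) - 1) / sr
      burst <- exp(-t / taus[b]) * sin(2 * pi * fcs[b] * t)
      burst <- burst / rms(burst) * target_rms[b]
      x[i0:(i0 + m - 1L)] <- x[i0:(i0 + m - 1L)] + burst
    }
    finalize_clip(x, config, "discontinuous", index,
                  list(class = "discontinuous", index = index,
                       n_bursts = n_b, burst_times_s = times,
                       carrier_hz = fcs, tau_s = taus,
                       snr_db = config$snr_db))
  })
}

#' Generate an unknown-class clip (interference-dominated)
#'
#' The breath component is masked by environmental interference at the
#' configured interference-to-breath ratio (so the respiratory component
#' sits `snr_db` dB below the interference). Interference is either
#' vocal-like (a harmonic series with formant-shaped amplitudes and vibrato)
#' or broadband equipment noise with slow amplitude modulation.
#'
#' @inheritParams gen_normal
#' @return An [audio_clip()] labelled `"unknown"`; the `"synthesis"`
#'   attribute logs the interference type and the measured powers of both
#'   components.
#' @export
gen_unknown <- function(config, index) {
  with_clip_seed(config, "unknown", index, function() {
    sr <- config$sample_rate
    n <- round(config$clip_seconds * sr)
    t <- (seq_len(n) - 1) / sr
    resp <- breath_noise(n, sr)
    type <- if (runif(1) < 0.5) "vocal" else "broadband"
    if (type == "vocal") {
      f0 <- runif(1, 120, 300)
      kmax <- max(1L, floor(1900 / f0))
      inst <- f0 * (1 + 0.02 * sin(2 * pi * 5 * t + runif(1, 0, 2 * pi)))
      phase <- 2 * pi * cumsum(inst) / sr
      interf <- numeric(n)
      for (k in seq_len(kmax)) {
        fk <- k * f0
        a <- exp(-((fk - 500) / 250)^2) + 0.7 * exp(-((fk - 1400) / 350)^2) + 0.05
        interf <- interf + a * sin(k * phase + runif(1, 0, 2 * pi))
      }
    } else {
      interf <- rnorm(n) * (0.8 + 0.2 * sin(2 * pi * runif(1, 1, 3) * t))
    }
    interf <- interf / rms(interf) * rms(resp) * 10^(config$snr_db / 20)
    p_resp <- mean(resp^2); p_interf <- mean(interf^2)
    x <- resp + interf
    finalize_clip(x, config, "unknown", index,
                  list(class = "unknown", index = index,
                       interference = type,
                       resp_power = p_resp, interference_power = p_interf,
                       resp_to_interference_db =
                         10 * log10(p_resp / p_interf)))
  })
}

synth_generator <- function(label) {
  switch(label,
         continuous = gen_wheeze, discontinuous = gen_crackle,
         normal = gen_normal, unknown = gen_unknown,
         stop("unknown class: ", label))
}

#' Generate a labelled synthetic corpus on disk
#'
#' Writes `n_per_class` WAV clips per class, a CSV manifest (`path,label`)
#' and a JSON synthesis log holding every clip's ground-truth generator
#' parameters. Re-running with the same config reproduces byte-identical
#' files.
#'
#' @param config A [synth_config()].
#' @param out_dir Output directory (created if needed).
#' @return The corpus [lung_manifest()], invisibly carrying the log path in
#'   attribute `"log"`.
#' @export
gen_corpus <- function(config, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stop("cannot create output directory: ", out_dir)
  paths <- character(0); labels <- character(0); logs <- list()
  for (lab in lung_classes()) {
    gen <- synth_generator(lab)
    for (i in seq_len(config$n_per_class)) {
      clip <- gen(config, i)
      p <- file.path(out_dir, sprintf("%s_%04d.wav", lab, i))
      write_clip(clip, p)
      paths <- c(paths, p); labels <- c(labels, lab)
      logs[[length(logs) + 1L]] <- attr(clip, "synthesis")
    }
  }
  m <- lung_manifest(paths, labels)
  write_manifest(m, file.path(out_dir, "manifest.csv"))
  log_path <- file.path(out_dir, "synthesis_log.json")
  jsonlite::write_json(
    list(config = unclass(config), clips = logs),
    log_path, auto_unbox = TRUE, digits = NA)
  attr(m, "log") <- log_path
  invisible(m)
}

#' Generate a synthetic corpus in memory
#'
#' Like [gen_corpus()] but returns the clips directly instead of writing
#' WAV files; useful for programmatic experiments.
#'
#' @param config A [synth_config()].
#' @return A list with `clips` (list of [audio_clip()]) and `labels`.
#' @export
gen_corpus_memory <- function(config) {
  clips <- list(); labels <- character(0)
  for (lab in lung_classes()) {
    gen <- synth_generator(lab)
    for (i in seq_len(config$n_per_class)) {
      clips[[length(clips) + 1L]] <- gen(config, i)
      labels <- c(labels, lab)
    }
  }
  list(clips = clips, labels = labels)
}
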