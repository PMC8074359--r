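# Synthetic corpus generator: determinism and the class-specific acoustic
# signatures, checked with independent periodogram/spectrogram/envelope
# oracles on the generated waveforms.

sc <- synth_config(n_per_class = 5, snr_db = 15, seed = 123)

test_that("generators are deterministic in (seed, class, index) and sized", {
  n_expected <- round(sc$clip_seconds * sc$sample_rate)
  gens <- list(gen_normal, gen_wheeze, gen_crackle, gen_unknown)
  for (g in gens) {
    a <- g(sc, 3); b <- g(sc, 3)
    expect_identical(a$samples, b$samples)
    expect_length(a$samples, n_expected)
    expect_lte(max(abs(a$samples)), 1)
    expect_false(identical(a$samples, g(sc, 4)$samples))
  }
  # different master seed changes the waveform
  sc2 <- synth_config(n_per_class = 5, snr_db = 15, seed = 124)
  expect_false(identical(gen_normal(sc, 1)$samples, gen_normal(sc2, 1)$samples))
})

test_that("normal clips concentrate energy below 100 Hz with a steep fall-off", {
  for (i in 1:5) {
    clip <- gen_normal(sc, i)
    expect_gt(energy_fraction_below(clip$samples, clip$sample_rate, 100), 0.5)
    low <- band_mean_power(clip$samples, clip$sample_rate, 0, 100)
    high <- band_mean_power(clip$samples, clip$sample_rate, 200, 300)
    expect_gte(10 * log10(low / high), 12)
  }
})

test_that("wheeze clips hold a tonal ridge at the logged fundamental for >250 ms", {
  sp <- stft_params(256, 40, scale = "magnitude")
  for (i in 1:5) {
    clip <- gen_wheeze(sc, i)
    info <- attr(clip, "synthesis")
    expect_gt(info$duration_s, 0.25)
    f <- stft(clip, sp)
    bin_hz <- clip$sample_rate / sp$window_size
    ridge_bin <- round(info$f0_hz / bin_hz) + 1
    inside <- f$time_s >= info$onset_s + 0.02 &
      f$time_s <= info$onset_s + info$duration_s - 0.02
    peaks <- apply(f$values[, inside, drop = FALSE], 2, which.max)
    on_ridge <- abs(peaks - ridge_bin) <= 3
    expect_gte(sum(on_ridge) * sp$hop / clip$sample_rate, 0.25)
  }
})

test_that("at +20 dB SNR the wheeze ridge rises >=10 dB above the background bin", {
  sc20 <- synth_config(n_per_class = 3, snr_db = 20, seed = 55)
  sp <- stft_params(256, 40, scale = "power")
  for (i in 1:3) {
    clip <- gen_wheeze(sc20, i)
    info <- attr(clip, "synthesis")
    f <- stft(clip, sp)
    ridge_bin <- round(info$f0_hz / (clip$sample_rate / sp$window_size)) + 1
    inside <- f$time_s >= info$onset_s + 0.02 &
      f$time_s <= info$onset_s + info$duration_s - 0.02
    outside <- f$time_s < info$onset_s - 0.05 |
      f$time_s > info$onset_s + info$duration_s + 0.05
    ridge_power <- max(f$values[ridge_bin, inside])
    bg_power <- mean(f$values[ridge_bin, outside])
    expect_gte(10 * log10(ridge_power / bg_power), 10)
  }
})

test_that("crackle bursts are <20 ms transients that fatten the amplitude tails", {
  for (i in 1:5) {
    clip <- gen_crackle(sc, i)
    info <- attr(clip, "synthesis")
    expect_gte(info$n_bursts, 3); expect_lte(info$n_bursts, 15)
    expect_true(all(info$carrier_hz > 100 & info$carrier_hz < 2000))
    env <- hilbert_envelope(clip$samples)
    sr <- clip$sample_rate
    for (b in seq_len(info$n_bursts)) {
      i0 <- max(1, round(info$burst_times_s[b] * sr) - round(0.005 * sr))
      i1 <- min(length(env), round(info$burst_times_s[b] * sr) + round(0.030 * sr))
      win <- env[i0:i1]
      above <- sum(win > max(win) / 2) / sr
      expect_lt(above, 0.020)
    }
    matched_normal <- gen_normal(sc, i)
    expect_gt(excess_kurtosis(clip$samples),
              excess_kurtosis(matched_normal$samples))
  }
})

test_that("unknown clips mask the breath component by at least 6 dB", {
  for (i in 1:30) {
    clip <- gen_unknown(sc, i)
    info <- attr(clip, "synthesis")
    expect_lte(info$resp_to_interference_db, -6)
    # the logged powers are real measurements of the mixed components
    expect_equal(info$resp_to_interference_db,
                 10 * log10(info$resp_power / info$interference_power))
  }
})

test_that("gen_corpus writes a reproducible labelled corpus with a log", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  cfg <- synth_config(n_per_class = 3, seed = 9)
  m1 <- gen_corpus(cfg, d1)
  expect_identical(nrow(m1), 12L)
  expect_identical(sort(unique(m1$label)), sort(lung_classes()))
  expect_identical(as.vector(table(m1$label)), rep(3L, 4))
  expect_true(file.exists(file.path(d1, "manifest.csv")))
  expect_true(file.exists(attr(m1, "log")))
  # byte-identical reruns
  m2 <- gen_corpus(cfg, d2)
  for (i in seq_len(nrow(m1))) {
    expect_identical(unname(tools::md5sum(m1$path[i])),
                     unname(tools::md5sum(m2$path[i])))
  }
  # clips load back at the configured rate and length
  clip <- load_clip(m1$path[1], 4000, label = m1$label[1])
  expect_length(clip$samples, 5000)
  log <- jsonlite::read_json(attr(m1, "log"), simplifyVector = FALSE)
  expect_length(log$clips, 12L)
})

test_that("synth_config validates its invariants", {
  expect_error(synth_config(n_per_class = 0), "n_per_class")
  expect_error(synth_config(clip_seconds = 0.2), "0.3")
  expect_error(synth_config(snr_db = Inf), "finite")
})
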