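# STFT, mel/MFCC and fusion: shapes, analytic identities and agreement with
# direct-sum oracles.

test_that("STFT shapes follow the framing formulas", {
  clip <- audio_clip(runif(5000, -0.5, 0.5), 4000)
  f512 <- stft(clip, stft_params(512, 40))
  expect_identical(dim(f512$values), c(257L, 126L))
  f256 <- stft(clip, stft_params(256, 40))
  expect_identical(dim(f256$values), c(129L, 126L))
  # frame count is independent of L under centered framing
  for (L in c(64, 128, 256, 512))
    for (R in c(20, 30, 40, 50))
      expect_identical(ncol(stft(clip, stft_params(L, R))$values),
                       5000L %/% as.integer(R) + 1L)
  # non-centered: 1 + floor((N - L)/R)
  fnc <- stft(clip, stft_params(256, 40, centered = FALSE))
  expect_identical(ncol(fnc$values), (5000L - 256L) %/% 40L + 1L)
  short <- audio_clip(runif(100, -0.5, 0.5), 4000)
  expect_error(stft(short, stft_params(256, 40, centered = FALSE)), "shorter")
})

test_that("all-zero input gives an all-zero magnitude spectrogram", {
  clip <- audio_clip(numeric(5000), 4000)
  f <- stft(clip, stft_params(256, 40, scale = "magnitude"))
  expect_identical(dim(f$values), c(129L, 126L))
  expect_true(all(f$values == 0))
})

test_that("a bin-aligned sinusoid peaks at its own frequency row", {
  sr <- 4000; L <- 256; k <- 20
  f0 <- k * sr / L
  t <- (0:4999) / sr
  clip <- audio_clip(0.8 * sin(2 * pi * f0 * t), sr)
  f <- stft(clip, stft_params(L, 40, scale = "magnitude"))
  # interior frames: windows fully inside the signal (edge windows overlap
  # the reflection padding, where the sinusoid's phase folds back)
  interior <- which(f$time_s * 4000 >= L / 2 & f$time_s * 4000 <= 5000 - L / 2)
  peaks <- apply(f$values[, interior], 2, which.max)
  expect_true(all(peaks == k + 1))
})

test_that("dB-scaled spectrogram is referenced to the per-clip maximum", {
  clip <- audio_clip(runif(5000, -0.5, 0.5), 4000)
  f <- stft(clip, stft_params(256, 40, scale = "dB"))
  expect_equal(max(f$values), 0)
  expect_gte(min(f$values), -80)
})

test_that("fast STFT equals the direct DFT sum on the parameter grids", {
  # small-grid spot check; the full 50-signal sweep runs in the acceptance
  # suite
  set.seed(31)
  for (rep in 1:5) {
    x <- runif(5000, -0.9, 0.9)
    clip <- audio_clip(x, 4000)
    for (L in c(64, 256)) for (R in c(20, 50)) {
      p <- stft_params(L, R, scale = "magnitude")
      fast <- stft(clip, p)$values
      direct <- dft_direct_mag(lungsounds:::stft_frames(x, p))
      expect_lt(max(abs(fast - direct)) / max(direct), 1e-8)
    }
  }
})

test_that("mel map matches its closed form, is monotone, concave, invertible", {
  expect_identical(hz_to_mel(0), 0)
  expect_equal(hz_to_mel(700), 2595 * log10(2))
  expect_equal(hz_to_mel(700), 781.17, tolerance = 1e-4)
  f <- seq(0, 2000, by = 5)
  m <- hz_to_mel(f)
  expect_true(all(diff(m) > 0))            # strictly increasing
  expect_true(all(diff(diff(m)) < 0))      # concave
  for (x in c(0, 500, 1000))
    expect_equal(hz_to_mel(mel_to_hz(x)), x, tolerance = 1e-9)
  expect_lt(max(abs(mel_to_hz(hz_to_mel(f)) - f)), 1e-9)
  expect_error(hz_to_mel(-1), "nonnegative")
})

test_that("mel filterbank is triangular, unimodal and covers the band", {
  mp <- mfcc_params(20, n_mel_filters = 40, framing = stft_params(256, 40))
  fb <- mel_filterbank(mp, 4000)
  expect_identical(dim(fb), c(40L, 129L))
  expect_true(all(fb >= 0))
  centers <- attr(fb, "centers_hz")
  expect_lt(max(abs(diff(hz_to_mel(centers)) - diff(hz_to_mel(centers))[1])),
            1e-9)
  # unimodal rows: values rise then fall
  for (i in c(1, 10, 25, 40)) {
    row <- fb[i, ]
    peak <- which.max(row)
    expect_true(all(diff(row[1:peak]) >= 0))
    expect_true(all(diff(row[peak:length(row)]) <= 0))
  }
  # interior bins between the first center and Nyquist are covered
  bin_hz <- (0:128) * 4000 / 256
  interior <- bin_hz > centers[1] & bin_hz < 2000
  expect_true(all(colSums(fb)[interior] > 0))
  # too many filters for the resolution is an error
  expect_error(mel_filterbank(mfcc_params(20, n_mel_filters = 40,
                                          framing = stft_params(64, 20)),
                              4000),
               "too large")
})

test_that("MFCC features have 3 n_mfcc rows and vanish deltas on constant input", {
  clip <- audio_clip(rep(0.3, 5000), 4000)
  for (n in c(10, 13, 20)) {
    feat <- mfcc(clip, mfcc_params(n))
    expect_identical(nrow(feat$values), 3L * as.integer(n))
    expect_identical(ncol(feat$values), 126L)
    expect_true(all(abs(feat$values[(n + 1):(3 * n), ]) < 1e-10))
  }
})

test_that("MFCC agrees with the step-by-step oracle", {
  set.seed(17)
  for (rep in 1:2) {
    x <- runif(900, -0.8, 0.8)
    clip <- audio_clip(x, 4000)
    mp <- mfcc_params(13, n_mel_filters = 26, delta_width = 9,
                      framing = stft_params(128, 30))
    got <- mfcc(clip, mp)$values
    want <- mfcc_oracle(x, 4000, 128, 30, 13, 26, 9, mp$energy_floor)
    expect_lt(max(abs(got - want)), 1e-6)
  }
})

test_that("coefficient 0 carries the overall log energy on white noise", {
  set.seed(4)
  clip <- audio_clip(runif(5000, -0.9, 0.9), 4000)
  feat <- mfcc(clip, mfcc_params(20))
  mean_abs <- abs(rowMeans(feat$values[1:20, ]))
  expect_identical(unname(which.max(mean_abs)), 1L)
  expect_gt(mean_abs[1], 2 * max(mean_abs[-1]))
})

test_that("the DCT step is orthonormal", {
  C <- lungsounds:::dct_matrix(40, 40)
  expect_lt(max(abs(C %*% t(C) - diag(40))), 1e-12)
  # truncating to n_mfcc rows then re-projecting is the identity on the
  # kept coefficients
  Ck <- lungsounds:::dct_matrix(13, 40)
  v <- rnorm(40)
  kept <- Ck %*% v
  recon <- t(C) %*% c(kept, numeric(27))
  expect_equal(as.vector(Ck %*% recon), as.vector(kept), tolerance = 1e-12)
})

test_that("fusion stacks 189 rows, z-scores per row, and is invertible", {
  sc <- synth_config(n_per_class = 2, seed = 21)
  clips <- lapply(1:4, function(i) gen_normal(sc, i))
  sp <- stft_params(256, 40)
  mp <- mfcc_params(20, framing = sp)
  raw <- lapply(clips, lungsounds:::clip_feature_matrix, kind = "fused",
                stft_par = sp, mfcc_par = mp)
  stats <- feature_stats(raw)
  fused <- fuse(stft(clips[[1]], sp), mfcc(clips[[1]], mp), stats)
  expect_identical(nrow(fused$values), 189L)
  expect_identical(fused$n_stft_rows, 129L)
  expect_identical(fused$channel_count, 1L)
  # pooled training rows are standardized
  z <- lapply(raw, lungsounds:::apply_stats, stats = stats)
  pooled <- do.call(cbind, z)
  expect_lt(max(abs(rowMeans(pooled))), 1e-6)
  expect_lt(max(abs(apply(pooled, 1, function(r) mean(r^2)) - 1)), 1e-4)
  # unfuse recovers both blocks
  blocks <- unfuse(fused, stats)
  expect_equal(blocks$stft, stft(clips[[1]], sp)$values, tolerance = 1e-10,
               ignore_attr = "dimnames")
  expect_equal(blocks$mfcc, mfcc(clips[[1]], mp)$values, tolerance = 1e-10,
               ignore_attr = "dimnames")
})

test_that("fusion rejects mismatched framing", {
  clip <- gen_normal(synth_config(n_per_class = 1, seed = 3), 1)
  s256 <- stft(clip, stft_params(256, 40))
  m512 <- mfcc(clip, mfcc_params(20, framing = stft_params(512, 40)))
  expect_error(fuse(s256, m512), "framing")
  m_hop <- mfcc(clip, mfcc_params(20, framing = stft_params(256, 50)))
  expect_error(fuse(s256, m_hop), "framing")
  bad_stats <- feature_stats(list(matrix(rnorm(50), 10, 5)))
  s_ok <- stft(clip, stft_params(256, 40))
  m_ok <- mfcc(clip, mfcc_params(20, framing = stft_params(256, 40)))
  expect_error(fuse(s_ok, m_ok, bad_stats), "does not match")
})

test_that("feature files round trip through TSV + JSON sidecar", {
  clip <- gen_normal(synth_config(n_per_class = 1, seed = 13), 1)
  feat <- stft(clip, stft_params(128, 40))
  p <- withr::local_tempfile(fileext = ".tsv")
  write_feature(feat, p)
  back <- read_feature(p)
  expect_equal(back$values, feat$values, tolerance = 1e-12)
  expect_identical(back$meta$params$window_size, 128L)
})
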