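# Independent oracle implementations used to cross-check the package:
# everything here is deliberately written as direct sums / explicit loops,
# sharing no code path with the implementation under test.

# Periodogram band statistics -------------------------------------------------

periodogram <- function(x, sr) {
  n <- length(x)
  P <- Mod(fft(x))^2 / n
  f <- (0:(n - 1)) * sr / n
  keep <- f <= sr / 2
  list(f = f[keep], p = P[keep])
}

band_mean_power <- function(x, sr, f_lo, f_hi) {
  pg <- periodogram(x, sr)
  sel <- pg$f >= f_lo & pg$f < f_hi
  mean(pg$p[sel])
}

energy_fraction_below <- function(x, sr, f_cut) {
  pg <- periodogram(x, sr)
  sum(pg$p[pg$f < f_cut]) / sum(pg$p)
}

# Analytic-signal envelope via FFT Hilbert transform --------------------------

hilbert_envelope <- function(x) {
  n <- length(x)
  X <- fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  Mod(fft(X * h, inverse = TRUE) / n)
}

excess_kurtosis <- function(x) {
  m <- mean(x); v <- mean((x - m)^2)
  mean((x - m)^4) / v^2 - 3
}

# Direct evaluation of the STFT sum (per-frame DFT as an explicit complex
# matrix product, no FFT) -----------------------------------------------------

dft_direct_mag <- function(frames) {
  L <- nrow(frames)
  E <- exp(-2i * pi * outer(0:(L %/% 2), 0:(L - 1)) / L)
  Mod(E %*% frames)
}

# Step-by-step MFCC oracle: power spectrum -> triangular mel weighting ->
# log -> explicit cosine-sum DCT -> regression deltas ------------------------

mel_of <- function(f) 2595 * log10(1 + f / 700)
hz_of <- function(m) 700 * (10^(m / 2595) - 1)

mfcc_oracle <- function(x, sr, L, R, n_mfcc, n_filt, delta_width, floor_e) {
  # centered framing, rectangular window
  n <- length(x); h <- L %/% 2
  pad <- c(x[(h + 1):2], x, x[(n - 1):(n - h)])
  n_frames <- n %/% R + 1
  pow <- matrix(0, L %/% 2 + 1, n_frames)
  for (m in seq_len(n_frames)) {
    fr <- pad[((m - 1) * R + 1):((m - 1) * R + L)]
    for (k in 0:(L %/% 2)) {
      re <- sum(fr * cos(2 * pi * k * (0:(L - 1)) / L))
      im <- -sum(fr * sin(2 * pi * k * (0:(L - 1)) / L))
      pow[k + 1, m] <- re^2 + im^2
    }
  }
  # triangular filters, centers equally spaced in mel
  mel_pts <- seq(0, mel_of(sr / 2), length.out = n_filt + 2)
  hz_pts <- hz_of(mel_pts)
  bin_hz <- (0:(L %/% 2)) * sr / L
  logE <- matrix(0, n_filt, n_frames)
  for (i in seq_len(n_filt)) {
    l <- hz_pts[i]; c <- hz_pts[i + 1]; r <- hz_pts[i + 2]
    wgt <- pmax(0, pmin((bin_hz - l) / (c - l), (r - bin_hz) / (r - c)))
    logE[i, ] <- log(pmax(colSums(wgt * pow), floor_e))
  }
  cc <- matrix(0, n_mfcc, n_frames)
  for (k in 0:(n_mfcc - 1)) {
    scale <- if (k == 0) sqrt(1 / n_filt) else sqrt(2 / n_filt)
    for (m in seq_len(n_frames))
      cc[k + 1, m] <- scale * sum(logE[, m] *
                                    cos(pi * k * ((0:(n_filt - 1)) + 0.5) / n_filt))
  }
  reg_delta <- function(v) {
    D <- (delta_width - 1) %/% 2
    out <- matrix(0, nrow(v), ncol(v))
    for (m in seq_len(ncol(v)))
      for (d in seq_len(D)) {
        m_p <- min(m + d, ncol(v)); m_m <- max(m - d, 1)
        out[, m] <- out[, m] + d * (v[, m_p] - v[, m_m])
      }
    out / (2 * sum((seq_len(D))^2))
  }
  d1 <- reg_delta(cc); d2 <- reg_delta(d1)
  rbind(cc, d1, d2)
}

# Brute-force single-channel 2-D convolution with ceil-division same padding -

conv2d_same_oracle <- function(x, w, stride) {
  k <- nrow(w); h <- nrow(x); wd <- ncol(x)
  oh <- ceiling(h / stride); ow <- ceiling(wd / stride)
  pt <- max((oh - 1) * stride + k - h, 0) %/% 2
  pl <- max((ow - 1) * stride + k - wd, 0) %/% 2
  out <- matrix(0, oh, ow)
  for (oi in seq_len(oh)) for (oj in seq_len(ow)) {
    acc <- 0
    for (di in 0:(k - 1)) for (dj in 0:(k - 1)) {
      ii <- (oi - 1) * stride + di - pt + 1
      jj <- (oj - 1) * stride + dj - pl + 1
      if (ii >= 1 && ii <= h && jj >= 1 && jj <= wd)
        acc <- acc + w[di + 1, dj + 1] * x[ii, jj]
    }
    out[oi, oj] <- acc
  }
  out
}

# Direct-summation metrics oracle ---------------------------------------------

metrics_oracle <- function(m) {
  nc <- nrow(m)
  rec <- prc <- f1 <- rep(NA_real_, nc)
  for (i in seq_len(nc)) {
    rs <- sum(m[i, ]); cs <- sum(m[, i])
    if (rs > 0) rec[i] <- m[i, i] / rs
    if (cs > 0) prc[i] <- m[i, i] / cs
    if (!is.na(rec[i]) && !is.na(prc[i]) && rec[i] + prc[i] > 0)
      f1[i] <- 2 * prc[i] * rec[i] / (prc[i] + rec[i])
  }
  list(recall = rec, precision = prc, f1 = f1,
       accuracy = sum(diag(m)) / sum(m))
}

# Small helpers for building test corpora ------------------------------------

tiny_manifest <- function(n_per_class, dir, sc = NULL) {
  if (is.null(sc))
    sc <- synth_config(n_per_class = n_per_class, seed = 11)
  gen_corpus(sc, dir)
}
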