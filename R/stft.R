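# Short-time Fourier transform features.
#
# The discrete STFT of x(n) with a length-L window w and hop R is
#   X(f, m) = sum_n x(n) w(n - mR) exp(-j 2 pi f n),  f = k/L, k = 0..L/2.
# The window is rectangular by default (w = 1 on its support); an optional
# Hann taper is available. With centered framing the signal is reflection-
# padded by L/2 on each side and frames start at multiples of R, giving
# 1 + floor(N/R) frames regardless of L.

#' STFT parameters
#'
#' @param window_size Window length L in samples; a power of two, typically
#'   in `{64, 128, 256, 512}`.
#' @param hop Hop length R in samples, typically in `{20, 30, 40, 50}`;
#'   must satisfy `1 <= R <= L`.
#' @param centered Use centered framing with reflection padding (default
#'   TRUE), so the frame count is `1 + floor(N/R)` for every window size.
#' @param scale Output scale: `"dB"` (log-magnitude referenced to the
#'   per-clip maximum, floored at -80 dB), `"magnitude"`, or `"power"`.
#' @param window `"rectangular"` (default) or `"hann"`.
#' @return An `stft_params` list.
#' @export
stft_params <- function(window_size = 256, hop = 40, centered = TRUE,
                        scale = c("dB", "magnitude", "power"),
                        window = c("rectangular", "hann")) {
  scale <- match.arg(scale)
  window <- match.arg(window)
  L <- as.integer(window_size); R <- as.integer(hop)
  if (L < 2 || bitwAnd(L, L - 1L) != 0L)
    stop("window_size must be a power of two")
  if (R < 1 || R > L) stop("hop must satisfy 1 <= hop <= window_size")
  structure(list(window_size = L, hop = R, centered = isTRUE(centered),
                 scale = scale, window = window),
            class = "stft_params")
}

# Frame matrix (L x n_frames) under the params' framing convention.
stft_frames <- function(x, params) {
  L <- params$window_size; R <- params$hop
  n <- length(x)
  if (params$centered) {
    h <- L %/% 2L
    if (n < h + 1L) stop("clip too short for reflection padding at this window size")
    pad <- c(x[(h + 1L):2L], x, x[(n - 1L):(n - h)])
    n_frames <- n %/% R + 1L
    starts <- (seq_len(n_frames) - 1L) * R + 1L
  } else {
    if (n < L) stop("clip shorter than the window in non-centered mode")
    pad <- x
    n_frames <- (n - L) %/% R + 1L
    starts <- (seq_len(n_frames) - 1L) * R + 1L
  }
  frames <- matrix(0, L, n_frames)
  for (m in seq_len(n_frames)) {
    frames[, m] <- pad[starts[m]:(starts[m] + L - 1L)]
  }
  if (params$window == "hann") {
    w <- 0.5 - 0.5 * cos(2 * pi * (0:(L - 1L)) / L)
    frames <- frames * w
  }
  frames
}

#' Short-time Fourier transform of a clip
#'
#' @param clip An [audio_clip()].
#' @param params An [stft_params()].
#' @return An `stft_feature` with a `(L/2 + 1) x n_frames` matrix `values`,
#'   the bin frequencies `freq_hz`, frame times `time_s` and the params.
#' @export
stft <- function(clip, params = stft_params()) {
  stopifnot(inherits(clip, "audio_clip"), inherits(params, "stft_params"))
  L <- params$window_size
  frames <- stft_frames(clip$samples, params)
  spec <- stats::mvfft(frames)[seq_len(L %/% 2L + 1L), , drop = FALSE]
  mag <- Mod(spec)
  values <- switch(params$scale,
    magnitude = mag,
    power = mag^2,
    dB = {
      ref <- max(mag)
      if (ref <= 0) {
        matrix(-80, nrow(mag), ncol(mag))
      } else {
        pmax(20 * log10(pmax(mag, ref * 1e-12) / ref), -80)
      }
    })
  structure(list(values = values,
                 freq_hz = (0:(L %/% 2L)) * clip$sample_rate / L,
                 time_s = (seq_len(ncol(values)) - 1L) * params$hop /
                   clip$sample_rate,
                 params = params, sample_rate = clip$sample_rate),
            class = "stft_feature")
}

#' @export
print.stft_feature <- function(x, ...) {
  cat(sprintf("<stft_feature> %d bins x %d frames (L=%d, R=%d, %s, %s)\n",
              nrow(x$values), ncol(x$values), x$params$window_size,
              x$params$hop, x$params$window, x$params$scale))
  invisible(x)
}

#' @export
plot.stft_feature <- function(x, ...) {
  image(x = x$time_s, y = x$freq_hz, z = t(x$values),
        xlab = "time (s)", ylab = "frequency (Hz)",
        main = sprintf("STFT (%s)", x$params$scale), useRaster = TRUE, ...)
  invisible(x)
}
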