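# Mel-frequency cepstral coefficients with first and second differences.
#
# Per frame: power spectrum -> triangular mel filterbank -> log -> orthonormal
# type-II DCT -> first n_mfcc coefficients. Delta rows are local linear
# regression slopes over delta_width frames; delta-delta applies the same
# operator to the deltas. The feature matrix stacks [MFCC; delta; delta2],
# giving 3 * n_mfcc rows.

#' Hz to mel conversion
#'
#' `m = 2595 log10(1 + f/700)`, the standard base-10 mel map.
#'
#' @param f Frequencies in Hz (vectorized), `f >= 0`.
#' @return Mel values.
#' @export
hz_to_mel <- function(f) {
  if (any(f < 0)) stop("frequency must be nonnegative")
  2595 * log10(1 + f / 700)
}

#' Mel to Hz conversion (inverse of [hz_to_mel()])
#'
#' @param m Mel values (vectorized), `m >= 0`.
#' @return Frequencies in Hz.
#' @export
mel_to_hz <- function(m) {
  if (any(m < 0)) stop("mel value must be nonnegative")
  700 * (10^(m / 2595) - 1)
}

#' MFCC parameters
#'
#' @param n_mfcc Number of cepstral coefficients kept, typically in
#'   `{10, 13, 20}`.
#' @param n_mel_filters Number of triangular mel filters (default 40).
#' @param delta_width Odd regression width (frames) for the delta operator
#'   (default 9).
#' @param framing An [stft_params()] describing the shared framing.
#' @param energy_floor Floor applied to filterbank energies before the log
#'   (default 1e-10).
#' @return An `mfcc_params` list.
#' @export
mfcc_params <- function(n_mfcc = 20, n_mel_filters = 40, delta_width = 9,
                        framing = stft_params(256, 40),
                        energy_floor = 1e-10) {
  n_mfcc <- as.integer(n_mfcc); n_mel_filters <- as.integer(n_mel_filters)
  delta_width <- as.integer(delta_width)
  if (n_mfcc < 1 || n_mfcc > n_mel_filters)
    stop("need 1 <= n_mfcc <= n_mel_filters")
  if (delta_width < 3 || delta_width %% 2L == 0L)
    stop("delta_width must be odd and >= 3")
  stopifnot(inherits(framing, "stft_params"))
  structure(list(n_mfcc = n_mfcc, n_mel_filters = n_mel_filters,
                 delta_width = delta_width, framing = framing,
                 energy_floor = energy_floor),
            class = "mfcc_params")
}

#' Triangular mel filterbank
#'
#' Filter centers are equally spaced on the mel axis from 0 to
#' `hz_to_mel(sample_rate/2)`; each filter is triangular in linear frequency.
#'
#' @param params An [mfcc_params()].
#' @param sample_rate Sampling rate in Hz.
#' @return A `n_mel_filters x (L/2 + 1)` nonnegative matrix with attribute
#'   `"centers_hz"`.
#' @export
mel_filterbank <- function(params, sample_rate = 4000) {
  stopifnot(inherits(params, "mfcc_params"))
  nf <- params$n_mel_filters
  if (nf < 2) stop("need at least 2 mel filters")
  L <- params$framing$window_size
  n_bins <- L %/% 2L + 1L
  mel_pts <- seq(0, hz_to_mel(sample_rate / 2), length.out = nf + 2L)
  hz_pts <- mel_to_hz(mel_pts)
  bin_hz <- (0:(n_bins - 1L)) * sample_rate / L
  fb <- matrix(0, nf, n_bins)
  for (i in seq_len(nf)) {
    l <- hz_pts[i]; c <- hz_pts[i + 1L]; r <- hz_pts[i + 2L]
    fb[i, ] <- pmax(0, pmin((bin_hz - l) / (c - l), (r - bin_hz) / (r - c)))
  }
  if (any(rowSums(fb) == 0))
    stop("n_mel_filters too large for this window size: a filter has no ",
         "frequency bin in its support")
  attr(fb, "centers_hz") <- hz_pts[2:(nf + 1L)]
  fb
}

# Local linear-regression slope over (2D+1) frames with edge replication.
delta_frames <- function(values, width) {
  D <- (width - 1L) %/% 2L
  n <- ncol(values)
  idx <- function(j) pmin(pmax(j, 1L), n)
  denom <- 2 * sum((1:D)^2)
  out <- matrix(0, nrow(values), n)
  for (d in seq_len(D)) {
    out <- out + d * (values[, idx(seq_len(n) + d), drop = FALSE] -
                        values[, idx(seq_len(n) - d), drop = FALSE])
  }
  out / denom
}

# Orthonormal type-II DCT matrix (n_keep x n).
dct_matrix <- function(n_keep, n) {
  k <- 0:(n_keep - 1L); j <- 0:(n - 1L)
  C <- sqrt(2 / n) * cos(pi * outer(k, j + 0.5) / n)
  C[1, ] <- C[1, ] / sqrt(2)
  C
}

#' MFCC feature with delta and delta-delta rows
#'
#' @param clip An [audio_clip()].
#' @param params An [mfcc_params()].
#' @return An `mfcc_feature` with a `3*n_mfcc x n_frames` matrix `values`
#'   (rows: MFCCs, deltas, delta-deltas) and the params.
#' @export
mfcc <- function(clip, params = mfcc_params()) {
  stopifnot(inherits(clip, "audio_clip"), inherits(params, "mfcc_params"))
  framing <- params$framing
  framing$scale <- "power"
  pow <- stft(clip, framing)$values
  fb <- mel_filterbank(params, clip$sample_rate)
  log_e <- log(pmax(fb %*% pow, params$energy_floor))
  C <- dct_matrix(params$n_mfcc, params$n_mel_filters)
  cc <- C %*% log_e
  d1 <- delta_frames(cc, params$delta_width)
  d2 <- delta_frames(d1, params$delta_width)
  values <- rbind(cc, d1, d2)
  rownames(values) <- c(paste0("mfcc", seq_len(params$n_mfcc)),
                        paste0("delta", seq_len(params$n_mfcc)),
                        paste0("delta2", seq_len(params$n_mfcc)))
  structure(list(values = values, params = params,
                 time_s = (seq_len(ncol(values)) - 1L) * framing$hop /
                   clip$sample_rate,
                 sample_rate = clip$sample_rate),
            class = "mfcc_feature")
}

#' @export
print.mfcc_feature <- function(x, ...) {
  cat(sprintf("<mfcc_feature> %d rows (3 x %d) x %d frames (L=%d, R=%d)\n",
              nrow(x$values), x$params$n_mfcc, ncol(x$values),
              x$params$framing$window_size, x$params$framing$hop))
  invisible(x)
}

#' @export
plot.mfcc_feature <- function(x, ...) {
  image(x = x$time_s, y = seq_len(nrow(x$values)), z = t(x$values),
        xlab = "time (s)", ylab = "coefficient row",
        main = "MFCC + deltas", useRaster = TRUE, ...)
  invisible(x)
}
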