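# Feature fusion and per-row normalization.
#
# The fused feature stacks the STFT block (L/2+1 rows, dB scale) above the
# MFCC block (3*n_mfcc rows) computed with the same framing, then z-scores
# every row with statistics estimated on the training split only. The result
# is a single-channel matrix of (L/2+1 + 3*n_mfcc) rows; the affine z-score
# is invertible given the statistics, so no information is lost.

#' Per-row normalization statistics
#'
#' Mean and standard deviation of every feature row, pooled over all frames
#' of all matrices in `features`. Compute this on the training split only.
#'
#' @param features A list of feature matrices with identical row counts.
#' @param sd_floor Lower bound on the standard deviation (default 1e-6).
#' @return A `feature_stats` list with `mean` and `sd` vectors.
#' @export
feature_stats <- function(features, sd_floor = 1e-6) {
  stopifnot(is.list(features), length(features) > 0)
  nr <- nrow(features[[1]])
  if (!all(vapply(features, nrow, 0L) == nr))
    stop("all feature matrices must have the same number of rows")
  n_tot <- sum(vapply(features, ncol, 0L))
  s1 <- rowSums(vapply(features, rowSums, numeric(nr)))
  s2 <- rowSums(vapply(features, function(f) rowSums(f^2), numeric(nr)))
  mu <- s1 / n_tot
  sdv <- sqrt(pmax(s2 / n_tot - mu^2, 0))
  structure(list(mean = mu, sd = pmax(sdv, sd_floor), n_frames = n_tot),
            class = "feature_stats")
}

apply_stats <- function(values, stats) {
  if (nrow(values) != length(stats$mean))
    stop("row count of feature (", nrow(values),
         ") does not match normalization statistics (", length(stats$mean), ")")
  (values - stats$mean) / stats$sd
}

#' Fuse STFT and MFCC features into one single-channel matrix
#'
#' Both features must share the same framing (window size, hop, centering),
#' hence the same frame count. Rows are z-scored with training-split
#' statistics and the MFCC block is stacked below the STFT block.
#'
#' @param stft_feat An `stft_feature` from [stft()].
#' @param mfcc_feat An `mfcc_feature` from [mfcc()].
#' @param stats A [feature_stats()] for the stacked rows (from the training
#'   split), or `NULL` to return the raw stacked matrix un-normalized.
#' @return A `fused_feature` with matrix `values`
#'   (`(L/2+1) + 3*n_mfcc` rows), `n_stft_rows`, and the framing params.
#' @export
fuse <- function(stft_feat, mfcc_feat, stats = NULL) {
  stopifnot(inherits(stft_feat, "stft_feature"),
            inherits(mfcc_feat, "mfcc_feature"))
  fa <- stft_feat$params; fb <- mfcc_feat$params$framing
  if (fa$window_size != fb$window_size || fa$hop != fb$hop ||
      fa$centered != fb$centered)
    stop("STFT and MFCC blocks must share the same framing (L, R, centering)")
  if (ncol(stft_feat$values) != ncol(mfcc_feat$values))
    stop("frame-count mismatch between STFT and MFCC blocks")
  values <- rbind(stft_feat$values, mfcc_feat$values)
  if (!is.null(stats)) values <- apply_stats(values, stats)
  structure(list(values = values,
                 n_stft_rows = nrow(stft_feat$values),
                 channel_count = 1L,
                 normalized = !is.null(stats),
                 params = list(stft = stft_feat$params,
                               mfcc = mfcc_feat$params)),
            class = "fused_feature")
}

#' Recover the STFT and MFCC blocks from a fused feature
#'
#' Inverts the per-row z-score given the statistics used in [fuse()].
#'
#' @param fused A `fused_feature`.
#' @param stats The [feature_stats()] used at fusion time (or `NULL` if the
#'   feature was not normalized).
#' @return A list with matrices `stft` and `mfcc`.
#' @export
unfuse <- function(fused, stats = NULL) {
  stopifnot(inherits(fused, "fused_feature"))
  v <- fused$values
  if (fused$normalized) {
    if (is.null(stats)) stop("stats are required to undo the normalization")
    v <- v * stats$sd + stats$mean
  }
  k <- fused$n_stft_rows
  list(stft = v[seq_len(k), , drop = FALSE],
       mfcc = v[(k + 1L):nrow(v), , drop = FALSE])
}

#' @export
print.fused_feature <- function(x, ...) {
  cat(sprintf("<fused_feature> %d rows (%d STFT + %d MFCC) x %d frames, 1 channel%s\n",
              nrow(x$values), x$n_stft_rows, nrow(x$values) - x$n_stft_rows,
              ncol(x$values), if (x$normalized) ", z-scored" else ""))
  invisible(x)
}

# Raw (un-normalized) feature matrix for one clip and feature kind.
clip_feature_matrix <- function(clip, kind, stft_par, mfcc_par) {
  switch(kind,
    stft = stft(clip, stft_par)$values,
    mfcc = mfcc(clip, mfcc_par)$values,
    fused = {
      sp <- stft_par
      sp$window_size <- mfcc_par$framing$window_size
      sp$hop <- mfcc_par$framing$hop
      sp$centered <- mfcc_par$framing$centered
      rbind(stft(clip, sp)$values, mfcc(clip, mfcc_par)$values)
    },
    stop("feature kind must be one of 'stft', 'mfcc', 'fused'"))
}

#' Extract a feature array from a list of clips
#'
#' Computes the raw feature matrix for every clip and stacks them into a
#' `rows x frames x n_clips` array. If `stats` is supplied each row is
#' z-scored; compute `stats` on the training split via [feature_stats()] on
#' the `raw` element of a training-split call.
#'
#' @param clips List of [audio_clip()] objects (already length-normalized).
#' @param kind One of `"stft"`, `"mfcc"`, `"fused"`.
#' @param stft_par An [stft_params()] (used for `"stft"`; for `"fused"` its
#'   scale/window are used with the MFCC framing so both blocks share L, R).
#' @param mfcc_par An [mfcc_params()].
#' @param stats Optional [feature_stats()] for normalization.
#' @return A list with `x` (the 3-D array) and `raw` (list of raw matrices).
#' @export
feature_array <- function(clips, kind = c("fused", "stft", "mfcc"),
                          stft_par = stft_params(512, 40),
                          mfcc_par = mfcc_params(20),
                          stats = NULL) {
  kind <- match.arg(kind)
  raw <- lapply(clips, clip_feature_matrix, kind = kind,
                stft_par = stft_par, mfcc_par = mfcc_par)
  mats <- if (is.null(stats)) raw else lapply(raw, apply_stats, stats = stats)
  x <- array(unlist(mats, use.names = FALSE),
             dim = c(nrow(mats[[1]]), ncol(mats[[1]]), length(mats)))
  list(x = x, raw = raw)
}

#' Persist a feature matrix as TSV with a JSON parameter sidecar
#'
#' @param feature An `stft_feature`, `mfcc_feature` or `fused_feature`.
#' @param path Output TSV path; the sidecar is written to `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_feature <- function(feature, path) {
  v <- feature$values
  utils::write.table(v, path, sep = "\t", row.names = FALSE,
                     col.names = FALSE)
  strip_classes <- function(x) {
    if (is.list(x)) lapply(unclass(x), strip_classes) else x
  }
  meta <- list(class = class(feature)[1], n_rows = nrow(v), n_cols = ncol(v),
               params = strip_classes(feature$params))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a feature matrix written by [write_feature()]
#'
#' @param path TSV path.
#' @return A list with the `values` matrix and the sidecar `meta` data.
#' @export
read_feature <- function(path) {
  values <- as.matrix(utils::read.table(path, sep = "\t", header = FALSE))
  dimnames(values) <- NULL
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  list(values = values, meta = meta)
}
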