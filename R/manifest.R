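# Dataset manifests (path,label tables) and stratified splitting.

#' Build a dataset manifest
#'
#' A manifest is a data frame with columns `path` and `label` plus a
#' `split_tag` attribute; labels must come from [lung_classes()] and paths
#' must be unique.
#'
#' @param paths Character vector of clip paths.
#' @param labels Character vector of labels, same length as `paths`.
#' @param split_tag One of `"train"`, `"val"`, `"test"`, `"all"`.
#' @return A `lung_manifest` data frame.
#' @export
lung_manifest <- function(paths, labels, split_tag = "all") {
  split_tag <- match.arg(split_tag, c("train", "val", "test", "all"))
  paths <- as.character(paths); labels <- as.character(labels)
  if (length(paths) != length(labels))
    stop("paths and labels must have the same length")
  if (anyDuplicated(paths)) stop("manifest paths must be unique")
  bad <- setdiff(unique(labels), lung_classes())
  if (length(bad)) stop("unknown labels: ", paste(bad, collapse = ", "))
  m <- data.frame(path = paths, label = labels, stringsAsFactors = FALSE)
  attr(m, "split_tag") <- split_tag
  class(m) <- c("lung_manifest", "data.frame")
  m
}

#' Read a manifest CSV (`path,label` header)
#'
#' @param path CSV file path.
#' @param split_tag Split tag to attach.
#' @return A [lung_manifest()].
#' @export
read_manifest <- function(path, split_tag = "all") {
  d <- read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("path", "label") %in% names(d)))
    stop("manifest CSV must have columns 'path' and 'label'")
  lung_manifest(d$path, d$label, split_tag)
}

#' Write a manifest to CSV
#'
#' @param manifest A [lung_manifest()].
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  write.csv(data.frame(path = manifest$path, label = manifest$label),
            path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Stratified train/validation/test split of a manifest
#'
#' Entries are partitioned per label with largest-remainder rounding, so the
#' split is stratified, exhaustive and disjoint, and per-class counts are
#' conserved. Deterministic given `seed`.
#'
#' @param manifest A [lung_manifest()].
#' @param ratios Numeric vector of three positive fractions summing to 1
#'   (default `c(train = 0.72, val = 0.08, test = 0.20)`).
#' @param seed Integer seed controlling the shuffle.
#' @return A named list of three manifests: `train`, `val`, `test`.
#' @export
split_manifest <- function(manifest,
                           ratios = c(train = 0.72, val = 0.08, test = 0.20),
                           seed = 1L) {
  stopifnot(inherits(manifest, "lung_manifest"))
  if (length(ratios) != 3L || any(ratios <= 0))
    stop("ratios must be three positive fractions")
  if (abs(sum(ratios) - 1) > 1e-9) stop("ratios must sum to 1")
  if (nrow(manifest) < 3L) stop("need at least 3 entries to split")
  counts <- table(factor(manifest$label, levels = lung_classes()))
  if (any(counts == 0L))
    stop("every class needs at least one entry; missing: ",
         paste(names(counts)[counts == 0L], collapse = ", "))

  idx_split <- list(integer(0), integer(0), integer(0))
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  for (lab in lung_classes()) {
    idx <- which(manifest$label == lab)
    idx <- idx[sample.int(length(idx))]
    n <- length(idx)
    share <- n * ratios
    base <- floor(share)
    rem <- n - sum(base)
    if (rem > 0) {
      frac_order <- order(share - base, decreasing = TRUE)
      base[frac_order[seq_len(rem)]] <- base[frac_order[seq_len(rem)]] + 1L
    }
    ends <- cumsum(base)
    starts <- c(1L, head(ends, -1L) + 1L)
    for (k in 1:3) {
      if (base[k] > 0)
        idx_split[[k]] <- c(idx_split[[k]], idx[starts[k]:ends[k]])
    }
  }
  tags <- c("train", "val", "test")
  out <- lapply(1:3, function(k) {
    i <- sort(idx_split[[k]])
    lung_manifest(manifest$path[i], manifest$label[i], tags[k])
  })
  names(out) <- tags
  out
}

#' Load every clip in a manifest
#'
#' Clips are loaded, checked against `expected_rate`, and normalized to
#' `target_seconds` with [pad_or_truncate()].
#'
#' @param manifest A [lung_manifest()].
#' @param expected_rate Required sampling rate (Hz).
#' @param target_seconds Fixed clip duration (seconds); `NULL` to skip
#'   normalization.
#' @return A list of [audio_clip()] objects.
#' @export
load_corpus <- function(manifest, expected_rate = 4000, target_seconds = 1.25) {
  clips <- lapply(seq_len(nrow(manifest)), function(i)
    load_clip(manifest$path[i], expected_rate, label = manifest$label[i]))
  if (!is.null(target_seconds))
    clips <- lapply(clips, pad_or_truncate, target_seconds = target_seconds)
  clips
}
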