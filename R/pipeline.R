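# Experiment orchestration: feature grids, training one model per feature
# kind and comparing them on the held-out test split.

default_feature_params <- function() {
  list(stft = stft_params(512, 40),
       mfcc = mfcc_params(20, framing = stft_params(256, 40)),
       fused = mfcc_params(20, framing = stft_params(256, 40)))
}

# Extract normalized train/val/test arrays for one feature kind; statistics
# always come from the training split alone.
prepare_features <- function(clips_split, kind, stft_par, mfcc_par) {
  tr_raw <- feature_array(clips_split$train, kind, stft_par, mfcc_par)$raw
  stats <- feature_stats(tr_raw)
  pack <- function(raw) {
    mats <- lapply(raw, apply_stats, stats = stats)
    array(unlist(mats, use.names = FALSE),
          dim = c(nrow(mats[[1]]), ncol(mats[[1]]), length(mats)))
  }
  list(x_train = pack(tr_raw),
       x_val = pack(feature_array(clips_split$val, kind, stft_par, mfcc_par)$raw),
       x_test = pack(feature_array(clips_split$test, kind, stft_par, mfcc_par)$raw),
       stats = stats)
}

train_one <- function(feats, labels_split, kind, alpha, beta, tc) {
  dims <- dim(feats$x_train)
  cfg <- model_config(alpha, beta, input_rows = dims[1], input_cols = dims[2])
  model <- build_model(block_plan(cfg), seed = tc$seed)
  fit_dscnn(feats$x_train, labels_split$train, feats$x_val, labels_split$val,
            model, tc)
}

#' Grid search over feature-extraction parameters
#'
#' Trains one model per parameter combination and selects the combination
#' with the best validation accuracy. Grids follow the method's search
#' space: window size in `{64, 128, 256, 512}` and hop in `{20, 30, 40,
#' 50}` for the STFT (and fused) feature, `n_mfcc` in `{10, 13, 20}` for
#' the MFCC feature. Ties are broken toward smaller window, then smaller
#' hop, then fewer coefficients.
#'
#' @param clips_split Named list of clip lists `train`, `val` (from
#'   [load_corpus()] on split manifests, or in-memory clips).
#' @param labels_split Named list of label vectors `train`, `val`.
#' @param feature_kind One of `"stft"`, `"mfcc"`, `"fused"`.
#' @param model_cfg A [model_config()] giving alpha/beta (input dims are
#'   taken from each feature).
#' @param budget A [train_config()] for the per-combination training runs.
#' @param windows,hops,n_mfccs Optional grid overrides.
#' @param verbose Print progress.
#' @return A list with `best` (the winning parameter set) and `table` (one
#'   row per combination with its validation accuracy).
#' @export
grid_search <- function(clips_split, labels_split, feature_kind,
                        model_cfg = model_config(),
                        budget = train_config(epochs = 5, patience = 5),
                        windows = c(64, 128, 256, 512),
                        hops = c(20, 30, 40, 50),
                        n_mfccs = c(10, 13, 20),
                        verbose = FALSE) {
  feature_kind <- match.arg(feature_kind, c("stft", "mfcc", "fused"))
  combos <- switch(feature_kind,
    stft = expand.grid(window = sort(windows), hop = sort(hops),
                       n_mfcc = NA_integer_),
    mfcc = expand.grid(window = NA_integer_, hop = NA_integer_,
                       n_mfcc = sort(n_mfccs)),
    fused = expand.grid(window = sort(windows), hop = sort(hops),
                        n_mfcc = 20L))
  combos <- combos[order(combos$window, combos$hop, combos$n_mfcc), ,
                   drop = FALSE]
  if (nrow(combos) == 0) stop("empty parameter grid")
  if (!length(clips_split$train) || !length(clips_split$val))
    stop("train and val splits must be nonempty")
  acc <- numeric(nrow(combos))
  for (i in seq_len(nrow(combos))) {
    sp <- stft_params(if (is.na(combos$window[i])) 256 else combos$window[i],
                      if (is.na(combos$hop[i])) 40 else combos$hop[i])
    mp <- mfcc_params(if (is.na(combos$n_mfcc[i])) 20 else combos$n_mfcc[i],
                      framing = sp)
    feats <- prepare_features(c(clips_split, list(test = clips_split$val)),
                              feature_kind, sp, mp)
    fit <- train_one(feats, labels_split, feature_kind,
                     model_cfg$alpha, model_cfg$beta, budget)
    acc[i] <- fit$val_accuracy
    if (verbose)
      message(sprintf("combo %d/%d (L=%s R=%s n_mfcc=%s): val acc %.3f",
                      i, nrow(combos), combos$window[i], combos$hop[i],
                      combos$n_mfcc[i], acc[i]))
  }
  table <- cbind(combos, val_accuracy = acc)
  rownames(table) <- NULL
  best <- table[which.max(acc), , drop = FALSE]  # ties -> first in sort order
  list(best = as.list(best), table = table)
}

#' Run the feature-comparison experiment
#'
#' Trains one shrunk DS-CNN per feature kind (STFT, MFCC, fused) on the
#' train split, selects checkpoints on the validation split, evaluates each
#' on the held-out test split, and reports per-class metrics plus confusion
#' matrices in a single comparison table.
#'
#' @param manifest A corpus [lung_manifest()] (all four classes present).
#' @param model_cfg A [model_config()] giving alpha and beta.
#' @param tc A [train_config()].
#' @param feature_params Named list of feature parameters as produced by
#'   grid-search winners: `stft` (an [stft_params()]), `mfcc` and `fused`
#'   (each an [mfcc_params()] carrying its shared framing). Defaults to the
#'   selected combinations: STFT 512/40, 20 MFCCs, fused framing 256/40.
#' @param ratios,split_seed Split fractions and seed for
#'   [split_manifest()].
#' @param kinds Feature kinds to run (default all three).
#' @param out_dir Optional directory for CSV/JSON reports.
#' @param verbose Print progress.
#' @return A `level1_report`: per-feature fits, confusion matrices, metrics
#'   and the full configuration.
#' @export
run_level1 <- function(manifest, model_cfg = model_config(),
                       tc = train_config(),
                       feature_params = default_feature_params(),
                       ratios = c(train = 0.72, val = 0.08, test = 0.20),
                       split_seed = 1L,
                       kinds = c("stft", "mfcc", "fused"),
                       out_dir = NULL, verbose = FALSE) {
  splits <- split_manifest(manifest, ratios, seed = split_seed)
  for (s in names(splits))
    if (!all(lung_classes() %in% splits[[s]]$label))
      stop("class missing from the ", s, " split")
  clips_split <- lapply(splits, load_corpus)
  labels_split <- lapply(splits, function(m) m$label)

  results <- list()
  for (kind in kinds) {
    sp <- if (kind == "stft") feature_params$stft
          else feature_params[[kind]]$framing
    mp <- if (kind == "stft") feature_params$mfcc else feature_params[[kind]]
    if (verbose) message("feature: ", kind)
    feats <- prepare_features(clips_split, kind, sp, mp)
    fit <- train_one(feats, labels_split, kind, model_cfg$alpha,
                     model_cfg$beta, tc)
    pred <- predict(fit, feats$x_test)
    cm <- confusion(labels_split$test, pred)
    results[[kind]] <- list(fit = fit, confusion = cm, metrics = metrics(cm),
                            stats = feats$stats,
                            feature_rows = dim(feats$x_train)[1])
  }
  report <- structure(
    list(results = results,
         n_params = results[[1]]$fit$model$n_params,
         config = list(model = unclass(model_cfg), train = unclass(tc),
                       ratios = ratios, split_seed = split_seed,
                       n_clips = nrow(manifest))),
    class = "level1_report")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    for (kind in names(results))
      write_metrics(results[[kind]]$confusion, file.path(out_dir, kind))
    jsonlite::write_json(report_to_list(report),
                         file.path(out_dir, "level1_report.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  report
}

report_to_list <- function(report) {
  list(config = report$config,
       n_params = report$n_params,
       features = lapply(report$results, function(r)
         list(accuracy = r$metrics$accuracy,
              per_class = r$metrics$per_class,
              confusion = unclass(r$confusion),
              best_epoch = r$fit$best_epoch,
              val_accuracy = r$fit$val_accuracy)))
}

#' @export
print.level1_report <- function(x, ...) {
  kinds <- names(x$results)
  cat("Feature comparison (per-class F1 / REC / PRC, then accuracy)\n\n")
  classes <- lung_classes()
  hdr <- paste0(sprintf("%-15s", ""),
                paste(sprintf("%-22s", toupper(kinds)), collapse = ""))
  cat(hdr, "\n")
  for (cl in classes) {
    row <- sprintf("%-15s", cl)
    for (k in kinds) {
      pc <- x$results[[k]]$metrics$per_class
      i <- match(cl, pc$class)
      row <- paste0(row, sprintf("%.2f / %.2f / %.2f   ", pc$f1[i],
                                 pc$recall[i], pc$precision[i]))
    }
    cat(row, "\n")
  }
  row <- sprintf("%-15s", "accuracy")
  for (k in kinds)
    row <- paste0(row, sprintf("%-22s",
                               sprintf("%.2f%%", 100 * x$results[[k]]$metrics$accuracy)))
  cat(row, "\n")
  cat(sprintf("\nModel: %.2f M parameters\n", round(x$n_params / 1e6, 2)))
  invisible(x)
}
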