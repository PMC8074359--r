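# Training: Adam on softmax cross-entropy, batch statistics for
# normalization layers with running averages for inference, checkpointing on
# validation accuracy.

#' Training configuration
#'
#' The training schedule is a package choice (the classification method
#' itself does not prescribe one): adaptive-moment (Adam) optimization,
#' learning rate 1e-3, batch size 32, at most 50 epochs with early-stopping
#' patience 10, cross-entropy loss, no data augmentation, training from
#' random initialization.
#'
#' @param epochs Maximum epochs.
#' @param batch_size Minibatch size.
#' @param lr Learning rate.
#' @param optimizer Only `"adam"` is implemented.
#' @param seed Seed controlling initialization and batch shuffling.
#' @param patience Early-stopping patience in epochs (no improvement in
#'   validation accuracy).
#' @param bn_momentum Running-average momentum for normalization statistics.
#' @return A `train_config` list.
#' @export
train_config <- function(epochs = 50, batch_size = 32, lr = 1e-3,
                         optimizer = "adam", seed = 1L, patience = 10,
                         bn_momentum = 0.9) {
  optimizer <- match.arg(optimizer, "adam")
  stopifnot(epochs >= 1, batch_size >= 1, lr > 0, patience >= 1)
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), lr = lr,
                 optimizer = optimizer, seed = as.integer(seed),
                 patience = as.integer(patience), bn_momentum = bn_momentum),
            class = "train_config")
}

labels_to_int <- function(labels) {
  f <- factor(labels, levels = lung_classes())
  if (anyNA(f)) stop("labels must come from lung_classes()")
  as.integer(f) - 1L
}

#' Fit a depthwise-separable CNN classifier
#'
#' The central fitting function: trains a DS-CNN on feature arrays with
#' softmax cross-entropy and Adam, evaluating validation accuracy after
#' every epoch and returning the weights of the best-validation epoch.
#' Fully deterministic given the seeds in `model` and `config`.
#'
#' @param x_train `rows x frames x n` feature array (normalized with
#'   training-split statistics).
#' @param y_train Character labels (from [lung_classes()]) or 0-based
#'   integers.
#' @param x_val,y_val Validation split, same conventions.
#' @param model A [build_model()] result (its input dims must match `x`).
#' @param config A [train_config()].
#' @param verbose Print per-epoch progress.
#' @return A `dscnn_fit`: the trained model plus a per-epoch `history` data
#'   frame and the configuration.
#' @export
fit_dscnn <- function(x_train, y_train, x_val, y_val, model,
                      config = train_config(), verbose = FALSE) {
  stopifnot(inherits(model, "dscnn_model"), inherits(config, "train_config"))
  if (is.character(y_train) || is.factor(y_train)) y_train <- labels_to_int(y_train)
  if (is.character(y_val) || is.factor(y_val)) y_val <- labels_to_int(y_val)
  n <- dim(x_train)[3]
  stopifnot(n == length(y_train), dim(x_val)[3] == length(y_val))

  w <- model$weights
  param_idx <- which(vapply(w, Negate(is.null), TRUE))
  m_state <- lapply(w, function(v) if (is.null(v)) NULL else numeric(length(v)))
  v_state <- m_state
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  t_step <- 0L
  mom <- config$bn_momentum

  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(config$seed)

  best <- list(acc = -Inf, weights = w, bn = model$bn, epoch = 0L)
  history <- data.frame(epoch = integer(0), loss = numeric(0),
                        val_accuracy = numeric(0))
  stall <- 0L
  for (epoch in seq_len(config$epochs)) {
    ord <- sample.int(n)
    epoch_loss <- 0; n_batches <- 0L
    i <- 1L
    while (i <= n) {
      j <- min(i + config$batch_size - 1L, n)
      idx <- ord[i:j]
      xb <- x_train[, , idx, drop = FALSE]
      yb <- y_train[idx]
      model$weights <- w
      res <- engine_run(model, xb, yb, training = TRUE, want_grad = TRUE)
      if (!is.finite(res$loss))
        stop("training diverged (non-finite loss) at epoch ", epoch)
      epoch_loss <- epoch_loss + res$loss; n_batches <- n_batches + 1L
      t_step <- t_step + 1L
      corr1 <- 1 - beta1^t_step; corr2 <- 1 - beta2^t_step
      for (l in param_idx) {
        g <- res$grads[[l]]
        m_state[[l]] <- beta1 * m_state[[l]] + (1 - beta1) * g
        v_state[[l]] <- beta2 * v_state[[l]] + (1 - beta2) * g * g
        w[[l]] <- w[[l]] - config$lr * (m_state[[l]] / corr1) /
          (sqrt(v_state[[l]] / corr2) + eps)
      }
      for (l in seq_along(res$bn_mean)) {
        if (!is.null(res$bn_mean[[l]])) {
          model$bn$mean[[l]] <- mom * model$bn$mean[[l]] +
            (1 - mom) * res$bn_mean[[l]]
          model$bn$var[[l]] <- mom * model$bn$var[[l]] +
            (1 - mom) * res$bn_var[[l]]
        }
      }
      i <- j + 1L
    }
    model$weights <- w
    val_scores <- model_scores(model, x_val)
    val_pred <- max.col(t(val_scores), ties.method = "first") - 1L
    val_acc <- mean(val_pred == y_val)
    history <- rbind(history,
                     data.frame(epoch = epoch, loss = epoch_loss / n_batches,
                                val_accuracy = val_acc))
    if (verbose)
      message(sprintf("epoch %d: loss %.4f, val accuracy %.3f", epoch,
                      epoch_loss / n_batches, val_acc))
    if (val_acc > best$acc) {
      best <- list(acc = val_acc, weights = w, bn = model$bn, epoch = epoch)
      stall <- 0L
    } else {
      stall <- stall + 1L
      if (stall >= config$patience) break
    }
  }
  model$weights <- best$weights
  model$bn <- best$bn
  structure(list(model = model, history = history,
                 best_epoch = best$epoch, val_accuracy = best$acc,
                 config = config, classes = lung_classes()),
            class = "dscnn_fit")
}

#' @export
print.dscnn_fit <- function(x, ...) {
  cat(sprintf("<dscnn_fit> alpha=%g beta=%d, %.2f M parameters; best epoch %d/%d, val accuracy %.3f\n",
              x$model$config$alpha, x$model$config$beta,
              round(x$model$n_params / 1e6, 2), x$best_epoch,
              nrow(x$history), x$val_accuracy))
  invisible(x)
}

#' @export
summary.dscnn_fit <- function(object, ...) {
  cat("Depthwise-separable CNN classifier\n")
  print(object)
  cat("\nTraining history:\n")
  print(object$history, row.names = FALSE)
  invisible(object)
}

#' @export
plot.dscnn_fit <- function(x, ...) {
  h <- x$history
  plot(h$epoch, h$loss, type = "b", xlab = "epoch", ylab = "training loss",
       main = "DS-CNN training", ...)
  invisible(x)
}

#' Predict classes or scores from a fitted DS-CNN
#'
#' @param object A `dscnn_fit`.
#' @param x A `rows x frames x n` feature array normalized with the same
#'   training-split statistics used at fit time.
#' @param type `"class"` for labels, `"prob"` for softmax probabilities,
#'   `"score"` for raw logits.
#' @param ... Unused.
#' @return Labels, or a `classes x n` matrix.
#' @export
predict.dscnn_fit <- function(object, x, type = c("class", "prob", "score"),
                              ...) {
  type <- match.arg(type)
  if (length(dim(x)) == 2L) x <- array(x, dim = c(dim(x), 1L))
  scores <- model_scores(object$model, x)
  rownames(scores) <- object$classes
  if (type == "score") return(scores)
  if (type == "prob") {
    return(apply(scores, 2, function(s) {
      e <- exp(s - max(s)); e / sum(e)
    }))
  }
  object$classes[max.col(t(scores), ties.method = "first")]
}
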