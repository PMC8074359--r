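# Model construction: weight initialization over a layer plan, and the
# bridge to the compiled engine.

LAYER_TYPE_CODES <- c(standard_conv = 0L, depthwise_conv = 1L,
                      pointwise_conv = 2L, batch_norm = 3L,
                      activation = 4L, global_pool = 5L, dense = 6L)

plan_matrix <- function(plan) {
  cbind(type = LAYER_TYPE_CODES[plan$kind], k = plan$k, stride = plan$stride,
        in_ch = plan$in_ch, out_ch = plan$out_ch)
}

init_weights <- function(plan, seed) {
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  lapply(seq_len(nrow(plan)), function(l) {
    kind <- plan$kind[l]; k <- plan$k[l]
    n_in <- plan$in_ch[l]; n_out <- plan$out_ch[l]
    switch(kind,
      standard_conv  = rnorm(k * k * n_in * n_out, sd = sqrt(2 / (k * k * n_in))),
      depthwise_conv = rnorm(k * k * n_in, sd = sqrt(2 / (k * k))),
      pointwise_conv = rnorm(n_in * n_out, sd = sqrt(2 / n_in)),
      batch_norm     = c(rep(1, n_out), rep(0, n_out)),
      dense          = c(rnorm(n_in * n_out, sd = sqrt(2 / (n_in + n_out))),
                         rep(0, n_out)),
      NULL)
  })
}

init_bn_state <- function(plan) {
  mean_l <- vector("list", nrow(plan)); var_l <- vector("list", nrow(plan))
  for (l in which(plan$kind == "batch_norm")) {
    mean_l[[l]] <- rep(0, plan$out_ch[l])
    var_l[[l]] <- rep(1, plan$out_ch[l])
  }
  list(mean = mean_l, var = var_l)
}

#' Build a trainable DS-CNN from a layer plan
#'
#' Weights are drawn from seeded He/Glorot normal initializers, so the model
#' is a deterministic function of (plan, seed). The reported parameter count
#' always equals [count_params()] of the plan.
#'
#' @param plan A [block_plan()].
#' @param seed Integer seed for weight initialization.
#' @return A `dscnn_model` with the plan, weight list and batch-norm state.
#' @export
build_model <- function(plan, seed = 1L) {
  stopifnot(inherits(plan, "layer_plan"))
  cfg <- attr(plan, "config")
  # check spatial validity through the stride-2 stages
  h <- cfg$input_rows; w <- cfg$input_cols
  for (l in seq_len(nrow(plan))) {
    s <- plan$stride[l]
    if (plan$kind[l] %in% c("standard_conv", "depthwise_conv") && s > 1) {
      h <- ceiling(h / s); w <- ceiling(w / s)
    }
  }
  if (h < 1 || w < 1) stop("input spatial dimensions collapse before pooling")
  weights <- init_weights(plan, seed)
  n_params <- sum(vapply(weights, length, 0L))
  stopifnot(n_params == as.numeric(count_params(plan)))
  structure(list(plan = plan, config = cfg, weights = weights,
                 bn = init_bn_state(plan), seed = as.integer(seed),
                 n_params = n_params),
            class = "dscnn_model")
}

#' @export
print.dscnn_model <- function(x, ...) {
  cat(sprintf("<dscnn_model> alpha=%g beta=%d, input %dx%dx%d -> %d classes, %s parameters (%.2f M)\n",
              x$config$alpha, x$config$beta, x$config$input_rows,
              x$config$input_cols, x$config$in_channels, x$config$n_classes,
              format(x$n_params, big.mark = ","), round(x$n_params / 1e6, 2)))
  invisible(x)
}

# One engine call. x: (rows, cols, batch) array; y: integer 0-based or NULL.
engine_run <- function(model, x, y = NULL, training = FALSE, want_grad = FALSE) {
  pm <- plan_matrix(model$plan)
  storage.mode(pm) <- "integer"
  cpp_dscnn_run(pm, model$weights, x,
                if (is.null(y)) integer(0) else as.integer(y),
                model$bn$mean, model$bn$var, training, want_grad)
}

# Forward scores for a feature array, batched; returns K x n matrix.
model_scores <- function(model, x, batch_size = 32L) {
  n <- dim(x)[3]
  out <- matrix(0, model$config$n_classes, n)
  i <- 1L
  while (i <= n) {
    j <- min(i + batch_size - 1L, n)
    xb <- x[, , i:j, drop = FALSE]
    out[, i:j] <- engine_run(model, xb)$logits
    i <- j + 1L
  }
  out
}
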