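# Confusion matrices and per-class metrics.
#
# The confusion matrix M is 4x4 with rows = true labels and columns =
# predictions, in the fixed order continuous, discontinuous, normal,
# unknown. Per class i:
#   recall    REC_i = M[i,i] / sum_j M[i,j]
#   precision PRC_i = M[i,i] / sum_j M[j,i]
#   F1_i      = 2 * PRC * REC / (PRC + REC)
# and overall accuracy = trace(M) / sum(M). Empty rows/columns give NA (with
# a warning), never a silent zero.

#' Confusion matrix from true and predicted labels
#'
#' @param truth,predicted Equal-length label vectors drawn from
#'   [lung_classes()].
#' @return A `lung_confusion` 4x4 integer matrix (rows = truth, columns =
#'   prediction).
#' @export
confusion <- function(truth, predicted) {
  truth <- as.character(truth); predicted <- as.character(predicted)
  if (length(truth) != length(predicted))
    stop("truth and predicted must have the same length")
  bad <- setdiff(unique(c(truth, predicted)), lung_classes())
  if (length(bad)) stop("unknown labels: ", paste(bad, collapse = ", "))
  tf <- factor(truth, levels = lung_classes())
  pf <- factor(predicted, levels = lung_classes())
  m <- table(truth = tf, predicted = pf)
  m <- matrix(as.integer(m), 4, 4,
              dimnames = list(truth = lung_classes(),
                              predicted = lung_classes()))
  structure(m, class = c("lung_confusion", "matrix"))
}

#' Per-class and overall metrics from a confusion matrix
#'
#' @param matrix A `lung_confusion` (or any square count matrix with rows =
#'   truth, columns = prediction, identically ordered).
#' @return A `class_metrics` object: a `per_class` data frame with columns
#'   `class`, `recall`, `precision`, `f1` (NA where the denominator is
#'   zero) and the overall `accuracy`.
#' @export
metrics <- function(matrix) {
  m <- unclass(matrix)
  if (!is.matrix(m) || nrow(m) != ncol(m)) stop("need a square count matrix")
  if (sum(m) == 0) stop("empty confusion matrix")
  classes <- rownames(m)
  if (is.null(classes)) classes <- as.character(seq_len(nrow(m)))
  diagv <- diag(m)
  row_s <- rowSums(m); col_s <- colSums(m)
  rec <- ifelse(row_s > 0, diagv / row_s, NA_real_)
  prc <- ifelse(col_s > 0, diagv / col_s, NA_real_)
  f1 <- ifelse(!is.na(rec) & !is.na(prc) & (rec + prc) > 0,
               2 * prc * rec / (prc + rec), NA_real_)
  if (any(row_s == 0))
    warning("class(es) with no true samples: recall/F1 undefined (NA): ",
            paste(classes[row_s == 0], collapse = ", "))
  if (any(col_s == 0))
    warning("class(es) never predicted: precision/F1 undefined (NA): ",
            paste(classes[col_s == 0], collapse = ", "))
  structure(list(per_class = data.frame(class = classes, recall = rec,
                                        precision = prc, f1 = f1,
                                        row.names = NULL),
                 accuracy = sum(diagv) / sum(m)),
            class = "class_metrics")
}

#' @export
print.lung_confusion <- function(x, ...) {
  cat("Confusion matrix (rows = truth, columns = prediction):\n")
  print(unclass(x))
  invisible(x)
}

#' @export
print.class_metrics <- function(x, digits = 2, ...) {
  d <- x$per_class
  d$recall <- round(d$recall, digits)
  d$precision <- round(d$precision, digits)
  d$f1 <- round(d$f1, digits)
  print(d, row.names = FALSE)
  cat(sprintf("Accuracy: %.2f%%\n", 100 * x$accuracy))
  invisible(x)
}

#' Write a confusion matrix and its metrics to CSV and JSON
#'
#' @param matrix A `lung_confusion`.
#' @param prefix Output path prefix; writes `<prefix>_confusion.csv`,
#'   `<prefix>_metrics.csv` and `<prefix>_metrics.json`.
#' @return The metric object, invisibly.
#' @export
write_metrics <- function(matrix, prefix) {
  met <- metrics(matrix)
  write.csv(as.data.frame(unclass(matrix)),
            paste0(prefix, "_confusion.csv"))
  write.csv(met$per_class, paste0(prefix, "_metrics.csv"), row.names = FALSE)
  jsonlite::write_json(list(confusion = unclass(matrix),
                            per_class = met$per_class,
                            accuracy = met$accuracy),
                       paste0(prefix, "_metrics.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(met)
}
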