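# Confusion-matrix evaluation: counts (rows = actual, columns =
# predicted), row percentages, overall accuracy, per-class error.

round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

#' Evaluation report from a confusion matrix
#'
#' Wraps a K x K confusion-count matrix (rows actual, columns predicted)
#' with its derived quantities: row percentages, overall accuracy
#' (trace / total), and per-class error (1 minus the diagonal row
#' percentage). Percentages are reported rounded half-up to two decimals,
#' matching the conventional table formatting.
#'
#' @param counts square integer matrix of confusion counts; row/column
#'   names give the class labels.
#' @return an `eval_report` object with fields `counts`, `row_pct`,
#'   `accuracy` (proportion), `accuracy_pct` (rounded percent), and
#'   `per_class_error_pct`.
#' @examples
#' cm <- matrix(c(9, 1, 2, 8), 2, byrow = TRUE,
#'              dimnames = list(c("a", "b"), c("a", "b")))
#' eval_report(cm)$accuracy
#' @export
eval_report <- function(counts) {
  counts <- as.matrix(counts)
  if (nrow(counts) != ncol(counts)) stop("confusion matrix must be square")
  if (any(counts < 0) || anyNA(counts)) stop("counts must be non-negative")
  if (is.null(rownames(counts)))
    rownames(counts) <- colnames(counts) <- paste0("class_", seq_len(nrow(counts)))
  row_tot <- rowSums(counts)
  row_pct <- sweep(counts, 1, pmax(row_tot, 1), "/") * 100
  acc <- sum(diag(counts)) / sum(counts)
  structure(list(counts = counts,
                 row_pct = row_pct,
                 accuracy = acc,
                 accuracy_pct = round_half_up(acc * 100, 2),
                 per_class_error_pct = round_half_up(100 - diag(row_pct), 2)),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> overall accuracy %.2f%% (%d / %d)\n",
              x$accuracy_pct, sum(diag(x$counts)), sum(x$counts)))
  k <- nrow(x$counts)
  disp <- matrix("", k, k, dimnames = dimnames(x$counts))
  for (i in seq_len(k)) for (j in seq_len(k))
    disp[i, j] <- sprintf("%.2f%% (%d)", round_half_up(x$row_pct[i, j], 2),
                          x$counts[i, j])
  print(disp, quote = FALSE)
  cat("per-class error (%):\n")
  print(x$per_class_error_pct)
  invisible(x)
}

#' Evaluate a model on a held-out test set
#'
#' Predicts every test clip and assembles the confusion matrix in the
#' model's class order.
#'
#' @param model a trained `anuran_cnn`.
#' @param x `(h, w, N)` test feature array.
#' @param y true labels (already merged for the 4-class task).
#' @return an [eval_report()].
#' @export
evaluate_model <- function(model, x, y) {
  stopifnot(inherits(model, "anuran_cnn"), isTRUE(model$trained))
  y <- as.character(y)
  if (length(y) == 0L) stop("empty test set")
  pred <- predict(model, x, type = "class")
  classes <- model$classes
  counts <- table(factor(y, levels = classes),
                  factor(pred, levels = classes))
  eval_report(unclass(as.matrix(counts)))
}

#' Merge a 5-class confusion matrix to the 4-class task
#'
#' Sums the `ec_standard` and `ec_chorus` rows and columns into the single
#' merged `ec_st&ch` class; the total count is preserved.
#'
#' @param counts 5 x 5 confusion matrix with rows/columns named by
#'   [call_classes()].
#' @return the 4 x 4 merged confusion matrix.
#' @export
merge_confusion <- function(counts) {
  stopifnot(all(dim(counts) == 5L))
  if (is.null(rownames(counts))) rownames(counts) <- colnames(counts) <- call_classes()
  agg <- function(m) {
    grp <- merge_class(rownames(m))
    rowsum(m, factor(grp, levels = merged_classes()))
  }
  out <- t(agg(t(agg(as.matrix(counts)))))
  dimnames(out) <- list(merged_classes(), merged_classes())
  out
}
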