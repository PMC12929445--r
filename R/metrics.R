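# Accuracy assessment: confusion matrices and the derived metric suite
# (overall accuracy, per-class precision/recall/F1, chance agreement and
# Cohen's kappa). Rows index the reference class, columns the prediction.

#' Accumulate a confusion matrix
#'
#' @param pred,true Integer labels in `0..n_classes-1`; vectors, matrices, or
#'   lists of matrices (e.g. one per patch) of matching total length.
#' @param n_classes Number of classes.
#' @param ignore Optional integer vector of class ids excluded from both
#'   axes; pixels whose reference or predicted label is ignored are dropped.
#' @return Integer matrix with `dimnames` giving the retained class ids,
#'   class `confusion_matrix`. Rows are reference counts `a_{i+}`, columns
#'   predicted counts `a_{+i}`.
#' @export
confusion_counts <- function(pred, true, n_classes, ignore = NULL) {
  if (is.list(pred)) pred <- unlist(lapply(pred, as.integer))
  if (is.list(true)) true <- unlist(lapply(true, as.integer))
  pred <- as.integer(pred); true <- as.integer(true)
  if (length(pred) != length(true)) stop("pred and true differ in length")
  K <- as.integer(n_classes)
  if (any(pred < 0L | pred >= K) || any(true < 0L | true >= K)) {
    stop(sprintf("labels must lie in [0, %d)", K))
  }
  keep_class <- setdiff(0:(K - 1L), as.integer(ignore))
  sel <- true %in% keep_class & pred %in% keep_class
  if (!any(sel)) {
    warning("no pixels left after exclusion; confusion matrix is empty")
    cm <- matrix(0L, length(keep_class), length(keep_class),
                 dimnames = list(keep_class, keep_class))
    class(cm) <- c("confusion_matrix", class(cm))
    return(cm)
  }
  ri <- match(true[sel], keep_class)
  ci <- match(pred[sel], keep_class)
  n <- length(keep_class)
  cm <- matrix(tabulate((ci - 1L) * n + ri, nbins = n * n), n, n,
               dimnames = list(keep_class, keep_class))
  class(cm) <- c("confusion_matrix", class(cm))
  cm
}

#' Metric suite from a confusion matrix
#'
#' Overall accuracy `OA = sum(a_ii)/N`; per-class precision
#' `P_i = a_ii / a_{+i}` (predicted-total denominator), recall
#' `R_i = a_ii / a_{i+}` (reference-total denominator),
#' `F1_i = 2 P_i R_i / (P_i + R_i)`; chance agreement
#' `p_c = sum(a_{i+} a_{+i}) / N^2` and `Kappa = (OA - p_c) / (1 - p_c)`.
#' Classes with zero support get zero metrics with a warning.
#'
#' @param cm Square counts matrix (reference rows, predicted columns).
#' @return Object of class `metrics_report`: list with `oa`, `kappa`, `pc`,
#'   and `per_class` (data frame with class, support, precision, recall, f1).
#' @export
classification_metrics <- function(cm) {
  cm <- unclass(as.matrix(cm))
  if (nrow(cm) != ncol(cm)) stop("confusion matrix must be square")
  N <- sum(cm)
  if (N == 0) stop("empty confusion matrix (N = 0)")
  di <- diag(cm)
  rs <- rowSums(cm)   # a_{i+}: reference totals
  cs <- colSums(cm)   # a_{+i}: predicted totals
  oa <- sum(di) / N
  if (any(rs == 0)) {
    warning(sprintf("class(es) %s have zero reference support; metrics set to 0",
                    paste(rownames(cm)[rs == 0] %||% which(rs == 0),
                          collapse = ", ")))
  }
  P <- ifelse(cs > 0, di / cs, 0)
  R <- ifelse(rs > 0, di / rs, 0)
  F1 <- ifelse(P + R > 0, 2 * P * R / (P + R), 0)
  pc <- sum(rs * cs) / N^2
  kappa <- if (abs(1 - pc) < 1e-12) {
    if (oa >= 1) 1 else 0
  } else (oa - pc) / (1 - pc)
  cls <- rownames(cm) %||% as.character(seq_len(nrow(cm)) - 1L)
  structure(list(oa = oa, kappa = kappa, pc = pc,
                 per_class = data.frame(class = cls, support = as.integer(rs),
                                        precision = P, recall = R, f1 = F1,
                                        row.names = NULL)),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, digits = 4, ...) {
  cat("Per-class accuracy:\n")
  df <- x$per_class
  df$precision <- round(df$precision, digits)
  df$recall <- round(df$recall, digits)
  df$f1 <- round(df$f1, digits)
  print(df, row.names = FALSE)
  cat(sprintf("\nOA %.4f | Kappa %.4f (chance agreement %.4f)\n",
              x$oa, x$kappa, x$pc))
  invisible(x)
}

#' Write a metrics report as a CSV table
#'
#' Columns class, precision, recall, f1, with footer rows for OA and Kappa.
#'
#' @param report A [classification_metrics()] result.
#' @param path Destination file.
#' @param class_names Optional names replacing the class ids.
#' @export
write_metrics_csv <- function(report, path, class_names = NULL) {
  df <- report$per_class[, c("class", "precision", "recall", "f1")]
  if (!is.null(class_names)) {
    df$class <- class_names[as.integer(df$class) + 1L]
  }
  foot <- data.frame(class = c("OA", "Kappa"),
                     precision = c(report$oa, report$kappa),
                     recall = NA_real_, f1 = NA_real_)
  utils::write.csv(rbind(df, foot), path, row.names = FALSE)
  invisible(path)
}
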