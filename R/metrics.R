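# Segmentation metrics from a per-class pixel confusion matrix.
#
# counts[k, l] = number of pixels whose true class is k and predicted class
# is l (classes are 0-based labels, rows/cols 1-based in R).  Miou and MPA
# skip classes with an empty union / empty truth row: images without fish
# would otherwise contribute an undefined 0/0 term.

#' Create an empty confusion matrix
#' @param n_classes number of classes (2 for fish/background).
#' @return integer `n_classes x n_classes` matrix, rows = truth, cols =
#'   prediction.
#' @export
confusion_matrix <- function(n_classes = 2L) {
  m <- matrix(0L, n_classes, n_classes)
  dimnames(m) <- list(truth = 0:(n_classes - 1L), pred = 0:(n_classes - 1L))
  class(m) <- c("fishseg_cm", class(m))
  m
}

#' Accumulate a prediction/truth pair into a confusion matrix
#'
#' Associative over batches: the order of accumulation never changes the
#' final matrix.
#' @param cm matrix from [confusion_matrix()].
#' @param pred,truth equally shaped integer arrays with values in
#'   `0..n_classes-1`.
#' @return the updated confusion matrix.
#' @export
cm_accumulate <- function(cm, pred, truth) {
  if (!identical(dim(pred), dim(truth)))
    stop("pred and truth must have the same shape", call. = FALSE)
  k <- nrow(cm)
  lv <- 0:(k - 1L)
  if (any(!(pred %in% lv)) || any(!(truth %in% lv)))
    stop("labels out of range 0..", k - 1L, call. = FALSE)
  tab <- table(factor(as.vector(truth), levels = lv),
               factor(as.vector(pred), levels = lv))
  cm + matrix(as.integer(tab), k, k)
}

cm_check <- function(cm) {
  if (sum(cm) == 0) stop("metric undefined on an all-zero confusion matrix",
                         call. = FALSE)
}

#' Mean intersection-over-union
#'
#' `mean_k diag_k / (row_k + col_k - diag_k)`, skipping classes whose union is
#' zero (absent in both truth and prediction).
#' @param cm confusion matrix.
#' @return scalar in `[0, 1]`.
#' @export
miou <- function(cm) {
  cm_check(cm)
  di <- diag(cm)
  union <- rowSums(cm) + colSums(cm) - di
  keep <- union > 0
  mean(di[keep] / union[keep])
}

#' Mean per-class pixel accuracy
#' @param cm confusion matrix.
#' @return mean over classes (with nonzero truth pixels) of
#'   `diag_k / row_k`.
#' @export
mpa <- function(cm) {
  cm_check(cm)
  di <- diag(cm)
  rs <- rowSums(cm)
  keep <- rs > 0
  mean(di[keep] / rs[keep])
}

#' Per-class pixel accuracy
#' @param cm confusion matrix.
#' @param k 0-based class label (0 = background).
#' @return `diag_k / row_k`.
#' @export
class_accuracy <- function(cm, k) {
  cm_check(cm)
  i <- k + 1L
  rs <- rowSums(cm)[i]
  if (rs == 0) stop("class ", k, " has no truth pixels", call. = FALSE)
  unname(diag(cm)[i] / rs)
}
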