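# SoftPool: exponentially weighted spatial pooling.
#
# For a window with index set R and activations a_i, the output is
#   a~ = sum_i exp(a_i) a_i / sum_j exp(a_j),
# a softmax-of-activations weighted mean.  It is parameter free, lies
# elementwise between average pooling and max pooling, and (unlike max
# pooling) propagates gradient to every window element.  Padded positions are
# excluded from R, so border outputs stay inside the data range.

#' Exponentially weighted (SoftPool) 2D pooling
#'
#' Replaces average pooling in the backbone: each output value is the
#' softmax-of-activations weighted mean of its window, computed per channel.
#' Implementation subtracts the per-window maximum before exponentiation,
#' which is exact because softmax weights are invariant to a constant shift.
#'
#' @param x numeric array, `(channels, height, width)` feature map.
#' @param kernel integer window size, length 1 or 2 (rows, cols).
#' @param stride integer stride, length 1 or 2; defaults to `kernel`.
#' @param padding integer zero-padding, length 1 or 2. Padded positions are
#'   excluded from the pooling window rather than treated as zeros.
#' @return pooled feature map with the standard floor output-size convention.
#' @examples
#' x <- array(1:4, c(1, 2, 2))
#' softpool2d(x, kernel = 2)  # ~3.4927, between mean (2.5) and max (4)
#' @export
softpool2d <- function(x, kernel = 2L, stride = kernel, padding = 0L) {
  x <- as_4d(x)
  kernel <- rep(as.integer(kernel), length.out = 2L)
  stride <- rep(as.integer(stride), length.out = 2L)
  padding <- rep(as.integer(padding), length.out = 2L)
  if (any(kernel < 1L) || any(stride < 1L))
    stop("kernel and stride must be positive", call. = FALSE)
  if (dim(x)[2L] + 2L * padding[1L] < kernel[1L] ||
      dim(x)[3L] + 2L * padding[2L] < kernel[2L])
    stop("kernel larger than padded input", call. = FALSE)
  out <- ag_softpool(ag_tensor(x), kernel, stride, padding)
  drop_batch(out$v)
}

#' Scalar reference implementation of SoftPool (test oracle)
#'
#' Direct loop evaluation of the defining weighted sum, kept independent of
#' the vectorised kernel in `softpool2d()` so the two can be checked against
#' each other. Intended for small inputs only.
#'
#' @inheritParams softpool2d
#' @return pooled feature map, identical contract to [softpool2d()].
#' @export
softpool_reference <- function(x, kernel = 2L, stride = kernel, padding = 0L) {
  x <- as_4d(x)
  if (!all(is.finite(x))) stop("softpool: non-finite values in input", call. = FALSE)
  kernel <- rep(as.integer(kernel), length.out = 2L)
  stride <- rep(as.integer(stride), length.out = 2L)
  padding <- rep(as.integer(padding), length.out = 2L)
  d <- dim(x)
  if (d[2L] + 2L * padding[1L] < kernel[1L] ||
      d[3L] + 2L * padding[2L] < kernel[2L])
    stop("kernel larger than padded input", call. = FALSE)
  ho <- (d[2L] + 2L * padding[1L] - kernel[1L]) %/% stride[1L] + 1L
  wo <- (d[3L] + 2L * padding[2L] - kernel[2L]) %/% stride[2L] + 1L
  out <- array(0, c(d[1L], ho, wo, d[4L]))
  for (n in seq_len(d[4L])) for (cc in seq_len(d[1L])) {
    for (ow in seq_len(wo)) for (oh in seq_len(ho)) {
      hs <- (oh - 1L) * stride[1L] - padding[1L] + seq_len(kernel[1L])
      ws <- (ow - 1L) * stride[2L] - padding[2L] + seq_len(kernel[2L])
      hs <- hs[hs >= 1L & hs <= d[2L]]
      ws <- ws[ws >= 1L & ws <= d[3L]]
      a <- as.vector(x[cc, hs, ws, n])
      w <- exp(a - max(a))
      out[cc, oh, ow, n] <- sum(w * a) / sum(w)
    }
  }
  drop_batch(out)
}
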