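# Triplet attention (TA): three-branch cross-dimension attention.
#
# Z-pool stacks the max and the mean over a tensor's leading dimension,
# turning (D, H, W) into (2, H, W).  Each TA branch views the input with a
# different axis in front — branch 1 rotates about the height axis, branch 2
# about the width axis, branch 3 leaves the tensor alone — then gates the
# rotated view with
# sigmoid(batchnorm(conv7x7(zpool(view)))) and rotates back.  The output is
# the arithmetic mean of the enabled branches.  Rotation is implemented as an
# axis permutation; the sign of the rotation is irrelevant because the
# inverse permutation is applied after gating.
#
# Branch naming (layout (C, H, W)):
#   "height":  permute to (H, C, W)  — pools over H, couples C with W
#   "width":   permute to (W, H, C)  — pools over W, couples H with C
#   "spatial": no permutation        — pools over C, plain spatial attention

TA_BRANCHES <- c("height", "width", "spatial")

#' Z-pool: stack max and mean over the leading dimension
#'
#' @param x numeric array whose first dimension is reduced; `(C, H, W)` in the
#'   usual case.
#' @return array `(2, H, W)`: channel 1 the elementwise max, channel 2 the
#'   elementwise mean over the leading dimension.
#' @export
z_pool <- function(x) {
  x <- as_4d(x)
  drop_batch(ag_zpool(ag_tensor(x))$v)
}

ta_perms <- list(height = c(2L, 1L, 3L), width = c(3L, 2L, 1L),
                 spatial = c(1L, 2L, 3L))

#' Create a triplet attention (TA) module
#'
#' Each enabled branch owns one `(2 -> 1)` convolution of size
#' `kernel x kernel` (padding preserves the spatial size) followed by batch
#' normalisation; the whole module costs ~300 parameters and is channel-count
#' agnostic, which is what makes weight sharing across pyramid scales free.
#'
#' @param kernel odd convolution size (7 in the reference design).
#' @param branches subset of `c("height", "width", "spatial")`.
#' @param init `"he"` or `"zero"` initialisation.
#' @return a TA module for [ta_forward()] / [shared_ta_apply()].
#' @export
ta_module <- function(kernel = 7L, branches = TA_BRANCHES, init = "he") {
  if (length(branches) < 1L) stop("at least one branch must be enabled", call. = FALSE)
  branches <- match.arg(branches, TA_BRANCHES, several.ok = TRUE)
  m <- new_module("triplet_attention")
  m$kernel <- as.integer(kernel)
  m$pad <- (m$kernel - 1L) %/% 2L
  m$branches <- branches
  for (b in branches) {
    m$children[[paste0("conv_", b)]] <-
      nn_conv2d(2L, 1L, m$kernel, pad = m$pad, init = init)
    m$children[[paste0("bn_", b)]] <- nn_batchnorm(1L)
  }
  m$forward <- function(x, training = FALSE) {
    outs <- lapply(m$branches, function(b) {
      p <- ta_perms[[b]]
      xb <- if (b == "spatial") x else ag_permute(x, p)
      z <- ag_zpool(xb)
      a <- m$children[[paste0("conv_", b)]]$forward(z, training)
      a <- m$children[[paste0("bn_", b)]]$forward(a, training)
      gate <- ag_sigmoid(a)
      gated <- ag_gate_mul(xb, gate)
      if (b == "spatial") gated else ag_permute(gated, order(p))
    })
    ag_mean_list(outs)
  }
  m$audit <- function(shape) {
    macs <- 0
    for (b in m$branches) {
      p <- ta_perms[[b]]
      sb <- shape[p]
      macs <- macs + 2 * prod(shape) +                     # z-pool (max + mean)
        m$children[[paste0("conv_", b)]]$audit(c(2L, sb[2:3]))$macs
    }
    list(shape = shape, macs = macs)
  }
  m
}

#' Apply triplet attention to a feature map
#'
#' @param x numeric `(C, H, W)` array.
#' @param module a [ta_module()].
#' @param training logical; batch-statistics mode.
#' @return array of the same shape; elementwise `|out| <= |x|` because every
#'   branch multiplies by a sigmoid gate in (0, 1).
#' @export
ta_forward <- function(x, module, training = FALSE) {
  x <- as_4d(x)
  if (length(dim(x)) != 4L) stop("ta_forward: input must be C x H x W", call. = FALSE)
  drop_batch(module$forward(ag_tensor(x), training)$v)
}

#' Apply one shared TA module across pyramid branches
#'
#' The parameter-sharing strategy: a single TA parameter set (conceptually the
#' one learned on the smallest-scale branch) is applied to every pyramid
#' branch, so TA costs one module's parameters no matter how many branches
#' carry it.
#'
#' @param features list of `(C, H, W)` arrays with a common channel count.
#' @param module a [ta_module()].
#' @param training logical.
#' @return list of attended feature maps, same shapes as the input.
#' @export
shared_ta_apply <- function(features, module, training = FALSE) {
  cs <- vapply(features, function(f) dim(as_4d(f))[1L], integer(1))
  if (length(unique(cs)) != 1L)
    stop("shared TA needs a common channel count across branches", call. = FALSE)
  lapply(features, ta_forward, module = module, training = training)
}
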