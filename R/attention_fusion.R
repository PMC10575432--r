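# MS-CAM multi-scale channel attention and the AFF / iAFF fusion operators.
#
# MS-CAM sums a global branch (global average pool -> 1x1 bottleneck) and a
# local branch (the same bottleneck applied per pixel), then squashes through
# a sigmoid to give a fusion weight map M with entries strictly in (0, 1).
# AFF fuses an identity path X with a residual path Y as
#   X (+) Y = M(X + Y) * X + (1 - M(X + Y)) * Y,
# and iAFF iterates: the initial integration X (+) Y is itself an AFF with
# its own MS-CAM, and a second, independent MS-CAM produces the final weight:
#   Z = M(X (+) Y) * X + (1 - M(X (+) Y)) * Y.
# Every output is therefore an elementwise convex combination of X and Y.

mscam_branch <- function(channels, inter, init) {
  nn_sequential(
    conv1 = nn_conv2d(channels, inter, 1L, init = init),
    bn1 = nn_batchnorm(inter),
    relu = nn_relu(),
    conv2 = nn_conv2d(inter, channels, 1L, init = init),
    bn2 = nn_batchnorm(channels)
  )
}

#' Create an MS-CAM multi-scale channel attention module
#'
#' Both branches use a 1x1-conv bottleneck `channels -> channels/r ->
#' channels` with batch normalisation; the global branch sees the globally
#' average-pooled feature (one value per channel), the local branch runs per
#' pixel. Their sum passes through a sigmoid.
#'
#' @param channels number of input/output channels.
#' @param r reduction ratio of the bottleneck; the hidden width is
#'   `max(1, channels %/% r)`. The package default of 25 is calibrated so that
#'   fusing every residual block of the backbone costs about 6.4 M parameters
#'   (see the methods vignette).
#' @param init `"he"` (random) or `"zero"` weight initialisation.
#' @return an MS-CAM module usable with [ms_cam()] or inside fusion modules.
#' @export
ms_cam_module <- function(channels, r = 25L, init = "he") {
  if (channels < 1L || r < 1L) stop("channels and r must be positive", call. = FALSE)
  inter <- max(1L, channels %/% as.integer(r))
  m <- new_module("ms_cam")
  m$channels <- channels
  m$r <- r
  m$inter <- inter
  m$children$gap <- nn_global_avgpool()
  m$children$global <- mscam_branch(channels, inter, init)
  m$children$local <- mscam_branch(channels, inter, init)
  m$forward <- function(x, training = FALSE) {
    if (dim(x$v)[1L] != m$channels)
      stop("ms_cam: input has ", dim(x$v)[1L], " channels, module expects ",
           m$channels, call. = FALSE)
    g <- m$children$global$forward(m$children$gap$forward(x, training), training)
    l <- m$children$local$forward(x, training)
    ag_sigmoid(ag_broadcast_add(l, g))
  }
  m$audit <- function(shape) {
    macs <- m$children$gap$audit(shape)$macs +
      m$children$global$audit(c(shape[1L], 1L, 1L))$macs +
      m$children$local$audit(shape)$macs
    list(shape = shape, macs = macs)
  }
  m
}

#' Compute MS-CAM fusion weights for a feature map
#'
#' @param x numeric `(channels, height, width)` array.
#' @param module an [ms_cam_module()].
#' @param training logical; use batch statistics in the normalisation layers.
#' @return array of the same shape with values strictly in (0, 1).
#' @export
ms_cam <- function(x, module, training = FALSE) {
  drop_batch(module$forward(ag_tensor(as_4d(x)), training)$v)
}

# Convex fusion with an explicit weight map: M*x + (1-M)*y,
# fused into one tape node to keep activation memory down.
fuse_convex_nodes <- function(x, y, m) {
  ag_fuse_convex(x, y, m)
}

#' Convex fusion of two feature maps with an explicit weight
#'
#' Computes `m * x + (1 - m) * y` elementwise; exposed mainly so tests can
#' probe the fusion algebra with frozen weights.
#' @param x,y equally shaped numeric arrays.
#' @param m weight array in `[0, 1]`, same shape (or broadcastable scalar).
#' @return fused array.
#' @keywords internal
#' @export
fuse_convex <- function(x, y, m) {
  if (length(m) == 1L) m <- array(m, dim(x))
  m * x + (1 - m) * y
}

check_same_shape <- function(x, y) {
  if (!identical(dim(x), dim(y)))
    stop("fusion inputs must have identical shapes", call. = FALSE)
}

#' Create an AFF (attentional feature fusion) module
#'
#' @inheritParams ms_cam_module
#' @return a fusion module with `forward2(x, y, training)` fusing an identity
#'   path `x` with a residual path `y`.
#' @export
aff_module <- function(channels, r = 25L, init = "he") {
  m <- new_module("aff")
  m$channels <- channels
  m$children$mscam <- ms_cam_module(channels, r, init)
  m$forward2 <- function(x, y, training = FALSE) {
    w <- m$children$mscam$forward(ag_add(x, y), training)
    fuse_convex_nodes(x, y, w)
  }
  m$forward <- function(x, training = FALSE)
    stop("aff is a two-input module; use forward2", call. = FALSE)
  m$audit <- function(shape) {
    list(shape = shape, macs = m$children$mscam$audit(shape)$macs)
  }
  m
}

#' Create an iAFF (iterative attentional feature fusion) module
#'
#' Two MS-CAM instances with distinct parameters: the first produces the
#' initial integration `X (+) Y`, the second weights the final fusion.
#' @inheritParams ms_cam_module
#' @return a fusion module with `forward2(x, y, training)`.
#' @export
iaff_module <- function(channels, r = 25L, init = "he") {
  m <- new_module("iaff")
  m$channels <- channels
  m$children$mscam1 <- ms_cam_module(channels, r, init)
  m$children$mscam2 <- ms_cam_module(channels, r, init)
  m$forward2 <- function(x, y, training = FALSE) {
    w1 <- m$children$mscam1$forward(ag_add(x, y), training)
    inner <- fuse_convex_nodes(x, y, w1)
    w2 <- m$children$mscam2$forward(inner, training)
    fuse_convex_nodes(x, y, w2)
  }
  m$forward <- function(x, training = FALSE)
    stop("iaff is a two-input module; use forward2", call. = FALSE)
  m$audit <- function(shape) {
    list(shape = shape, macs = m$children$mscam1$audit(shape)$macs +
           m$children$mscam2$audit(shape)$macs)
  }
  m
}

# "add" fusion: the plain residual sum, for the baseline variant.
add_fusion_module <- function() {
  m <- new_module("add_fusion")
  m$forward2 <- function(x, y, training = FALSE) ag_add(x, y)
  m$forward <- function(x, training = FALSE)
    stop("two-input module; use forward2", call. = FALSE)
  m$audit <- function(shape) list(shape = shape, macs = 0)
  m
}

#' Attentional feature fusion of an identity and a residual path
#'
#' @param x identity/shortcut feature map `(channels, height, width)`.
#' @param y residual feature map, same shape.
#' @param module an [aff_module()] (for [aff()]) or [iaff_module()] (for
#'   [iaff()]) with matching channel count.
#' @param training logical; batch-statistics mode for normalisation.
#' @return fused feature map, elementwise between `min(x, y)` and `max(x, y)`.
#' @export
aff <- function(x, y, module, training = FALSE) {
  check_same_shape(x, y)
  drop_batch(module$forward2(ag_tensor(as_4d(x)), ag_tensor(as_4d(y)),
                             training)$v)
}

#' @rdname aff
#' @export
iaff <- function(x, y, module, training = FALSE) {
  check_same_shape(x, y)
  drop_batch(module$forward2(ag_tensor(as_4d(x)), ag_tensor(as_4d(y)),
                             training)$v)
}

#' Closed-form MS-CAM parameter count
#'
#' `4*C*i + 4*i + 4*C` with bottleneck width `i = max(1, C %/% r)`: two
#' branches, each two 1x1 convolutions plus their batch-norm scale/shift.
#' @inheritParams ms_cam_module
#' @return expected number of trainable parameters of one MS-CAM.
#' @export
ms_cam_param_formula <- function(channels, r = 25L) {
  i <- max(1L, channels %/% as.integer(r))
  4 * channels * i + 4 * i + 4 * channels
}
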