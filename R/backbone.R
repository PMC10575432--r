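# Dilated ResNet50 feature extractor (output stride 8).
#
# Deep 3x3 stem (3->64->64->128, the stem used by the canonical PSPNet
# implementations), four bottleneck stages with channel plan
# (256, 512, 1024, 2048); stages 3 and 4 use dilation 2 and 4 with stride 1.
# Downsampling shortcuts are ResNet-D style: a 2x2 average pool (the AvgPool
# the SoftPool swap targets) followed by a stride-1 1x1 projection.  The
# residual merge `identity + residual` is configurable: plain addition, AFF,
# or iAFF.

bottleneck_module <- function(cin, mid, cout, stride = 1L, dilation = 1L,
                              fusion = "add", pool = "avg", ratio = 25L,
                              init = "he") {
  m <- new_module("bottleneck")
  m$cin <- cin; m$cout <- cout; m$stride <- stride
  m$children$conv1 <- conv_bn_relu(cin, mid, 1L, init = init)
  m$children$conv2 <- conv_bn_relu(mid, mid, 3L, stride = stride,
                                   pad = dilation, dil = dilation, init = init)
  m$children$conv3 <- nn_sequential(conv = nn_conv2d(mid, cout, 1L, init = init),
                                    bn = nn_batchnorm(cout))
  if (cin != cout || stride != 1L) {
    down <- list()
    if (stride != 1L) {
      down$pool <- if (pool == "soft") nn_softpool(2L, 2L) else nn_avgpool(2L, 2L)
    }
    down$conv <- nn_conv2d(cin, cout, 1L, init = init)
    down$bn <- nn_batchnorm(cout)
    m$children$shortcut <- do.call(nn_sequential, down)
  }
  m$children$fuse <- switch(fusion,
    add = add_fusion_module(),
    aff = aff_module(cout, ratio, init),
    iaff = iaff_module(cout, ratio, init),
    stop("unknown fusion '", fusion, "'", call. = FALSE))
  m$children$relu_out <- nn_relu()
  m$forward <- function(x, training = FALSE) {
    res <- m$children$conv1$forward(x, training)
    res <- m$children$conv2$forward(res, training)
    res <- m$children$conv3$forward(res, training)
    idn <- if (!is.null(m$children$shortcut))
      m$children$shortcut$forward(x, training) else x
    out <- m$children$fuse$forward2(idn, res, training)
    m$children$relu_out$forward(out, training)
  }
  m$audit <- function(shape) {
    a1 <- m$children$conv1$audit(shape)
    a2 <- m$children$conv2$audit(a1$shape)
    a3 <- m$children$conv3$audit(a2$shape)
    macs <- a1$macs + a2$macs + a3$macs
    if (!is.null(m$children$shortcut))
      macs <- macs + m$children$shortcut$audit(shape)$macs
    macs <- macs + m$children$fuse$audit(a3$shape)$macs
    list(shape = a3$shape, macs = macs)
  }
  m
}

resnet_stage <- function(cin, mid, cout, blocks, stride, dilation,
                         fusion, pool, ratio, init) {
  mods <- list(bottleneck_module(cin, mid, cout, stride, dilation,
                                 fusion, pool, ratio, init))
  for (i in seq_len(blocks - 1L)) {
    mods[[i + 1L]] <- bottleneck_module(cout, mid, cout, 1L, dilation,
                                        fusion, pool, ratio, init)
  }
  names(mods) <- sprintf("block%d", seq_along(mods))
  do.call(nn_sequential, mods)
}

#' Build the dilated ResNet50 backbone
#'
#' @param fusion residual merge: `"add"` (baseline), `"aff"`, or `"iaff"`.
#' @param pool downsampling pool in the shortcut path: `"avg"` or `"soft"`
#'   (SoftPool). A parameter-free swap: shapes and parameter counts are
#'   unchanged.
#' @param output_stride only 8 is supported (PSPNet convention).
#' @param ms_cam_ratio MS-CAM reduction ratio used when `fusion != "add"`.
#' @param init `"he"` or `"zero"` weight initialisation (`"zero"` is handy for
#'   audits, which never run a forward pass).
#' @return a backbone module; its `forward` returns
#'   `list(main = (2048, H/8, W/8), aux = (1024, H/8, W/8))`.
#' @export
build_backbone <- function(fusion = c("add", "aff", "iaff"),
                           pool = c("avg", "soft"),
                           output_stride = 8L, ms_cam_ratio = 25L,
                           init = "he") {
  fusion <- match.arg(fusion)
  pool <- match.arg(pool)
  if (output_stride != 8L)
    stop("only output stride 8 is supported", call. = FALSE)
  m <- new_module("backbone")
  m$fusion <- fusion; m$pool <- pool; m$output_stride <- 8L
  m$children$stem <- nn_sequential(
    conv_bn_relu(3L, 64L, 3L, stride = 2L, pad = 1L, init = init),
    conv_bn_relu(64L, 64L, 3L, pad = 1L, init = init),
    conv_bn_relu(64L, 128L, 3L, pad = 1L, init = init),
    nn_maxpool(3L, 2L, 1L)
  )
  m$children$layer1 <- resnet_stage(128L, 64L, 256L, 3L, 1L, 1L,
                                    fusion, pool, ms_cam_ratio, init)
  m$children$layer2 <- resnet_stage(256L, 128L, 512L, 4L, 2L, 1L,
                                    fusion, pool, ms_cam_ratio, init)
  m$children$layer3 <- resnet_stage(512L, 256L, 1024L, 6L, 1L, 2L,
                                    fusion, pool, ms_cam_ratio, init)
  m$children$layer4 <- resnet_stage(1024L, 512L, 2048L, 3L, 1L, 4L,
                                    fusion, pool, ms_cam_ratio, init)
  m$forward <- function(x, training = FALSE) {
    d <- dim(x$v)
    if (d[2L] %% 8L != 0L || d[3L] %% 8L != 0L)
      stop("input spatial size must be divisible by the output stride (8)",
           call. = FALSE)
    h <- m$children$stem$forward(x, training)
    h <- m$children$layer1$forward(h, training)
    h <- m$children$layer2$forward(h, training)
    c3 <- m$children$layer3$forward(h, training)
    c4 <- m$children$layer4$forward(c3, training)
    list(main = c4, aux = c3)
  }
  m$audit <- function(shape) {
    macs <- 0
    for (nm in c("stem", "layer1", "layer2", "layer3", "layer4")) {
      a <- m$children[[nm]]$audit(shape)
      shape <- a$shape
      macs <- macs + a$macs
    }
    list(shape = shape, macs = macs)
  }
  m
}

#' Run the backbone on an image batch
#'
#' @param backbone module from [build_backbone()].
#' @param x numeric array `(3, H, W)` or `(3, H, W, N)`, spatial size
#'   divisible by 8.
#' @param training logical.
#' @return `list(main, aux)` of arrays `(2048, H/8, W/8[, N])` and
#'   `(1024, H/8, W/8[, N])`.
#' @export
extract_features <- function(backbone, x, training = FALSE) {
  out <- backbone$forward(ag_tensor(as_4d(x)), training)
  list(main = drop_batch(out$main$v), aux = drop_batch(out$aux$v))
}
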