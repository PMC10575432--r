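# Neural-network modules.
#
# A module is an environment with a `forward(x, training)` closure, a named
# list of parameter nodes in `params`, child modules in `children`, and an
# `audit(shape)` closure returning list(shape, macs) for analytic FLOP
# accounting (shape = c(C, H, W)).  Parameter enumeration walks the tree.

new_module <- function(type) {
  m <- new.env(parent = emptyenv())
  m$type <- type
  m$params <- list()
  m$children <- list()
  class(m) <- c(paste0("fs_", type), "fs_module")
  m
}

#' Enumerate the trainable parameters of a module
#' @param m a module (or model) built by this package.
#' @return named list of parameter nodes.
#' @keywords internal
module_parameters <- function(m) {
  out <- m$params
  for (nm in names(m$children)) {
    ch <- module_parameters(m$children[[nm]])
    if (length(ch)) names(ch) <- paste0(nm, ".", names(ch))
    out <- c(out, ch)
  }
  out
}

#' Count trainable parameters
#'
#' @param m a module or model.
#' @return integer scalar: the number of trainable scalar weights.
#' @export
count_params <- function(m) {
  sum(vapply(module_parameters(m), function(p) length(p$v), numeric(1)))
}

set_training_mode <- function(m, training) {
  m$training <- training
  for (ch in m$children) set_training_mode(ch, training)
  invisible(m)
}

fwd <- function(m, x, training = FALSE) m$forward(x, training)

# ---- sparse spatial operators ----------------------------------------------

# Bilinear interpolation matrix (align_corners = FALSE convention), rows are
# output pixels in (h fastest, then w) order to match the tensor layout.
bilinear_matrix <- function(h_in, w_in, h_out, w_out) {
  key <- paste("bil", h_in, w_in, h_out, w_out, sep = "_")
  cache <- .fs$op_cache
  if (!is.null(cache[[key]])) return(cache[[key]])
  axis <- function(n_in, n_out) {
    src <- (seq_len(n_out) - 0.5) * n_in / n_out - 0.5
    src <- pmin(pmax(src, 0), n_in - 1)
    i0 <- floor(src)
    frac <- src - i0
    i1 <- pmin(i0 + 1, n_in - 1)
    list(i0 = i0 + 1, i1 = i1 + 1, w1 = frac, w0 = 1 - frac)
  }
  ah <- axis(h_in, h_out)
  aw <- axis(w_in, w_out)
  rows <- integer(0); cols <- integer(0); vals <- numeric(0)
  oh <- rep(seq_len(h_out), times = w_out)
  ow <- rep(seq_len(w_out), each = h_out)
  row_id <- oh + h_out * (ow - 1)
  for (dh in 0:1) for (dw in 0:1) {
    hi <- if (dh == 0) ah$i0[oh] else ah$i1[oh]
    wi <- if (dw == 0) aw$i0[ow] else aw$i1[ow]
    wt <- (if (dh == 0) ah$w0[oh] else ah$w1[oh]) *
          (if (dw == 0) aw$w0[ow] else aw$w1[ow])
    rows <- c(rows, row_id)
    cols <- c(cols, hi + h_in * (wi - 1))
    vals <- c(vals, wt)
  }
  S <- Matrix::sparseMatrix(i = rows, j = cols, x = vals,
                            dims = c(h_out * w_out, h_in * w_in))
  cache[[key]] <- S
  S
}

# Adaptive average pooling matrix with the floor/ceil window convention.
adaptive_avg_matrix <- function(h_in, w_in, s_h, s_w = s_h) {
  key <- paste("adp", h_in, w_in, s_h, s_w, sep = "_")
  cache <- .fs$op_cache
  if (!is.null(cache[[key]])) return(cache[[key]])
  spans <- function(n_in, s) {
    lapply(seq_len(s), function(i) {
      a <- floor((i - 1) * n_in / s) + 1
      b <- ceiling(i * n_in / s)
      a:b
    })
  }
  sh <- spans(h_in, s_h)
  sw <- spans(w_in, s_w)
  rows <- integer(0); cols <- integer(0); vals <- numeric(0)
  for (j in seq_len(s_w)) for (i in seq_len(s_h)) {
    cells <- as.vector(outer(sh[[i]], (sw[[j]] - 1) * h_in, "+"))
    r <- i + s_h * (j - 1)
    rows <- c(rows, rep(r, length(cells)))
    cols <- c(cols, cells)
    vals <- c(vals, rep(1 / length(cells), length(cells)))
  }
  S <- Matrix::sparseMatrix(i = rows, j = cols, x = vals,
                            dims = c(s_h * s_w, h_in * w_in))
  cache[[key]] <- S
  S
}

# ---- elementary layers -----------------------------------------------------

conv_out_shape <- function(shape, k, stride, pad, dil, cout) {
  h <- (shape[2L] + 2L * pad[1L] - dil[1L] * (k[1L] - 1L) - 1L) %/% stride[1L] + 1L
  w <- (shape[3L] + 2L * pad[2L] - dil[2L] * (k[2L] - 1L) - 1L) %/% stride[2L] + 1L
  c(cout, h, w)
}

nn_conv2d <- function(cin, cout, k, stride = 1L, pad = 0L, dil = 1L,
                      bias = FALSE, init = "he") {
  m <- new_module("conv2d")
  k <- rep(as.integer(k), length.out = 2L)
  m$cin <- cin; m$cout <- cout; m$k <- k
  m$stride <- rep(as.integer(stride), length.out = 2L)
  m$pad <- rep(as.integer(pad), length.out = 2L)
  m$dil <- rep(as.integer(dil), length.out = 2L)
  n_w <- cin * prod(k) * cout
  w <- if (identical(init, "zero")) numeric(n_w) else
    stats::rnorm(n_w, sd = sqrt(2 / (cin * prod(k))))
  m$params$weight <- ag_param(array(w, c(cin, k[1L], k[2L], cout)))
  if (bias) m$params$bias <- ag_param(numeric(cout))
  m$forward <- function(x, training = FALSE) {
    ag_conv2d(x, m$params$weight, m$params$bias, m$stride, m$pad, m$dil)
  }
  m$audit <- function(shape) {
    os <- conv_out_shape(shape, m$k, m$stride, m$pad, m$dil, m$cout)
    macs <- prod(os[2:3]) * m$cout * m$cin * prod(m$k) +
      if (!is.null(m$params$bias)) prod(os) else 0
    list(shape = os, macs = macs)
  }
  m
}

nn_batchnorm <- function(C, eps = 1e-5, momentum = 0.1) {
  m <- new_module("batchnorm")
  m$C <- C
  m$eps <- eps
  m$momentum <- momentum
  m$running_mean <- numeric(C)
  m$running_var <- rep(1, C)
  m$params$gamma <- ag_param(rep(1, C))
  m$params$beta <- ag_param(numeric(C))
  m$forward <- function(x, training = FALSE) {
    ag_batchnorm(x, m$params$gamma, m$params$beta, m, training)
  }
  m$audit <- function(shape) list(shape = shape, macs = 0)  # excluded by convention
  m
}

nn_relu <- function() {
  m <- new_module("relu")
  m$forward <- function(x, training = FALSE) ag_relu(x)
  m$audit <- function(shape) list(shape = shape, macs = 0)
  m
}

nn_maxpool <- function(k = 3L, stride = 2L, pad = 1L) {
  m <- new_module("maxpool")
  m$k <- rep(as.integer(k), 2L)[1:2]
  m$stride <- rep(as.integer(stride), 2L)[1:2]
  m$pad <- rep(as.integer(pad), 2L)[1:2]
  m$forward <- function(x, training = FALSE) ag_maxpool(x, m$k, m$stride, m$pad)
  m$audit <- function(shape) {
    os <- conv_out_shape(shape, m$k, m$stride, m$pad, c(1L, 1L), shape[1L])
    list(shape = os, macs = prod(os) * prod(m$k))
  }
  m
}

# SoftPool layer: drop-in replacement for a 2x2 average-pool downsampler.
nn_softpool <- function(k = 2L, stride = k, pad = 0L) {
  m <- new_module("softpool")
  m$k <- rep(as.integer(k), 2L)[1:2]
  m$stride <- rep(as.integer(stride), 2L)[1:2]
  m$pad <- rep(as.integer(pad), 2L)[1:2]
  m$forward <- function(x, training = FALSE) ag_softpool(x, m$k, m$stride, m$pad)
  m$audit <- function(shape) {
    os <- conv_out_shape(shape, m$k, m$stride, m$pad, c(1L, 1L), shape[1L])
    # exp + multiply per window element
    list(shape = os, macs = 2 * prod(os) * prod(m$k))
  }
  m
}

nn_avgpool <- function(k = 2L, stride = k, pad = 0L) {
  m <- new_module("avgpool")
  m$k <- rep(as.integer(k), 2L)[1:2]
  m$stride <- rep(as.integer(stride), 2L)[1:2]
  m$pad <- rep(as.integer(pad), 2L)[1:2]
  m$forward <- function(x, training = FALSE) {
    d <- dim(x$v)
    # non-overlapping average pooling expressed as an adaptive pool
    stopifnot(all(m$k == m$stride), all(m$pad == 0L))
    S <- adaptive_avg_matrix(d[2L], d[3L], d[2L] %/% m$k[1L], d[3L] %/% m$k[2L])
    ag_spatial_linear(x, S, c(d[2L] %/% m$k[1L], d[3L] %/% m$k[2L]))
  }
  m$audit <- function(shape) {
    os <- conv_out_shape(shape, m$k, m$stride, m$pad, c(1L, 1L), shape[1L])
    list(shape = os, macs = prod(os) * prod(m$k))
  }
  m
}

nn_adaptive_avgpool <- function(s) {
  m <- new_module("adaptive_avgpool")
  m$s <- as.integer(s)
  m$forward <- function(x, training = FALSE) {
    d <- dim(x$v)
    ag_spatial_linear(x, adaptive_avg_matrix(d[2L], d[3L], m$s), c(m$s, m$s))
  }
  m$audit <- function(shape) {
    list(shape = c(shape[1L], m$s, m$s), macs = prod(shape))
  }
  m
}

# Adaptive SoftPool: used only when the pooling swap is extended into the
# pyramid module (off by default).  Requires the grid to divide the input.
nn_adaptive_softpool <- function(s) {
  m <- new_module("adaptive_softpool")
  m$s <- as.integer(s)
  m$forward <- function(x, training = FALSE) {
    d <- dim(x$v)
    if (d[2L] %% m$s != 0L || d[3L] %% m$s != 0L)
      stop("adaptive softpool needs the grid to divide the feature map",
           call. = FALSE)
    k <- c(d[2L] %/% m$s, d[3L] %/% m$s)
    ag_softpool(x, k, k, c(0L, 0L))
  }
  m$audit <- function(shape) {
    list(shape = c(shape[1L], m$s, m$s), macs = 2 * prod(shape))
  }
  m
}

nn_global_avgpool <- function() {
  m <- new_module("global_avgpool")
  m$forward <- function(x, training = FALSE) ag_global_avgpool(x)
  m$audit <- function(shape) list(shape = c(shape[1L], 1L, 1L), macs = prod(shape))
  m
}

# Bilinear upsampling to a fixed size or by an integer factor.
nn_upsample <- function(size = NULL, factor = NULL) {
  m <- new_module("upsample")
  m$size <- size
  m$factor <- factor
  m$out_hw <- function(shape) {
    if (!is.null(m$size)) rep(as.integer(m$size), length.out = 2L)
    else as.integer(shape[2:3] * m$factor)
  }
  m$forward <- function(x, training = FALSE) {
    d <- dim(x$v)
    o <- m$out_hw(d[1:3])
    if (all(o == d[2:3])) return(x)
    ag_spatial_linear(x, bilinear_matrix(d[2L], d[3L], o[1L], o[2L]), o)
  }
  m$audit <- function(shape) {
    o <- m$out_hw(shape)
    list(shape = c(shape[1L], o), macs = 4 * shape[1L] * prod(o))
  }
  m
}

nn_dropout <- function(p = 0.1) {
  m <- new_module("dropout")
  m$p <- p
  m$forward <- function(x, training = FALSE) ag_dropout(x, m$p, training)
  m$audit <- function(shape) list(shape = shape, macs = 0)
  m
}

nn_sequential <- function(...) {
  m <- new_module("sequential")
  mods <- list(...)
  if (is.null(names(mods)) || any(names(mods) == ""))
    names(mods) <- sprintf("m%02d", seq_along(mods))
  m$children <- mods
  m$forward <- function(x, training = FALSE) {
    for (ch in m$children) x <- ch$forward(x, training)
    x
  }
  m$audit <- function(shape) {
    macs <- 0
    for (ch in m$children) {
      a <- ch$audit(shape)
      shape <- a$shape
      macs <- macs + a$macs
    }
    list(shape = shape, macs = macs)
  }
  m
}

conv_bn_relu <- function(cin, cout, k, stride = 1L, pad = 0L, dil = 1L,
                         init = "he") {
  nn_sequential(conv = nn_conv2d(cin, cout, k, stride, pad, dil, init = init),
                bn = nn_batchnorm(cout),
                relu = nn_relu())
}
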