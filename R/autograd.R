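# Minimal reverse-mode autograd over dense R arrays.
#
# Tensors are environments holding a value `v` (an R array with dim
# (C, H, W, N)), an accumulated gradient `g`, a flag `req` (gradient needed)
# and, for op outputs, a backward closure `bw`.  A forward pass under
# `fs_record()` appends op nodes to a tape; `ag_backward()` walks it in
# reverse.  All heavy lifting (conv unfolding, pooling) lives in src/ and in
# BLAS through `%*%`; the R-level overhead is one closure per layer call.

.fs <- new.env(parent = emptyenv())
.fs$grad_enabled <- FALSE
.fs$tape <- NULL
.fs$op_cache <- new.env(parent = emptyenv())

ag_tensor <- function(value) {
  nd <- new.env(parent = emptyenv())
  nd$v <- value
  nd$g <- NULL
  nd$req <- FALSE
  nd$bw <- NULL
  class(nd) <- "fs_tensor"
  nd
}

ag_param <- function(value) {
  nd <- ag_tensor(value)
  nd$req <- TRUE
  nd
}

ag_needs_grad <- function(parents) {
  isTRUE(.fs$grad_enabled) &&
    any(vapply(parents, function(p) isTRUE(p$req), logical(1)))
}

ag_record <- function(value, parents, bw) {
  nd <- ag_tensor(value)
  if (ag_needs_grad(parents)) {
    nd$req <- TRUE
    nd$bw <- bw
    .fs$tape[[length(.fs$tape) + 1L]] <- nd
  }
  nd
}

ag_acc <- function(p, g) {
  if (isTRUE(p$req)) p$g <- if (is.null(p$g)) g else p$g + g
  invisible(NULL)
}

#' Run an expression while recording an autograd tape
#'
#' Used by the training loop; inference runs without recording so
#' intermediate activations can be collected by the garbage collector.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
fs_record <- function(expr) {
  old_flag <- .fs$grad_enabled
  old_tape <- .fs$tape
  .fs$grad_enabled <- TRUE
  .fs$tape <- list()
  on.exit({
    .fs$grad_enabled <- old_flag
    .fs$tape <- old_tape
  })
  expr
}

# Backpropagate from a scalar loss node through the current tape, then drop
# the tape.  Parameter gradients accumulate in each parameter node's `g`.
ag_backward <- function(loss) {
  stopifnot(length(loss$v) == 1L)
  loss_val <- loss$v
  loss$g <- 1
  tape <- .fs$tape
  for (k in rev(seq_along(tape))) {
    nd <- tape[[k]]
    if (!is.null(nd$g) && !is.null(nd$bw)) nd$bw(nd$g)
    # once a node's backward has run, neither its value nor its gradient can
    # be needed again (all consumers ran earlier in the reverse sweep): free
    # both so peak memory is the forward tape plus a small frontier
    nd$g <- NULL
    nd$v <- NULL
    nd$bw <- NULL
    tape[[k]] <- NULL
  }
  loss$v <- loss_val
  .fs$tape <- list()
  invisible(NULL)
}

as_4d <- function(x) {
  d <- dim(x)
  if (is.null(d)) stop("input must be an array", call. = FALSE)
  if (length(d) == 3L) dim(x) <- c(d, 1L)
  else if (length(d) != 4L) stop("input must be a 3D or 4D array", call. = FALSE)
  x
}

drop_batch <- function(x) {
  d <- dim(x)
  if (length(d) == 4L && d[4L] == 1L) dim(x) <- d[1:3]
  x
}

# ---- elementwise ops -------------------------------------------------------

ag_add <- function(x, y) {
  ag_record(x$v + y$v, list(x, y), function(g) {
    ag_acc(x, g); ag_acc(y, g)
  })
}

ag_mul <- function(x, y) {
  xv <- x$v; yv <- y$v
  ag_record(xv * yv, list(x, y), function(g) {
    ag_acc(x, g * yv); ag_acc(y, g * xv)
  })
}

ag_one_minus <- function(x) {
  ag_record(1 - x$v, list(x), function(g) ag_acc(x, -g))
}

ag_scale <- function(x, a) {
  ag_record(a * x$v, list(x), function(g) ag_acc(x, a * g))
}

ag_relu <- function(x) {
  out <- x$v
  out[out < 0] <- 0
  # mask recomputed in the backward pass to keep the tape lean
  ag_record(out, list(x), function(g) ag_acc(x, g * (x$v > 0)))
}

# Fused convex combination m*x + (1-m)*y in one tape node.
ag_fuse_convex <- function(x, y, m) {
  mv <- m$v
  out <- mv * x$v + (1 - mv) * y$v
  ag_record(out, list(x, y, m), function(g) {
    ag_acc(x, g * m$v)
    ag_acc(y, g * (1 - m$v))
    if (isTRUE(m$req)) ag_acc(m, g * (x$v - y$v))
  })
}

ag_sigmoid <- function(x) {
  s <- 1 / (1 + exp(-x$v))
  ag_record(s, list(x), function(g) ag_acc(x, g * s * (1 - s)))
}

# ---- convolution -----------------------------------------------------------

# x: (Cin,H,W,N); w: (Cin,kh,kw,Cout); bias: length Cout or NULL.
ag_conv2d <- function(x, w, bias = NULL, stride = c(1L, 1L), pad = c(0L, 0L),
                      dilation = c(1L, 1L)) {
  xv <- x$v
  d <- dim(xv)
  wd <- dim(w$v)
  if (d[1L] != wd[1L])
    stop("conv2d: input has ", d[1L], " channels, weight expects ", wd[1L],
         call. = FALSE)
  kh <- wd[2L]; kw <- wd[3L]; cout <- wd[4L]
  one_by_one <- kh == 1L && kw == 1L && all(stride == 1L) && all(pad == 0L)
  if (one_by_one) {
    col <- xv
    dim(col) <- c(d[1L], prod(d[-1L]))
    hout <- d[2L]; wout <- d[3L]
  } else {
    col <- cpp_im2col(xv, d, kh, kw, stride[1L], stride[2L],
                      pad[1L], pad[2L], dilation[1L], dilation[2L])
    hout <- (d[2L] + 2L * pad[1L] - dilation[1L] * (kh - 1L) - 1L) %/% stride[1L] + 1L
    wout <- (d[3L] + 2L * pad[2L] - dilation[2L] * (kw - 1L) - 1L) %/% stride[2L] + 1L
  }
  wm <- w$v
  dim(wm) <- c(prod(wd[1:3]), cout)
  out <- crossprod(wm, col)
  if (!is.null(bias)) out <- out + bias$v
  dim(out) <- c(cout, hout, wout, d[4L])
  parents <- if (is.null(bias)) list(x, w) else list(x, w, bias)
  if (!ag_needs_grad(parents)) return(ag_tensor(out))
  # the unfolded input and the reshaped weight are large; recompute both in
  # the backward pass instead of keeping them alive on the tape
  rm(col, wm)
  ag_record(out, parents, function(g) {
    gm <- g
    dim(gm) <- c(cout, length(g) %/% cout)
    if (!is.null(bias) && isTRUE(bias$req)) ag_acc(bias, rowSums(gm))
    if (isTRUE(w$req)) {
      col <- if (one_by_one) {
        cb <- x$v
        dim(cb) <- c(d[1L], prod(d[-1L]))
        cb
      } else {
        cpp_im2col(x$v, d, kh, kw, stride[1L], stride[2L],
                   pad[1L], pad[2L], dilation[1L], dilation[2L])
      }
      dw <- tcrossprod(col, gm)
      dim(dw) <- wd
      ag_acc(w, dw)
      rm(col)
    }
    if (isTRUE(x$req)) {
      wm <- w$v
      dim(wm) <- c(prod(wd[1:3]), cout)
      dcol <- wm %*% gm
      if (one_by_one) {
        dim(dcol) <- d
        ag_acc(x, dcol)
      } else {
        ag_acc(x, cpp_col2im(dcol, d, kh, kw, stride[1L], stride[2L],
                             pad[1L], pad[2L], dilation[1L], dilation[2L]))
      }
    }
  })
}

# ---- batch normalisation ---------------------------------------------------

# Normalises per channel over (H, W, N).  `st` is the layer environment
# carrying running statistics; in eval mode those are used instead.
ag_batchnorm <- function(x, gamma, beta, st, training) {
  xv <- x$v
  d <- dim(xv)
  C <- d[1L]
  m <- xv
  dim(m) <- c(C, prod(d[-1L]))
  M <- ncol(m)
  eps <- st$eps
  if (training) {
    mu <- rowMeans(m)
    va <- rowMeans(m * m) - mu * mu
    va[va < 0] <- 0
    unbias <- if (M > 1L) M / (M - 1L) else 1
    st$running_mean <- (1 - st$momentum) * st$running_mean + st$momentum * mu
    st$running_var <- (1 - st$momentum) * st$running_var + st$momentum * va * unbias
  } else {
    mu <- st$running_mean
    va <- st$running_var
  }
  inv_sd <- 1 / sqrt(va + eps)
  xhat <- (m - mu) * inv_sd
  out <- gamma$v * xhat + beta$v
  dim(out) <- d
  parents <- list(x, gamma, beta)
  if (!ag_needs_grad(parents)) return(ag_tensor(out))
  rm(m, xhat)  # recomputed from the parent value in the backward pass
  ag_record(out, parents, function(g) {
    gm <- g
    dim(gm) <- c(C, M)
    xhat <- x$v
    dim(xhat) <- c(C, M)
    xhat <- (xhat - mu) * inv_sd
    dgamma <- rowSums(gm * xhat)
    dbeta <- rowSums(gm)
    ag_acc(gamma, dgamma)
    ag_acc(beta, dbeta)
    if (isTRUE(x$req)) {
      if (training) {
        dx <- (gamma$v * inv_sd) * (gm - dbeta / M - xhat * (dgamma / M))
      } else {
        dx <- (gamma$v * inv_sd) * gm
      }
      dim(dx) <- d
      ag_acc(x, dx)
    }
  })
}

# ---- pooling ---------------------------------------------------------------

ag_maxpool <- function(x, kernel = c(3L, 3L), stride = c(2L, 2L),
                       pad = c(1L, 1L)) {
  d <- dim(x$v)
  r <- cpp_maxpool(x$v, d, kernel[1L], kernel[2L], stride[1L], stride[2L],
                   pad[1L], pad[2L])
  ag_record(r$out, list(x), function(g) {
    ag_acc(x, {
      dx <- cpp_maxpool_backward(g, r$argmax, length(x$v))
      dim(dx) <- d
      dx
    })
  })
}

ag_softpool <- function(x, kernel = c(2L, 2L), stride = kernel,
                        pad = c(0L, 0L)) {
  xv <- x$v
  if (!all(is.finite(xv)))
    stop("softpool: non-finite values in input", call. = FALSE)
  d <- dim(xv)
  out <- cpp_softpool(xv, d, kernel[1L], kernel[2L], stride[1L], stride[2L],
                      pad[1L], pad[2L])
  ag_record(out, list(x), function(g) {
    ag_acc(x, cpp_softpool_backward(xv, g, d, kernel[1L], kernel[2L],
                                    stride[1L], stride[2L], pad[1L], pad[2L]))
  })
}

ag_global_avgpool <- function(x) {
  d <- dim(x$v)
  C <- d[1L]; hw <- d[2L] * d[3L]; N <- d[4L]
  a <- x$v
  dim(a) <- c(C, hw, N)
  out <- apply(a, c(1L, 3L), mean)
  dim(out) <- c(C, 1L, 1L, N)
  ag_record(out, list(x), function(g) {
    gexp <- g[, rep(1L, d[2L]), rep(1L, d[3L]), , drop = FALSE] / hw
    ag_acc(x, gexp)
  })
}

# Apply a fixed sparse spatial operator S (out_pixels x in_pixels) per sample
# and channel.  Used for adaptive average pooling and bilinear interpolation,
# which are both linear maps, so the backward pass is the transpose.
ag_spatial_linear <- function(x, S, out_hw) {
  d <- dim(x$v)
  C <- d[1L]; hw <- d[2L] * d[3L]; N <- d[4L]
  tS <- Matrix::t(S)
  out <- array(0, c(C, out_hw[1L], out_hw[2L], N))
  m <- x$v
  dim(m) <- c(C, hw, N)
  for (n in seq_len(N)) {
    out[, , , n] <- as.matrix(m[, , n] %*% tS)
  }
  rm(m)
  ag_record(out, list(x), function(g) {
    dg <- g
    dim(dg) <- c(C, out_hw[1L] * out_hw[2L], N)
    dx <- array(0, d)
    for (n in seq_len(N)) {
      dx[, , , n] <- as.matrix(dg[, , n] %*% S)
    }
    ag_acc(x, dx)
  })
}

# ---- broadcasting helpers --------------------------------------------------

# x: (C,H,W,N) + b: (C,1,1,N)
ag_broadcast_add <- function(x, b) {
  d <- dim(x$v)
  bexp <- b$v[, rep(1L, d[2L]), rep(1L, d[3L]), , drop = FALSE]
  out <- x$v + bexp
  rm(bexp)
  ag_record(out, list(x, b), function(g) {
    ag_acc(x, g)
    if (isTRUE(b$req)) {
      s <- g
      dim(s) <- c(d[1L], d[2L] * d[3L], d[4L])
      db <- apply(s, c(1L, 3L), sum)
      dim(db) <- c(d[1L], 1L, 1L, d[4L])
      ag_acc(b, db)
    }
  })
}

# x: (D,H,W,N) * gate: (1,H,W,N), broadcast over the leading dim.
ag_gate_mul <- function(x, gate) {
  d <- dim(x$v)
  gexp <- gate$v[rep(1L, d[1L]), , , , drop = FALSE]
  out <- x$v * gexp
  rm(gexp)
  ag_record(out, list(x, gate), function(g) {
    ag_acc(x, g * gate$v[rep(1L, d[1L]), , , , drop = FALSE])
    if (isTRUE(gate$req)) {
      s <- g * x$v
      dim(s) <- c(d[1L], d[2L] * d[3L] * d[4L])
      dg <- colSums(s)
      dim(dg) <- c(1L, d[2L], d[3L], d[4L])
      ag_acc(gate, dg)
    }
  })
}

# Permute the first three (C,H,W) axes; the batch axis stays last.
ag_permute <- function(x, perm) {
  full <- c(perm, 4L)
  inv <- c(order(perm), 4L)
  ag_record(aperm(x$v, full), list(x), function(g) {
    ag_acc(x, aperm(g, inv))
  })
}

# Z-pool: stack max and mean over the leading dimension -> (2,H,W,N).
ag_zpool <- function(x) {
  d <- dim(x$v)
  D <- d[1L]
  if (D < 1L) stop("z_pool: empty leading dimension", call. = FALSE)
  m <- x$v
  rest <- prod(d[-1L])
  dim(m) <- c(D, rest)
  amax <- max.col(t(m), ties.method = "first")
  cols <- seq_len(rest)
  vmax <- m[cbind(amax, cols)]
  vmean <- colMeans(m)
  out <- rbind(vmax, vmean)
  dim(out) <- c(2L, d[2L], d[3L], d[4L])
  rm(m, vmax, vmean)
  ag_record(out, list(x), function(g) {
    gm <- g
    dim(gm) <- c(2L, rest)
    dx <- matrix(rep(gm[2L, ] / D, each = D), D, rest)
    dx[cbind(amax, cols)] <- dx[cbind(amax, cols)] + gm[1L, ]
    dim(dx) <- d
    ag_acc(x, dx)
  })
}

ag_concat_channels <- function(xs) {
  dims <- lapply(xs, function(x) dim(x$v))
  cs <- vapply(dims, `[`, integer(1), 1L)
  d1 <- dims[[1L]]
  out <- array(0, c(sum(cs), d1[2L], d1[3L], d1[4L]))
  off <- 0L
  for (x in xs) {
    ci <- dim(x$v)[1L]
    out[off + seq_len(ci), , , ] <- x$v
    off <- off + ci
  }
  offs <- cumsum(c(0L, cs))
  ag_record(out, xs, function(g) {
    for (k in seq_along(xs)) {
      ag_acc(xs[[k]], g[offs[k] + seq_len(cs[k]), , , , drop = FALSE])
    }
  })
}

ag_mean_list <- function(xs) {
  k <- length(xs)
  v <- xs[[1L]]$v
  if (k > 1L) for (i in 2L:k) v <- v + xs[[i]]$v
  v <- v / k
  ag_record(v, xs, function(g) {
    gk <- g / k
    for (x in xs) ag_acc(x, gk)
  })
}

ag_dropout <- function(x, p, training) {
  if (!training || p <= 0) return(x)
  mask <- (array(stats::runif(length(x$v)), dim(x$v)) >= p) / (1 - p)
  ag_record(x$v * mask, list(x), function(g) ag_acc(x, g * mask))
}

# Pixelwise cross-entropy from logits (K,H,W,N) against integer labels
# (H,W,N) in 0..K-1.  Returns a scalar node (mean over pixels).
ag_cross_entropy <- function(logits, target) {
  d <- dim(logits$v)
  K <- d[1L]
  npix <- prod(d[-1L])
  m <- logits$v
  dim(m) <- c(K, npix)
  mx <- apply(m, 2L, max)
  em <- exp(sweep(m, 2L, mx))
  den <- colSums(em)
  tgt <- as.integer(target) + 1L
  idx <- cbind(tgt, seq_len(npix))
  loss <- mean(log(den) + mx - m[idx])
  rm(m)
  ag_record(loss, list(logits), function(g) {
    sm <- sweep(em, 2L, den, "/")
    sm[idx] <- sm[idx] - 1
    dx <- g * sm / npix
    dim(dx) <- d
    ag_acc(logits, dx)
  })
}
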