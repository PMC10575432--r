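# Shared test utilities: independent oracles kept deliberately naive.

# 4-connected component count of a binary matrix (flood fill).
count_components <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  seen <- matrix(FALSE, h, w)
  n <- 0L
  for (j in seq_len(w)) for (i in seq_len(h)) {
    if (mask[i, j] == 1L && !seen[i, j]) {
      n <- n + 1L
      queue <- list(c(i, j))
      seen[i, j] <- TRUE
      while (length(queue)) {
        p <- queue[[1L]]; queue <- queue[-1L]
        for (d in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))) {
          q <- p + d
          if (q[1L] >= 1 && q[1L] <= h && q[2L] >= 1 && q[2L] <= w &&
              mask[q[1L], q[2L]] == 1L && !seen[q[1L], q[2L]]) {
            seen[q[1L], q[2L]] <- TRUE
            queue[[length(queue) + 1L]] <- q
          }
        }
      }
    }
  }
  n
}

# scalar min/max pooling oracles with the same window/padding semantics as
# softpool (padded positions excluded)
pool_reference <- function(x, kernel, stride = kernel, padding = 0L,
                           fun = max) {
  kernel <- rep(as.integer(kernel), length.out = 2L)
  stride <- rep(as.integer(stride), length.out = 2L)
  padding <- rep(as.integer(padding), length.out = 2L)
  d <- dim(x)
  ho <- (d[2L] + 2L * padding[1L] - kernel[1L]) %/% stride[1L] + 1L
  wo <- (d[3L] + 2L * padding[2L] - kernel[2L]) %/% stride[2L] + 1L
  out <- array(0, c(d[1L], ho, wo))
  for (cc in seq_len(d[1L])) for (ow in seq_len(wo)) for (oh in seq_len(ho)) {
    hs <- (oh - 1L) * stride[1L] - padding[1L] + seq_len(kernel[1L])
    ws <- (ow - 1L) * stride[2L] - padding[2L] + seq_len(kernel[2L])
    hs <- hs[hs >= 1L & hs <= d[2L]]
    ws <- ws[ws >= 1L & ws <= d[3L]]
    out[cc, oh, ow] <- fun(x[cc, hs, ws])
  }
  out
}

# naive scalar 2D convolution for small oracles: x (C,H,W), w (C,kh,kw,Cout)
conv_reference <- function(x, w, pad = 0L) {
  d <- dim(x); wd <- dim(w)
  ho <- d[2L] + 2L * pad - wd[2L] + 1L
  wo <- d[3L] + 2L * pad - wd[3L] + 1L
  out <- array(0, c(wd[4L], ho, wo))
  for (co in seq_len(wd[4L])) for (oh in seq_len(ho)) for (ow in seq_len(wo)) {
    acc <- 0
    for (ci in seq_len(wd[1L])) for (i in seq_len(wd[2L])) for (j in seq_len(wd[3L])) {
      hi <- oh - pad + i - 1L; wi <- ow - pad + j - 1L
      if (hi >= 1L && hi <= d[2L] && wi >= 1L && wi <= d[3L])
        acc <- acc + x[ci, hi, wi] * w[ci, i, j, co]
    }
    out[co, oh, ow] <- acc
  }
  out
}

random_map <- function(C, H, W, sd = 1) array(stats::rnorm(C * H * W, sd = sd),
                                              c(C, H, W))

# naive scalar implementation of the three-branch module, following the
# defining equation term by term with explicit loops; batch-norm evaluated in
# running-statistics mode (mean 0, var 1 at initialisation)
naive_ta <- function(x, mod, branches = mod$branches) {
  eps <- 1e-5
  gate_branch <- function(xb, b) {
    d <- dim(xb)
    z <- array(0, c(2, d[2], d[3]))
    for (h in seq_len(d[2])) for (w in seq_len(d[3])) {
      z[1, h, w] <- max(xb[, h, w])
      z[2, h, w] <- mean(xb[, h, w])
    }
    wgt <- mod$children[[paste0("conv_", b)]]$params$weight$v
    a <- conv_reference(z, wgt, pad = mod$pad)
    bnm <- mod$children[[paste0("bn_", b)]]
    a <- bnm$params$gamma$v * (a - bnm$running_mean) /
      sqrt(bnm$running_var + eps) + bnm$params$beta$v
    gate <- 1 / (1 + exp(-a))
    out <- xb
    for (k in seq_len(d[1])) out[k, , ] <- xb[k, , ] * gate[1, , ]
    out
  }
  perms <- list(height = c(2, 1, 3), width = c(3, 2, 1), spatial = c(1, 2, 3))
  acc <- array(0, dim(x))
  for (b in branches) {
    p <- perms[[b]]
    xb <- aperm(x, p)
    acc <- acc + aperm(gate_branch(xb, b), order(p))
  }
  acc / length(branches)
}
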