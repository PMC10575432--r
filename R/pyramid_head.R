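# Pyramid pooling module, classifier head, and full-model assembly of the
# four ablation variants (baseline PSPNet, I-, IS-, IST-PSPNet).
#
# PPM: the 2048-channel backbone feature is adaptively pooled to 1x1, 2x2,
# 3x3 and 6x6 grids; each grid passes a 1x1 conv to 512 channels (+BN+ReLU),
# optionally triplet attention (one shared module across all scales), and is
# bilinearly upsampled back to the feature size; the four branches are
# concatenated with the input feature (2048 + 4*512 = 4096 channels).
# Head: 3x3 conv to 512, BN, ReLU, dropout, 1x1 conv to n_classes, then 8x
# bilinear upsampling to the input size.  An auxiliary classifier on the
# stage-3 feature (weight 0.4) is used during training only and excluded
# from audits.

PPM_POOL_SIZES <- c(1L, 2L, 3L, 6L)

ppm_module <- function(in_channels = 2048L, branch_channels = 512L,
                       pool_sizes = PPM_POOL_SIZES, ta = NULL,
                       ppm_pool = c("avg", "soft"), init = "he") {
  ppm_pool <- match.arg(ppm_pool)
  m <- new_module("ppm")
  m$in_channels <- in_channels
  m$branch_channels <- branch_channels
  m$pool_sizes <- pool_sizes
  m$out_channels <- in_channels + length(pool_sizes) * branch_channels
  for (s in pool_sizes) {
    m$children[[paste0("pool", s)]] <-
      if (ppm_pool == "soft") nn_adaptive_softpool(s) else nn_adaptive_avgpool(s)
    m$children[[paste0("reduce", s)]] <-
      conv_bn_relu(in_channels, branch_channels, 1L, init = init)
  }
  if (!is.null(ta)) m$children$ta <- ta
  m$forward <- function(x, training = FALSE) {
    d <- dim(x$v)
    if (d[2L] < max(m$pool_sizes) || d[3L] < max(m$pool_sizes))
      stop("feature map smaller than the largest pool size", call. = FALSE)
    branches <- lapply(m$pool_sizes, function(s) {
      b <- m$children[[paste0("pool", s)]]$forward(x, training)
      b <- m$children[[paste0("reduce", s)]]$forward(b, training)
      if (!is.null(m$children$ta)) b <- m$children$ta$forward(b, training)
      up <- nn_upsample(size = d[2:3])
      up$forward(b, training)
    })
    ag_concat_channels(c(list(x), branches))
  }
  m$audit <- function(shape) {
    macs <- 0
    for (s in m$pool_sizes) {
      a <- m$children[[paste0("pool", s)]]$audit(shape)
      b <- m$children[[paste0("reduce", s)]]$audit(a$shape)
      macs <- macs + a$macs + b$macs
      if (!is.null(m$children$ta)) macs <- macs + m$children$ta$audit(b$shape)$macs
      macs <- macs + nn_upsample(size = shape[2:3])$audit(b$shape)$macs
    }
    list(shape = c(m$out_channels, shape[2:3]), macs = macs)
  }
  m
}

#' Table of model variants and their toggles
#'
#' @return data.frame with one row per variant and its iAFF/SoftPool/TA
#'   toggles.
#' @export
model_variants <- function() {
  data.frame(
    variant = c("PSPNet", "I-PSPNet", "IS-PSPNet", "IST-PSPNet"),
    iaff = c(FALSE, TRUE, TRUE, TRUE),
    softpool = c(FALSE, FALSE, TRUE, TRUE),
    ta = c(FALSE, FALSE, FALSE, TRUE),
    stringsAsFactors = FALSE
  )
}

variant_toggles <- function(variant) {
  tab <- model_variants()
  row <- tab[tab$variant == variant, ]
  if (nrow(row) != 1L)
    stop("unknown variant '", variant, "'; one of: ",
         paste(tab$variant, collapse = ", "), call. = FALSE)
  list(fusion = if (row$iaff) "iaff" else "add",
       pool = if (row$softpool) "soft" else "avg",
       ta = row$ta)
}

classifier_head <- function(in_channels, n_classes, init) {
  nn_sequential(
    conv1 = nn_conv2d(in_channels, 512L, 3L, pad = 1L, init = init),
    bn = nn_batchnorm(512L),
    relu = nn_relu(),
    drop = nn_dropout(0.1),
    conv2 = nn_conv2d(512L, n_classes, 1L, bias = TRUE, init = init)
  )
}

#' Assemble a segmentation model variant
#'
#' @param variant one of `"PSPNet"`, `"I-PSPNet"`, `"IS-PSPNet"`,
#'   `"IST-PSPNet"` (toggle sets per [model_variants()]).
#' @param n_classes number of output classes (2: background, fish).
#' @param ms_cam_ratio MS-CAM bottleneck reduction ratio.
#' @param ta_branches TA branch subset (for ablations).
#' @param ta_shared share one TA parameter set across all pyramid scales.
#' @param aux include the training-only auxiliary classifier head.
#' @param ppm_pool pooling type inside the pyramid module (`"avg"` canonical;
#'   `"soft"` extends the SoftPool swap into the head — off by default).
#' @param init `"he"` or `"zero"` initialisation.
#' @return a model module; `forward` maps `(3, H, W, N)` to logits
#'   `(n_classes, H, W, N)`.
#' @export
build_model <- function(variant = "IST-PSPNet", n_classes = 2L,
                        ms_cam_ratio = 25L, ta_branches = TA_BRANCHES,
                        ta_shared = TRUE, aux = TRUE,
                        ppm_pool = "avg", init = "he") {
  tg <- variant_toggles(variant)
  m <- new_module("psp_model")
  m$variant <- variant
  m$n_classes <- as.integer(n_classes)
  m$toggles <- tg
  m$children$backbone <- build_backbone(tg$fusion, tg$pool,
                                        ms_cam_ratio = ms_cam_ratio, init = init)
  ta <- NULL
  if (tg$ta) {
    if (!ta_shared) {
      # independent TA per scale: wrap four modules in a dispatcher
      ta <- new_module("ta_per_scale")
      for (s in PPM_POOL_SIZES)
        ta$children[[paste0("ta", s)]] <- ta_module(7L, ta_branches, init)
      ta$idx <- 0L
      ta$forward <- function(x, training = FALSE) {
        ta$idx <- ta$idx %% length(PPM_POOL_SIZES) + 1L
        ta$children[[ta$idx]]$forward(x, training)
      }
      ta$audit <- function(shape) ta$children[[1L]]$audit(shape)
    } else {
      ta <- ta_module(7L, ta_branches, init)
    }
  }
  m$children$ppm <- ppm_module(2048L, 512L, PPM_POOL_SIZES, ta = ta,
                               ppm_pool = ppm_pool, init = init)
  m$children$head <- classifier_head(m$children$ppm$out_channels, n_classes, init)
  if (aux) m$children$aux_head <- nn_sequential(
    conv1 = nn_conv2d(1024L, 256L, 3L, pad = 1L, init = init),
    bn = nn_batchnorm(256L),
    relu = nn_relu(),
    drop = nn_dropout(0.1),
    conv2 = nn_conv2d(256L, n_classes, 1L, bias = TRUE, init = init)
  )
  m$forward <- function(x, training = FALSE, with_aux = FALSE) {
    d <- dim(x$v)
    feats <- m$children$backbone$forward(x, training)
    h <- m$children$ppm$forward(feats$main, training)
    h <- m$children$head$forward(h, training)
    up <- nn_upsample(size = d[2:3])
    logits <- up$forward(h, training)
    if (with_aux && !is.null(m$children$aux_head)) {
      a <- m$children$aux_head$forward(feats$aux, training)
      list(main = logits, aux = up$forward(a, training))
    } else {
      logits
    }
  }
  m$audit <- function(shape) {
    a <- m$children$backbone$audit(shape)
    b <- m$children$ppm$audit(a$shape)
    h <- m$children$head$audit(b$shape)
    up <- nn_upsample(size = shape[2:3])$audit(h$shape)
    list(shape = c(h$shape[1L], shape[2:3]),
         macs = a$macs + b$macs + h$macs + up$macs)
  }
  m
}

#' Forward pass of a segmentation model
#'
#' @param model from [build_model()].
#' @param x image array `(3, H, W)` or `(3, H, W, N)`, values on any scale
#'   (training and inference must use the same normalisation).
#' @param training logical.
#' @return logits `(n_classes, H, W[, N])`.
#' @export
model_forward <- function(model, x, training = FALSE) {
  drop_batch(model$forward(ag_tensor(as_4d(x)), training)$v)
}

# Parameter count of the model as audited: the auxiliary head is a pure
# training aid and excluded, matching the FLOP audit which never runs it.
audited_parameters <- function(model) {
  ps <- module_parameters(model)
  keep <- !grepl("^aux_head\\.", names(ps))
  sum(vapply(ps[keep], function(p) length(p$v), numeric(1)))
}
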