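# Training: Adam + per-epoch cosine learning-rate decay, pixelwise
# cross-entropy with an auxiliary loss (weight 0.4) on the stage-3 feature.
# Fully deterministic on CPU for a fixed (seed, config).

#' Training configuration
#'
#' Defaults follow the reference protocol (batch 4, initial learning rate
#' 5e-4, Adam with first-moment coefficient 0.9, cosine decay) at fixture
#' scale: 96 x 96 inputs instead of 480 x 480, identical code path.
#' @param epochs number of epochs.
#' @param batch_size samples per step.
#' @param lr0 initial learning rate.
#' @param beta1 Adam first-moment coefficient (the protocol's "momentum 0.9"
#'   read as Adam's beta1 — Adam has no classical momentum knob).
#' @param beta2,eps remaining Adam constants.
#' @param image_size square input side length (divisible by 8).
#' @param aux_weight auxiliary-loss weight.
#' @param seed integer seed controlling shuffling, dropout and initialisation
#'   order during the run.
#' @return a `fishseg_train_config` list.
#' @export
train_config <- function(epochs = 100L, batch_size = 4L, lr0 = 5e-4,
                         beta1 = 0.9, beta2 = 0.999, eps = 1e-8,
                         image_size = 480L, aux_weight = 0.4, seed = 1L) {
  structure(list(epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 lr0 = lr0, beta1 = beta1, beta2 = beta2, eps = eps,
                 image_size = as.integer(image_size), aux_weight = aux_weight,
                 seed = as.integer(seed)),
            class = "fishseg_train_config")
}

#' Cosine-annealed learning rate
#'
#' `lr0 * (1 + cos(pi * epoch / epochs)) / 2`, stepped per epoch: `lr(0) =
#' lr0`, monotone non-increasing, `lr(epochs/2) = lr0 / 2`.
#' @param epoch 0-based epoch index, `0 <= epoch < epochs`.
#' @param config a [train_config()].
#' @return the learning rate for that epoch.
#' @export
lr_schedule <- function(epoch, config) {
  if (epoch < 0 || epoch >= config$epochs)
    stop("epoch out of range [0, ", config$epochs, ")", call. = FALSE)
  config$lr0 * 0.5 * (1 + cos(pi * epoch / config$epochs))
}

# Adam moments live inside each parameter node (fields om/ov) and are
# updated in place by the compiled kernel; they materialise lazily on the
# first step a parameter receives a gradient.
adam_step <- function(params, lr, cfg, t) {
  corr1 <- 1 - cfg$beta1^t
  corr2 <- 1 - cfg$beta2^t
  for (p in params) {
    if (is.null(p$g)) next
    if (is.null(p$om)) {
      p$om <- numeric(length(p$v))
      p$ov <- numeric(length(p$v))
    }
    p$v <- cpp_adam_update(p$v, p$g, p$om, p$ov, lr, cfg$beta1, cfg$beta2,
                           cfg$eps, corr1, corr2)
    p$g <- NULL
  }
  invisible(NULL)
}

# batch of records (already preprocessed to a common square size) ->
# list(x = (3,S,S,N) tensor input, y = (S,S,N) integer labels)
assemble_batch <- function(records) {
  n <- length(records)
  s <- dim(records[[1L]]$image)[1L]
  x <- array(0, c(3L, s, s, n))
  y <- array(0L, c(s, s, n))
  for (i in seq_len(n)) {
    x[, , , i] <- image_to_tensor(records[[i]]$image)
    y[, , i] <- records[[i]]$mask
  }
  list(x = x, y = y)
}

model_state <- function(model) {
  ps <- module_parameters(model)
  bn <- list()
  walk <- function(m, prefix) {
    if (inherits(m, "fs_batchnorm")) {
      bn[[prefix]] <<- list(mean = m$running_mean, var = m$running_var)
    }
    for (nm in names(m$children)) walk(m$children[[nm]], paste0(prefix, ".", nm))
  }
  walk(model, "root")
  list(params = lapply(ps, function(p) p$v), bn = bn)
}

restore_state <- function(model, state) {
  ps <- module_parameters(model)
  stopifnot(identical(names(ps), names(state$params)))
  for (k in seq_along(ps)) ps[[k]]$v <- state$params[[k]]
  walk <- function(m, prefix) {
    if (inherits(m, "fs_batchnorm") && !is.null(state$bn[[prefix]])) {
      m$running_mean <- state$bn[[prefix]]$mean
      m$running_var <- state$bn[[prefix]]$var
    }
    for (nm in names(m$children)) walk(m$children[[nm]], paste0(prefix, ".", nm))
  }
  walk(model, "root")
  invisible(model)
}

#' Save / load a model checkpoint
#' @param model model from [build_model()].
#' @param path file path (RDS).
#' @return `save_checkpoint` returns the path invisibly; `load_checkpoint`
#'   returns a rebuilt model.
#' @export
save_checkpoint <- function(model, path) {
  saveRDS(list(variant = model$variant, n_classes = model$n_classes,
               has_aux = !is.null(model$children$aux_head),
               state = model_state(model)), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  model <- build_model(ck$variant, n_classes = ck$n_classes, aux = ck$has_aux,
                       init = "zero")
  restore_state(model, ck$state)
  model
}

#' Train a segmentation model on a record dataset
#'
#' Runs Adam with a cosine schedule, logs per-epoch mean training loss (and
#' validation Miou/MPA when a validation set is given) and keeps the
#' best-Miou state. Everything is seeded: identical (seed, config, data) give
#' identical trajectories on CPU.
#'
#' @param model from [build_model()].
#' @param train_records,val_records lists of samples already letterboxed to
#'   `config$image_size` (see [preprocess()]).
#' @param config a [train_config()].
#' @param history_path optional CSV path for the epoch log.
#' @param verbose print per-epoch progress.
#' @return `list(history, best_miou, final_loss, model)`; the model carries
#'   the final-epoch weights, `best_state` the best-validation weights.
#' @export
train_model <- function(model, train_records, val_records = NULL,
                        config = train_config(), history_path = NULL,
                        verbose = FALSE) {
  if (length(train_records) == 0L) stop("empty training dataset", call. = FALSE)
  params <- module_parameters(model)
  best <- list(miou = -Inf, state = NULL)
  history <- data.frame()
  t_global <- 0L
  with_seed(config$seed, {
    for (epoch in seq_len(config$epochs) - 1L) {
      lr <- lr_schedule(epoch, config)
      idx <- sample.int(length(train_records))
      losses <- c()
      for (start in seq(1L, length(idx), by = config$batch_size)) {
        take <- idx[start:min(start + config$batch_size - 1L, length(idx))]
        batch <- assemble_batch(train_records[take])
        loss_val <- fs_record({
          x <- ag_tensor(batch$x)
          out <- model$forward(x, training = TRUE, with_aux = TRUE)
          if (is.list(out) && !inherits(out, "fs_tensor")) {
            loss <- ag_add(ag_cross_entropy(out$main, batch$y),
                           ag_scale(ag_cross_entropy(out$aux, batch$y),
                                    config$aux_weight))
          } else {
            loss <- ag_cross_entropy(out, batch$y)
          }
          if (!is.finite(loss$v))
            stop("non-finite training loss at epoch ", epoch, call. = FALSE)
          ag_backward(loss)
          loss$v
        })
        t_global <- t_global + 1L
        adam_step(params, lr, config, t_global)
        losses <- c(losses, loss_val)
        # large transient graphs fragment the heap; collect eagerly
        gc(FALSE)
      }
      row <- data.frame(epoch = epoch, lr = lr, train_loss = mean(losses),
                        val_miou = NA_real_, val_mpa = NA_real_)
      if (!is.null(val_records) && length(val_records)) {
        cm <- confusion_matrix(model$n_classes)
        for (rec in val_records) {
          logits <- model_forward(model, image_to_tensor(rec$image))
          pred <- apply(logits, c(2L, 3L), which.max) - 1L
          cm <- cm_accumulate(cm, pred, rec$mask)
        }
        row$val_miou <- miou(cm)
        row$val_mpa <- mpa(cm)
        if (row$val_miou > best$miou) {
          best$miou <- row$val_miou
          best$state <- model_state(model)
        }
      }
      history <- rbind(history, row)
      if (verbose)
        message(sprintf("epoch %3d  lr %.2e  loss %.4f  val miou %s",
                        epoch, lr, row$train_loss,
                        ifelse(is.na(row$val_miou), "-",
                               sprintf("%.3f", row$val_miou))))
    }
  })
  if (!is.null(history_path))
    utils::write.csv(history, history_path, row.names = FALSE)
  list(history = history, best_miou = best$miou, best_state = best$state,
       final_loss = history$train_loss[nrow(history)], model = model)
}

#' Predict a binary mask for an image
#'
#' Letterboxes to the model's input size, takes the pixelwise argmax over
#' class logits, and maps the mask back to the source geometry.
#' @param model a trained model.
#' @param image `(height, width, 3)` array, 0-255.
#' @param image_size square input side the model was trained at.
#' @return integer `(height, width)` mask with values in `{0, 1, ...}`.
#' @export
predict_mask <- function(model, image, image_size = 480L) {
  rec <- preprocess(image, mask = NULL, target = image_size)
  logits <- model_forward(model, image_to_tensor(rec$image))
  pred <- apply(logits, c(2L, 3L), which.max) - 1L
  postprocess_mask(pred, rec)
}
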