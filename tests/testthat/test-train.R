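# Learning-rate schedule, training determinism, prediction contract.
# Training tests run a slimmed configuration (48x48, 2 samples) — the code
# path is identical to the full-scale protocol.

test_that("cosine schedule hits its anchors and never increases", {
  cfg <- train_config(epochs = 100L)
  expect_equal(lr_schedule(0, cfg), 5e-4)
  expect_equal(lr_schedule(50, cfg), 5e-4 / 2)
  lrs <- vapply(0:99, lr_schedule, numeric(1), config = cfg)
  expect_true(all(diff(lrs) <= 0))
  expect_error(lr_schedule(100, cfg), "out of range")
  expect_error(lr_schedule(-1, cfg), "out of range")
})

make_train_set <- function(n, size = 48L, seed = 71) {
  recs <- generate_fixtures(fixture_config(n_samples = n,
                                           image_size_range = c(size, size),
                                           contrast = 0.8, seed = seed))
  lapply(recs, function(r) preprocess(r$image, r$mask, target = size))
}

test_that("training is deterministic for a fixed seed and config", {
  prep <- make_train_set(2)
  cfg <- train_config(epochs = 1, batch_size = 2, image_size = 48, seed = 9)
  run <- function() {
    set.seed(123)
    m <- build_model("IST-PSPNet")
    loss <- train_model(m, prep, config = cfg)$final_loss
    rm(m); gc(FALSE)
    loss
  }
  l1 <- run()
  l2 <- run()
  expect_identical(l1, l2)
  expect_true(is.finite(l1))
})

test_that("training errors on an empty dataset", {
  m0 <- build_model("PSPNet", aux = FALSE, init = "zero")
  expect_error(train_model(m0, list()), "empty")
  rm(m0); gc(FALSE)
})

test_that("prediction returns source-geometry binary masks, idempotently", {
  set.seed(124)
  m <- build_model("PSPNet")
  img <- generate_fixtures(fixture_config(n_samples = 1,
                                          image_size_range = c(40, 60),
                                          seed = 5))[[1]]$image
  p1 <- predict_mask(m, img, image_size = 48)
  p2 <- predict_mask(m, img, image_size = 48)
  expect_identical(dim(p1), dim(img)[1:2])
  expect_true(all(p1 %in% c(0L, 1L)))
  expect_identical(p1, p2)
  rm(m); gc(FALSE)
})

test_that("checkpoints round-trip the model state", {
  set.seed(125)
  m <- build_model("IS-PSPNet")
  img <- array(stats::runif(56 * 64 * 3, 0, 255), c(56, 64, 3))
  before <- predict_mask(m, img, image_size = 48)
  path <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(m, path)
  m2 <- load_checkpoint(path)
  expect_identical(m2$variant, "IS-PSPNet")
  expect_identical(predict_mask(m2, img, image_size = 48), before)
  rm(m, m2); gc(FALSE)
})

test_that("validation metrics logged by training match a recomputation", {
  prep <- make_train_set(2, seed = 77)
  cfg <- train_config(epochs = 1, batch_size = 2, image_size = 48, seed = 3)
  set.seed(126)
  m <- build_model("PSPNet")
  hist_file <- withr::local_tempfile(fileext = ".csv")
  fit <- train_model(m, prep, val_records = prep, config = cfg,
                     history_path = hist_file)
  cm <- confusion_matrix(2)
  for (rec in prep) {
    lg <- model_forward(m, fishseg:::image_to_tensor(rec$image))
    pred <- apply(lg, c(2, 3), which.max) - 1L
    cm <- cm_accumulate(cm, pred, rec$mask)
  }
  expect_equal(fit$history$val_miou[1], miou(cm))
  expect_equal(fit$history$val_mpa[1], mpa(cm))
  logged <- utils::read.csv(hist_file)
  expect_equal(logged$train_loss, fit$history$train_loss)
  rm(m); gc(FALSE)
})
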