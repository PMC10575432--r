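# Pyramid pooling module and full-model assembly.

test_that("ppm concatenates 2048 + 4x512 channels and preserves space", {
  set.seed(61)
  ppm <- fishseg:::ppm_module(64L, 16L)  # slim stand-in, same structure
  x <- fishseg:::ag_tensor(array(stats::rnorm(64 * 12 * 12), c(64, 12, 12, 1)))
  out <- ppm$forward(x)
  expect_identical(dim(out$v), c(64L + 4L * 16L, 12L, 12L, 1L))
  # channel arithmetic at full width via the analytic auditor
  full <- fishseg:::ppm_module(2048L, 512L, init = "zero")
  expect_identical(full$audit(c(2048L, 60L, 60L))$shape, c(4096L, 60L, 60L))
  # TA on/off changes no shapes
  ppm_ta <- fishseg:::ppm_module(64L, 16L, ta = ta_module(7))
  expect_identical(dim(ppm_ta$forward(x)$v), dim(out$v))
  # feature map smaller than the largest pool size
  tiny <- fishseg:::ag_tensor(array(0, c(64, 4, 4, 1)))
  expect_error(ppm$forward(tiny), "pool size")
})

test_that("variant table is the expected toggle lattice", {
  tab <- model_variants()
  expect_identical(tab$variant,
                   c("PSPNet", "I-PSPNet", "IS-PSPNet", "IST-PSPNet"))
  # monotone: each variant adds one toggle on top of the previous
  flags <- as.matrix(tab[, c("iaff", "softpool", "ta")])
  expect_equal(unname(rowSums(flags)), c(0, 1, 2, 3))
  for (k in 2:4) expect_true(all(flags[k, ] >= flags[k - 1, ]))
  expect_error(build_model("PSP-Net"), "unknown variant")
})

test_that("models forward to input-size logits and share TA cost", {
  set.seed(62)
  m <- build_model("IST-PSPNet")
  x <- array(stats::rnorm(3 * 64 * 64), c(3, 64, 64))
  lg <- model_forward(m, x)
  expect_identical(dim(lg), c(2L, 64L, 64L))
  expect_true(all(is.finite(lg)))
  # training path returns main + aux logits of the same size
  out <- m$forward(fishseg:::ag_tensor(fishseg:::as_4d(x)), training = TRUE,
                   with_aux = TRUE)
  expect_identical(dim(out$main$v), c(2L, 64L, 64L, 1L))
  expect_identical(dim(out$aux$v), c(2L, 64L, 64L, 1L))
  rm(m, out); gc(FALSE)

  # shared TA costs one module's parameters; unshared costs four
  shared <- build_model("IST-PSPNet", aux = FALSE, init = "zero")
  unshared <- build_model("IST-PSPNet", aux = FALSE, ta_shared = FALSE,
                          init = "zero")
  nots <- build_model("IS-PSPNet", aux = FALSE, init = "zero")
  one_ta <- count_params(ta_module(7, init = "zero"))
  expect_equal(count_params(shared) - count_params(nots), one_ta)
  expect_equal(count_params(unshared) - count_params(nots), 4 * one_ta)
  rm(shared, unshared, nots); gc(FALSE)
})
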