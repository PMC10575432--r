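# MS-CAM weights and AFF/iAFF fusion algebra.

test_that("ms_cam outputs valid fusion weights", {
  set.seed(1)
  m <- ms_cam_module(8, r = 4)
  x <- random_map(8, 5, 6, sd = 2)
  w <- ms_cam(x, m)
  expect_identical(dim(w), dim(x))
  expect_true(all(w > 0 & w < 1))

  # zero input with zero-initialised shifts/biases: sigmoid(0) = 0.5
  z <- ms_cam(array(0, c(8, 5, 6)), m)
  expect_equal(z, array(0.5, c(8, 5, 6)))

  expect_error(ms_cam(random_map(4, 5, 6), m), "channels")
})

test_that("parameter counts match the closed forms", {
  for (cfg in list(c(8L, 4L), c(64L, 16L), c(256L, 25L))) {
    C <- cfg[1L]; r <- cfg[2L]
    m <- ms_cam_module(C, r)
    expect_equal(count_params(m), ms_cam_param_formula(C, r))
    ia <- iaff_module(C, r)
    expect_equal(count_params(ia), 2 * ms_cam_param_formula(C, r))
    af <- aff_module(C, r)
    expect_equal(count_params(af), ms_cam_param_formula(C, r))
  }
})

test_that("fusion with frozen weights follows the defining algebra", {
  set.seed(2)
  x <- random_map(3, 4, 4); y <- random_map(3, 4, 4)
  expect_equal(fuse_convex(x, y, 1), x)       # M = 1 selects the identity path
  expect_equal(fuse_convex(x, y, 0), y)       # M = 0 selects the residual
  m <- array(stats::runif(length(x)), dim(x))
  f <- fuse_convex(x, y, m)
  expect_true(all(f >= pmin(x, y) - 1e-12 & f <= pmax(x, y) + 1e-12))
})

test_that("aff and iaff are convex combinations of their inputs", {
  set.seed(3)
  af <- aff_module(6, r = 3)
  ia <- iaff_module(6, r = 3)
  for (rep in 1:20) {
    x <- random_map(6, 4, 5, sd = 2); y <- random_map(6, 4, 5, sd = 2)
    for (out in list(aff(x, y, af), iaff(x, y, ia))) {
      expect_identical(dim(out), dim(x))
      expect_true(all(out >= pmin(x, y) - 1e-12 & out <= pmax(x, y) + 1e-12))
    }
    # X = Y: both stages are convex combinations of equal terms
    expect_equal(aff(x, x, af), x, tolerance = 1e-12)
    expect_equal(iaff(x, x, ia), x, tolerance = 1e-12)
  }
  expect_error(aff(random_map(6, 4, 5), random_map(6, 5, 4), af), "shapes")
})

test_that("gradients reach both fusion inputs", {
  set.seed(4)
  ia <- iaff_module(2, r = 1)
  xv <- array(stats::rnorm(2 * 3 * 3), c(2, 3, 3, 1))
  yv <- array(stats::rnorm(2 * 3 * 3), c(2, 3, 3, 1))
  xn <- fishseg:::ag_param(xv); yn <- fishseg:::ag_param(yv)
  grads <- fishseg:::fs_record({
    z <- ia$forward2(xn, yn, training = TRUE)
    s <- fishseg:::ag_record(sum(z$v), list(z),
                             function(g) fishseg:::ag_acc(z, array(g, dim(z$v))))
    fishseg:::ag_backward(s)
    list(x = xn$g, y = yn$g)
  })
  expect_true(any(abs(grads$x) > 0))
  expect_true(any(abs(grads$y) > 0))
  # finite-difference spot check on one coordinate of each input
  f <- function(xv2, yv2) {
    sum(ia$forward2(fishseg:::ag_tensor(xv2), fishseg:::ag_tensor(yv2),
                    training = TRUE)$v)
  }
  eps <- 1e-5
  for (src in c("x", "y")) {
    v <- if (src == "x") xv else yv
    k <- 5L
    vp <- v; vp[k] <- vp[k] + eps
    vm <- v; vm[k] <- vm[k] - eps
    num <- if (src == "x") (f(vp, yv) - f(vm, yv)) / (2 * eps)
           else (f(xv, vp) - f(xv, vm)) / (2 * eps)
    expect_equal(grads[[src]][k], num, tolerance = 1e-4)
  }
})
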