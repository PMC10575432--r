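# SoftPool: defining weighted sum, limits, bounds, gradients.

test_that("softpool matches the scalar definition on hand cases", {
  # constant window: weights sum to 1, so the output is the constant
  x <- array(3.7, c(2, 4, 4))
  expect_equal(softpool2d(x, 2), array(3.7, c(2, 2, 2)))

  # 2x2 window (1,2,3,4): softmax-weighted mean, frozen from the scalar
  # oracle sum(exp(a)*a)/sum(exp(a)) = 3.492654
  x <- array(c(1, 3, 2, 4), c(1, 2, 2))  # column-major: rows (1,3), (2,4)
  expect_equal(as.numeric(softpool2d(x, 2)), 3.4926539, tolerance = 1e-6)

  # dominant activation behaves like max pooling
  x <- array(c(0, 50), c(1, 1, 2))
  expect_equal(as.numeric(softpool2d(x, c(1, 2))), 50, tolerance = 1e-9)

  # negative window stays inside its own range
  x <- array(c(-1, -2), c(1, 1, 2))
  v <- as.numeric(softpool2d(x, c(1, 2)))
  expect_gt(v, -2); expect_lt(v, -1)

  # 1x1 windows are the identity
  x <- random_map(2, 3, 3)
  expect_equal(softpool2d(x, 1), x)
})

test_that("vectorised softpool equals the loop reference on random maps", {
  set.seed(42)
  specs <- list(list(k = 2L, s = 2L, p = 0L),
                list(k = 3L, s = 1L, p = 1L),
                list(k = c(2L, 3L), s = c(1L, 2L), p = c(1L, 0L)))
  for (rep in 1:30) {
    x <- random_map(sample(1:3, 1), sample(4:9, 1), sample(4:9, 1), sd = 2)
    sp <- specs[[sample(length(specs), 1)]]
    a <- softpool2d(x, sp$k, sp$s, sp$p)
    b <- softpool_reference(x, sp$k, sp$s, sp$p)
    expect_equal(a, b, tolerance = 1e-6)
  }
})

test_that("softpool is bounded by min/max pooling and shift equivariant", {
  set.seed(7)
  for (rep in 1:20) {
    x <- random_map(2, 6, 8, sd = 3)
    sp <- softpool2d(x, 2)
    lo <- pool_reference(x, 2, fun = min)
    hi <- pool_reference(x, 2, fun = max)
    expect_true(all(sp >= lo - 1e-12 & sp <= hi + 1e-12))
    cshift <- stats::rnorm(1, sd = 10)
    expect_equal(softpool2d(x + cshift, 2), sp + cshift, tolerance = 1e-9)
  }
})

test_that("padding semantics exclude padded positions from the window", {
  # with zero-inclusive padding a hot corner would be diluted; excluded
  # padding keeps border outputs inside the data range
  x <- array(5, c(1, 2, 2))
  out <- softpool2d(x, kernel = 2, stride = 1, padding = 1)
  expect_equal(dim(out), c(1L, 3L, 3L))
  expect_true(all(out == 5))
})

test_that("softpool has no parameters and full gradient flow", {
  expect_identical(count_params(fishseg:::nn_softpool(2L)), 0)
  x <- array(c(0.3, -0.8, 1.2, 0.5), c(1, 2, 2))
  xn <- fishseg:::ag_param(array(x, c(1, 2, 2, 1)))
  g <- fishseg:::fs_record({
    out <- fishseg:::ag_softpool(xn, c(2L, 2L))
    fishseg:::ag_backward(fishseg:::ag_record(sum(out$v), list(out),
                                              function(gr) fishseg:::ag_acc(out, array(gr, dim(out$v)))))
    xn$g
  })
  # every window element receives nonzero gradient (contrast with max pool)
  expect_true(all(abs(g) > 0))
  num <- array(0, dim(x))
  for (k in seq_along(x)) {
    eps <- 1e-6
    xp <- x; xp[k] <- xp[k] + eps
    xm <- x; xm[k] <- xm[k] - eps
    num[k] <- (sum(softpool2d(xp, 2)) - sum(softpool2d(xm, 2))) / (2 * eps)
  }
  expect_equal(array(g, dim(x)), num, tolerance = 1e-5)
})

test_that("softpool error contract", {
  expect_error(softpool2d(random_map(1, 2, 2), kernel = 4), "larger than")
  x <- random_map(1, 4, 4); x[1, 2, 2] <- NA
  expect_error(softpool2d(x, 2), "non-finite")
  expect_error(softpool2d(random_map(1, 4, 4), kernel = 0), "positive")
})
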