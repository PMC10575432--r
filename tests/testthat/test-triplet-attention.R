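# Triplet attention: Z-pool, rotations, gating, parameter sharing.

test_that("z_pool stacks max and mean over the leading dimension", {
  x <- random_map(5, 4, 6)
  z <- z_pool(x)
  expect_identical(dim(z), c(2L, 4L, 6L))
  expect_equal(z[1, , ], apply(x, c(2, 3), max))
  expect_equal(z[2, , ], apply(x, c(2, 3), mean))

  # constants: max = mean
  zc <- z_pool(array(2.5, c(3, 2, 2)))
  expect_true(all(zc == 2.5))

  # hand case {1, 5} -> (5, 3)
  zh <- z_pool(array(c(1, 5), c(2, 1, 1)))
  expect_equal(as.numeric(zh), c(5, 3))
})

test_that("rotation round trip is the identity", {
  x <- fishseg:::ag_tensor(array(stats::rnorm(3 * 4 * 5 * 2), c(3, 4, 5, 2)))
  for (p in list(c(2L, 1L, 3L), c(3L, 2L, 1L))) {
    y <- fishseg:::ag_permute(fishseg:::ag_permute(x, p), order(p))
    expect_identical(y$v, x$v)
  }
})

test_that("ta_forward matches the naive loop oracle and is gated", {
  set.seed(31)
  mod <- ta_module(7)
  for (rep in 1:5) {
    x <- random_map(4, 6, 5, sd = 2)
    y <- ta_forward(x, mod)
    expect_identical(dim(y), dim(x))
    expect_equal(y, naive_ta(x, mod), tolerance = 1e-6)
    expect_true(all(abs(y) <= abs(x) + 1e-12))  # sigmoid gates shrink
  }
  # zero input stays zero (gates scale zeros)
  expect_equal(ta_forward(array(0, c(4, 6, 5)), mod), array(0, c(4, 6, 5)))
})

test_that("branch subsets reduce to the corresponding attention", {
  set.seed(32)
  mods <- ta_module(7, branches = "spatial")
  x <- random_map(6, 5, 5)
  y <- ta_forward(x, mods)
  # hand-rolled spatial attention: z-pool over channels, conv, bn, sigmoid
  expect_equal(y, naive_ta(x, mods, "spatial"), tolerance = 1e-6)
  # each branch subset preserves shape
  for (b in list("height", "width", c("height", "width"))) {
    mb <- ta_module(7, branches = b)
    expect_identical(dim(ta_forward(x, mb)), dim(x))
    expect_equal(count_params(mb), 100 * length(b))  # 7*7*2 conv + 2 bn terms
  }
  expect_error(ta_module(7, branches = character(0)), "branch")
})

test_that("parameter sharing costs one module regardless of branch count", {
  set.seed(33)
  mod <- ta_module(7)
  expect_equal(count_params(mod), 300)  # ~0.0003 M: negligible
  feats <- lapply(c(1, 2, 3, 6), function(s) random_map(8, s, s))
  outs <- shared_ta_apply(feats, mod)
  expect_identical(lapply(outs, dim), lapply(feats, dim))
  # identical inputs through the shared module give identical outputs
  expect_identical(ta_forward(feats[[2]], mod), ta_forward(feats[[2]], mod))
  # unshared instantiation: one parameter set per scale
  per_scale <- lapply(1:4, function(i) ta_module(7))
  expect_equal(sum(vapply(per_scale, count_params, numeric(1))),
               4 * count_params(mod))
  expect_error(shared_ta_apply(list(random_map(4, 2, 2), random_map(8, 2, 2)),
                               mod), "channel")
})
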