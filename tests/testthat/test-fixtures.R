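# Synthetic fixture generator, letterbox preprocessing, dataset splitting,
# PNG round trips.

test_that("generator is deterministic and honours fish counts", {
  cfg <- fixture_config(n_samples = 5, image_size_range = c(40, 64), seed = 7)
  a <- generate_fixtures(cfg)
  b <- generate_fixtures(cfg)
  expect_length(a, 5)
  expect_identical(a, b)  # byte-identical under the same seed + config

  # no fish: masks are all zero
  none <- generate_fixtures(fixture_config(n_samples = 3,
                                           image_size_range = c(40, 48),
                                           fish_count_range = c(0, 0), seed = 3))
  for (r in none) expect_true(all(r$mask == 0L))

  # exactly two non-overlapping fish: connected-component oracle finds 2
  two <- generate_fixtures(fixture_config(n_samples = 4,
                                          image_size_range = c(80, 96),
                                          fish_count_range = c(2, 2), seed = 5))
  for (r in two) expect_identical(count_components(r$mask), 2L)

  # masks are binary and match image dims
  for (r in c(a, two)) {
    expect_true(all(r$mask %in% c(0L, 1L)))
    expect_identical(dim(r$mask), dim(r$image)[1:2])
  }
})

test_that("generator config validation", {
  expect_error(fixture_config(image_size_range = c(64, 32)), "min > max")
  expect_error(fixture_config(fish_count_range = c(3, 1)), "min > max")
  expect_error(fixture_config(contrast = 1.5), "contrast")
})

test_that("zero contrast renders fish indistinguishable from background", {
  cfg <- fixture_config(n_samples = 4, image_size_range = c(64, 64),
                        contrast = 0, seed = 9)
  recs <- generate_fixtures(cfg)
  ins <- outs <- c()
  for (r in recs) {
    lum <- apply(r$image, c(1, 2), mean)
    ins <- c(ins, lum[r$mask == 1L])
    outs <- c(outs, lum[r$mask == 0L])
  }
  # same generative luminance process inside and outside the mask: no usable
  # intensity cue (a significance test at n ~ 1e4 pixels would instead detect
  # the background's spatial nonstationarity, since fish avoid borders)
  expect_lt(abs(mean(ins) - mean(outs)), 3)
  expect_gt(stats::sd(ins) / stats::sd(outs), 0.8)
  expect_lt(stats::sd(ins) / stats::sd(outs), 1.25)

  # ... whereas with contrast on, the separation is large
  hi <- generate_fixtures(fixture_config(n_samples = 4,
                                         image_size_range = c(64, 64),
                                         contrast = 0.8, seed = 9))
  d_hi <- abs(unlist(lapply(hi, function(r) {
    lum <- apply(r$image, c(1, 2), mean)
    mean(lum[r$mask == 1L]) - mean(lum[r$mask == 0L])
  })))
  expect_gt(mean(d_hi), 20)
})

test_that("preprocess letterboxes with the documented arithmetic", {
  # 200x300 at target 480: scale 1.6, content 320x480, 80-row bands
  img <- array(stats::runif(200 * 300 * 3, 0, 255), c(200, 300, 3))
  mask <- matrix(0L, 200, 300); mask[50:90, 100:200] <- 1L
  rec <- preprocess(img, mask, target = 480)
  expect_identical(dim(rec$image), c(480L, 480L, 3L))
  expect_identical(rec$pad_box, c(80L, 0L, 80L, 0L))
  expect_identical(rec$source_size, c(200L, 300L))
  # margins carry only the fill value
  expect_true(all(rec$image[1:80, , ] == 128))
  expect_true(all(rec$image[401:480, , ] == 128))
  # mask stays binary under nearest-neighbour + zero padding
  expect_true(all(rec$mask %in% c(0L, 1L)))
  expect_true(all(rec$mask[1:80, ] == 0L))

  # square input at target size is untouched
  sq <- array(7, c(480, 480, 3))
  rec2 <- preprocess(sq, NULL, target = 480)
  expect_identical(rec2$pad_box, c(0L, 0L, 0L, 0L))
  expect_equal(rec2$image, sq)

  expect_error(preprocess(array(0, c(0, 4, 3))), "empty")
})

test_that("preprocessing round-trips masks whose dimensions divide evenly", {
  set.seed(4)
  mask <- matrix(as.integer(stats::runif(60 * 120) > 0.7), 60, 120)
  img <- array(100, c(60, 120, 3))
  rec <- preprocess(img, mask, target = 240)  # scale 2, pad 60 top+bottom
  back <- postprocess_mask(rec$mask, rec)
  expect_identical(back, mask)
})

test_that("split sizes use largest remainder and conserve records", {
  recs <- as.list(seq_len(1120))
  sp <- split_dataset(recs, c(0.7, 0.15, 0.15), seed = 1)
  expect_identical(lengths(sp), c(train = 784L, val = 168L, test = 168L))

  sp10 <- split_dataset(as.list(1:10), seed = 2)
  expect_identical(unname(lengths(sp10)), c(7L, 2L, 1L))  # tie to val first
  expect_setequal(unlist(sp10), 1:10)

  # conservation + disjointness over random sizes
  set.seed(11)
  for (n in sample(3:200, 10)) {
    sp <- split_dataset(as.list(seq_len(n)), seed = n)
    expect_identical(sum(lengths(sp)), n)
    expect_identical(sort(unname(unlist(sp))), seq_len(n))
  }

  # determinism
  expect_identical(split_dataset(recs, seed = 5), split_dataset(recs, seed = 5))
  expect_error(split_dataset(as.list(1:2)), "fewer records")
  expect_error(split_dataset(recs, c(0.5, -0.1, 0.6)), "positive")
})

test_that("PNG round trip preserves masks and approximates images", {
  dir <- withr::local_tempdir()
  recs <- generate_fixtures(fixture_config(n_samples = 6,
                                           image_size_range = c(32, 48),
                                           seed = 21))
  sp <- split_dataset(recs, seed = 1)
  manifest <- write_fixture_dir(sp, dir)
  expect_identical(nrow(manifest), 6L)
  expect_setequal(unique(manifest$split), c("train", "val", "test"))
  back <- read_fixture_dir(dir)
  flat_in <- c(sp$train, sp$val, sp$test)
  flat_out <- c(back$train, back$val, back$test)
  for (k in seq_along(flat_in)) {
    expect_identical(flat_out[[k]]$mask, flat_in[[k]]$mask)
    expect_equal(flat_out[[k]]$image, flat_in[[k]]$image, tolerance = 0.5)
  }
})
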