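# Synthetic underwater-fish fixtures and dataset plumbing.
#
# The generator emulates the structure of an underwater fish segmentation
# dataset: variable-size RGB frames with a textured, tinted background and
# one or more low-contrast elliptical fish bodies (with an optional tail
# triangle), blurred and noised, paired with exact binary masks rendered from
# the same geometry before any blur.  It does not attempt photo-realism;
# it provides the low-contrast, fuzzy-edge regime the attention blocks are
# meant to address, with ground truth known exactly.

#' Fixture generator configuration
#'
#' @param n_samples number of image/mask pairs.
#' @param image_size_range (min, max) image side length in pixels; height and
#'   width are drawn independently.
#' @param fish_count_range (min, max) fish per image.
#' @param contrast fish/background intensity separation in `[0, 1]`; 0 makes
#'   fish statistically indistinguishable from the background.
#' @param blur_sigma Gaussian blur scale in pixels.
#' @param noise_sd additive Gaussian noise SD on the 0-255 scale.
#' @param seed integer seed; identical seed + config gives byte-identical
#'   output.
#' @param allow_overlap allow fish ellipses to overlap (the generator
#'   otherwise rejection-samples up to 50 placements per fish).
#' @return a `fishseg_config` list.
#' @export
fixture_config <- function(n_samples = 16L, image_size_range = c(96L, 144L),
                           fish_count_range = c(1L, 3L), contrast = 0.35,
                           blur_sigma = 1.5, noise_sd = 6, seed = 1L,
                           allow_overlap = FALSE) {
  chk_range <- function(r, what) {
    if (length(r) != 2L || r[1L] > r[2L])
      stop("invalid ", what, " range (min > max)", call. = FALSE)
  }
  chk_range(image_size_range, "image size")
  chk_range(fish_count_range, "fish count")
  if (contrast < 0 || contrast > 1) stop("contrast must be in [0,1]", call. = FALSE)
  structure(list(n_samples = as.integer(n_samples),
                 image_size_range = as.integer(image_size_range),
                 fish_count_range = as.integer(fish_count_range),
                 contrast = contrast, blur_sigma = blur_sigma,
                 noise_sd = noise_sd, seed = as.integer(seed),
                 allow_overlap = isTRUE(allow_overlap)),
            class = "fishseg_config")
}

# sample() treats a length-1 vector as a population size; guard the
# degenerate lo == hi range
sample_range <- function(lo, hi) if (lo >= hi) lo else sample(lo:hi, 1L)

with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# separable Gaussian blur with edge replication
gauss_blur <- function(mat, sigma) {
  if (sigma <= 0) return(mat)
  r <- max(1L, ceiling(2.5 * sigma))
  k <- exp(-((-r):r)^2 / (2 * sigma^2))
  k <- k / sum(k)
  pad_conv <- function(m) {
    n <- nrow(m)
    mp <- m[c(rep(1L, r), seq_len(n), rep(n, r)), , drop = FALSE]
    out <- matrix(0, n, ncol(m))
    for (i in seq_along(k)) out <- out + k[i] * mp[(i - 1L) + seq_len(n), , drop = FALSE]
    out
  }
  t(pad_conv(t(pad_conv(mat))))
}

dilate_mask <- function(m, times = 2L) {
  for (k in seq_len(times)) {
    d <- m
    n <- nrow(m); w <- ncol(m)
    d[-1, ] <- d[-1, ] | m[-n, ]
    d[-n, ] <- d[-n, ] | m[-1, ]
    d[, -1] <- d[, -1] | m[, -w]
    d[, -w] <- d[, -w] | m[, -1]
    m <- d
  }
  m
}

# membership mask of a rotated ellipse plus a tail triangle
render_fish <- function(h, w, cy, cx, a, b, theta, tail = TRUE) {
  ys <- matrix(seq_len(h), h, w) - cy
  xs <- matrix(seq_len(w), h, w, byrow = TRUE) - cx
  u <- xs * cos(theta) + ys * sin(theta)
  v <- -xs * sin(theta) + ys * cos(theta)
  inside <- (u / a)^2 + (v / b)^2 <= 1
  if (tail) {
    # triangle: tip behind the ellipse on the major axis, base on the rim
    tip <- c(-1.45 * a, 0)
    base1 <- c(-0.75 * a, 0.8 * b)
    base2 <- c(-0.75 * a, -0.8 * b)
    sign_edge <- function(p1, p2) {
      (u - p1[1]) * (p2[2] - p1[2]) - (v - p1[2]) * (p2[1] - p1[1])
    }
    d1 <- sign_edge(tip, base1); d2 <- sign_edge(base1, base2); d3 <- sign_edge(base2, tip)
    tri <- (d1 >= 0 & d2 >= 0 & d3 >= 0) | (d1 <= 0 & d2 <= 0 & d3 <= 0)
    inside <- inside | tri
  }
  inside
}

#' Generate synthetic image/mask fixtures
#'
#' @param config a [fixture_config()].
#' @return list of sample records; each has `image` (height, width, 3;
#'   0-255), `mask` (height, width; 0/1), `source_size`, and `pad_box`
#'   (all-zero until [preprocess()] is applied).
#' @export
generate_fixtures <- function(config = fixture_config()) {
  stopifnot(inherits(config, "fishseg_config"))
  with_seed(config$seed, {
    lapply(seq_len(config$n_samples), function(i) {
      h <- sample_range(config$image_size_range[1L], config$image_size_range[2L])
      w <- sample_range(config$image_size_range[1L], config$image_size_range[2L])
      # textured background: a few random low-frequency waves, blurred noise
      ys <- matrix(seq_len(h) / h, h, w)
      xs <- matrix(seq_len(w) / w, h, w, byrow = TRUE)
      tex <- matrix(0, h, w)
      for (k in 1:3) {
        fr <- stats::runif(2, 1, 5); ph <- stats::runif(2, 0, 2 * pi)
        tex <- tex + sin(2 * pi * fr[1] * ys + ph[1]) * cos(2 * pi * fr[2] * xs + ph[2])
      }
      tex <- tex / 3 + gauss_blur(matrix(stats::rnorm(h * w, sd = 0.4), h, w), 2)
      base <- stats::runif(1, 80, 130)
      lum <- base + 25 * tex
      # underwater tint: green/blue heavy channel gains
      tint <- c(stats::runif(1, 0.45, 0.7), stats::runif(1, 0.85, 1.0),
                stats::runif(1, 0.75, 1.0))
      n_fish <- sample_range(config$fish_count_range[1L], config$fish_count_range[2L])
      mask <- matrix(0L, h, w)
      fish_lum <- matrix(0, h, w)
      placed <- 0L
      tries <- 0L
      while (placed < n_fish && tries < 50L * max(1L, n_fish)) {
        tries <- tries + 1L
        a <- stats::runif(1, 0.08, 0.16) * min(h, w)
        b <- a * stats::runif(1, 0.35, 0.55)
        cy <- stats::runif(1, 1.3 * a, h - 1.3 * a)
        cx <- stats::runif(1, 1.6 * a, w - 1.6 * a)
        theta <- stats::runif(1, 0, pi)
        fm <- render_fish(h, w, cy, cx, a, b, theta)
        # keep a 2 px margin so distinct fish stay distinct components
        if (!config$allow_overlap && any(fm & dilate_mask(mask == 1L))) next
        mask[fm] <- 1L
        # fish luminance offset, direction random per fish
        dir <- sample(c(-1, 1), 1L)
        fish_lum[fm] <- dir * config$contrast * 120
        placed <- placed + 1L
      }
      img <- array(0, c(h, w, 3L))
      for (ch in 1:3) {
        plane <- (lum + fish_lum) * tint[ch]
        plane <- gauss_blur(plane, config$blur_sigma)
        plane <- plane + stats::rnorm(h * w, sd = config$noise_sd)
        img[, , ch] <- pmin(pmax(plane, 0), 255)
      }
      structure(list(image = img, mask = mask, source_size = c(h, w),
                     pad_box = c(0L, 0L, 0L, 0L), fill = NA_integer_),
                class = "fishseg_sample")
    })
  })
}

# nearest-neighbour index map from n_out positions back to n_in
nn_index <- function(n_in, n_out) {
  idx <- floor((seq_len(n_out) - 0.5) * n_in / n_out) + 1
  pmin(pmax(idx, 1L), n_in)
}

resize_image_bilinear <- function(img, h_out, w_out) {
  d <- dim(img)
  S <- bilinear_matrix(d[1L], d[2L], h_out, w_out)
  out <- array(0, c(h_out, w_out, d[3L]))
  for (ch in seq_len(d[3L])) {
    v <- as.numeric(S %*% as.vector(img[, , ch]))
    out[, , ch] <- matrix(v, h_out, w_out)
  }
  out
}

#' Letterbox an image (and mask) to a square with gray fill
#'
#' Scales uniformly so the longer side hits `target`, then pads the remaining
#' margins symmetrically with a constant gray, preserving the true aspect
#' ratio of the content. The mask is resized with nearest-neighbour (labels
#' stay binary) and padded with background (0). The pad box is recorded so a
#' predicted mask can be mapped back to the source geometry.
#'
#' @param image numeric `(height, width, 3)` array, 0-255.
#' @param mask optional integer `(height, width)` matrix with values in
#'   `{0, 1}`.
#' @param target output side length (480 for the full-scale configuration).
#' @param fill gray fill value on the 0-255 scale.
#' @return a `fishseg_sample` with fields `image`, `mask` (or NULL),
#'   `source_size`, `pad_box = c(top, left, bottom, right)`, `fill`.
#' @export
preprocess <- function(image, mask = NULL, target = 480L, fill = 128L) {
  d <- dim(image)
  if (is.null(d) || length(d) != 3L || d[1L] < 1L || d[2L] < 1L)
    stop("empty or non-RGB image", call. = FALSE)
  if (target < 1L) stop("target must be positive", call. = FALSE)
  target <- as.integer(target)
  h <- d[1L]; w <- d[2L]
  scale <- min(target / h, target / w)
  nh <- as.integer(round(h * scale)); nw <- as.integer(round(w * scale))
  top <- (target - nh) %/% 2L
  left <- (target - nw) %/% 2L
  bottom <- target - nh - top
  right <- target - nw - left
  out <- array(as.numeric(fill), c(target, target, 3L))
  content <- if (nh == h && nw == w) image else resize_image_bilinear(image, nh, nw)
  out[top + seq_len(nh), left + seq_len(nw), ] <- content
  mout <- NULL
  if (!is.null(mask)) {
    if (!all(mask %in% c(0L, 1L))) stop("mask must be binary {0,1}", call. = FALSE)
    mout <- matrix(0L, target, target)
    mout[top + seq_len(nh), left + seq_len(nw)] <-
      mask[nn_index(h, nh), nn_index(w, nw)]
  }
  structure(list(image = out, mask = mout, source_size = c(h, w),
                 pad_box = c(top, left, bottom, right),
                 fill = as.integer(fill)),
            class = "fishseg_sample")
}

#' Map a predicted mask back to the source image geometry
#'
#' Inverse of [preprocess()] for masks: crops the recorded pad box and
#' resizes with nearest-neighbour back to the source size.
#' @param mask square integer mask as produced at the model's input size.
#' @param record the `fishseg_sample` whose `pad_box`/`source_size` to invert.
#' @return integer mask of the original `(height, width)`.
#' @export
postprocess_mask <- function(mask, record) {
  pb <- record$pad_box
  d <- dim(mask)
  content <- mask[(pb[1L] + 1L):(d[1L] - pb[3L]),
                  (pb[2L] + 1L):(d[2L] - pb[4L]), drop = FALSE]
  h <- record$source_size[1L]; w <- record$source_size[2L]
  content[nn_index(nrow(content), h), nn_index(ncol(content), w), drop = FALSE]
}

#' Split records into train/validation/test partitions
#'
#' Largest-remainder apportionment of the (normalised) ratios, applied to a
#' seeded random permutation: the partition is disjoint, exhaustive, and
#' deterministic per seed. Remainder seats go to the partitions with the
#' largest fractional part (ties broken in train/val/test order).
#'
#' @param records list of samples.
#' @param ratios positive weights for (train, val, test); normalised to 1.
#' @param seed integer seed for the permutation.
#' @return `list(train = ..., val = ..., test = ...)`.
#' @export
split_dataset <- function(records, ratios = c(0.7, 0.15, 0.15), seed = 1L) {
  n <- length(records)
  if (any(ratios <= 0) || length(ratios) != 3L)
    stop("ratios must be three positive numbers", call. = FALSE)
  if (n < 3L) stop("fewer records than partitions", call. = FALSE)
  ratios <- ratios / sum(ratios)
  raw <- n * ratios
  sizes <- floor(raw)
  rem <- n - sum(sizes)
  if (rem > 0) {
    frac <- raw - sizes
    take <- order(-frac, seq_along(frac))[seq_len(rem)]
    sizes[take] <- sizes[take] + 1
  }
  perm <- with_seed(seed, sample.int(n))
  ends <- cumsum(sizes)
  starts <- c(1, ends[-3L] + 1)
  slice <- function(k) {
    if (sizes[k] == 0) list() else records[perm[starts[k]:ends[k]]]
  }
  list(train = slice(1L), val = slice(2L), test = slice(3L))
}

# ---- PNG I/O ---------------------------------------------------------------

#' Write fixtures as PNG pairs with a manifest
#'
#' Directory layout: `images/<stem>.png` (8-bit RGB), `masks/<stem>.png`
#' (8-bit gray, 0/255), and `manifest.csv` with columns `stem, split`.
#' @param splits named list of record lists as from [split_dataset()], or a
#'   plain list of records (split column then says "all").
#' @param dir output directory (created if needed).
#' @return invisibly, the manifest data.frame.
#' @export
write_fixture_dir <- function(splits, dir) {
  if (!is.list(splits)) stop("splits must be a list", call. = FALSE)
  if (inherits(splits, "fishseg_sample") ||
      (length(splits) && inherits(splits[[1L]], "fishseg_sample"))) {
    splits <- list(all = splits)
  }
  dir.create(file.path(dir, "images"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "masks"), recursive = TRUE, showWarnings = FALSE)
  rows <- list()
  i <- 0L
  for (sp in names(splits)) {
    for (rec in splits[[sp]]) {
      i <- i + 1L
      stem <- sprintf("sample_%04d", i)
      png::writePNG(rec$image / 255, file.path(dir, "images", paste0(stem, ".png")))
      png::writePNG(rec$mask * 1.0, file.path(dir, "masks", paste0(stem, ".png")))
      rows[[i]] <- data.frame(stem = stem, split = sp, stringsAsFactors = FALSE)
    }
  }
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}

#' Read an image/mask PNG pair
#'
#' Masks stored as `{0, 1}` or `{0, 255}` (or any two-level gray) are
#' normalised to `{0, 1}` on read.
#' @param image_path path to the RGB PNG.
#' @param mask_path optional path to the mask PNG.
#' @return a `fishseg_sample`.
#' @export
read_sample <- function(image_path, mask_path = NULL) {
  img <- png::readPNG(image_path)
  if (length(dim(img)) == 2L) img <- array(rep(img, 3L), c(dim(img), 3L))
  img <- img[, , 1:3, drop = FALSE] * 255
  mask <- NULL
  if (!is.null(mask_path)) {
    mk <- png::readPNG(mask_path)
    if (length(dim(mk)) == 3L) mk <- mk[, , 1L]
    mask <- matrix(as.integer(mk > 0.5), nrow(mk), ncol(mk))
  }
  structure(list(image = img, mask = mask,
                 source_size = dim(img)[1:2],
                 pad_box = c(0L, 0L, 0L, 0L), fill = NA_integer_),
            class = "fishseg_sample")
}

#' Read a fixture directory written by [write_fixture_dir()]
#' @param dir directory containing `images/`, `masks/`, `manifest.csv`.
#' @return named list of record lists, one per split.
#' @export
read_fixture_dir <- function(dir) {
  manifest <- utils::read.csv(file.path(dir, "manifest.csv"),
                              stringsAsFactors = FALSE)
  out <- list()
  for (sp in unique(manifest$split)) {
    stems <- manifest$stem[manifest$split == sp]
    out[[sp]] <- lapply(stems, function(s) {
      read_sample(file.path(dir, "images", paste0(s, ".png")),
                  file.path(dir, "masks", paste0(s, ".png")))
    })
  }
  out
}

# (height, width, 3) 0-255 image -> (3, H, W) tensor scaled to [-1, 1]-ish
image_to_tensor <- function(img) {
  aperm(img / 127.5 - 1, c(3L, 1L, 2L))
}
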