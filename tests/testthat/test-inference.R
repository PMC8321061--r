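test_that("probability maps obey the softmax law", {
  net <- build_network(tiny_arch(c(32, 32), 4), seed = 9)
  img <- array(runif(32 * 32 * 3), c(32, 32, 3))
  fw <- network_forward(net, img)
  z <- fw$scores
  p2 <- exp(z[, , 2]) / (exp(z[, , 1]) + exp(z[, , 2]))
  pm <- predict_probability(net, img)
  expect_equal(pmat(pm), p2, tolerance = 1e-12)
  expect_true(all(pm >= 0 & pm <= 1))
  expect_false(anyNA(pm))
})

test_that("tta_spec enforces the divisibility invariant and view count", {
  expect_equal(tta_spec(15)$n_views, 24L)
  expect_equal(tta_spec(90)$n_views, 4L)
  expect_equal(tta_spec(360)$n_views, 1L)
  expect_error(tta_spec(17), "divide")
})

test_that("rotation TTA processes 24 views at the 15-degree default", {
  calls <- new.env(); calls$n <- 0L
  dummy <- function(image) {
    calls$n <- calls$n + 1L
    matrix(0.5, dim(image)[1], dim(image)[2])
  }
  img <- array(runif(20 * 20 * 3), c(20, 20, 3))
  out <- predict_tta(dummy, img, tta_spec(15, "probability_mean"))
  expect_equal(calls$n, 24L)
  expect_equal(attr(out, "n_views"), 24L)
  expect_true(attr(out, "tta"))
})

test_that("single-view TTA in probability mode is bit-identical to predict", {
  net <- build_network(tiny_arch(c(24, 28), 4), seed = 10)
  img <- array(runif(24 * 28 * 3), c(24, 28, 3))
  plain <- predict_probability(net, img)
  tta1 <- predict_tta(net, img, tta_spec(360, "probability_mean"))
  expect_identical(pmat(tta1), pmat(plain))
})

test_that("TTA is neutral for a constant predictor and lattice-valued in binary mode", {
  const <- function(image) matrix(0.7, dim(image)[1], dim(image)[2])
  img <- array(runif(24 * 24 * 3), c(24, 24, 3))
  out <- predict_tta(const, img, tta_spec(45, "probability_mean"))
  expect_equal(max(abs(out - 0.7)), 0, tolerance = 1e-12)
  outb <- predict_tta(const, img, tta_spec(45, "binary_mean"))
  # every view thresholds 0.7 to 1, so the aggregate is exactly 1
  expect_true(all(outb == 1))
  # lattice property on a half-and-half predictor
  half <- function(image) {
    h <- dim(image)[1]
    matrix(rep(c(0.9, 0.1), each = ceiling(h / 2))[seq_len(h)],
           h, dim(image)[2])
  }
  outl <- predict_tta(half, img, tta_spec(90, "binary_mean"))
  lattice <- outl * 4
  expect_equal(lattice, round(lattice), tolerance = 1e-9)
})

test_that("TTA equals plain prediction for an equivariant dummy predictor", {
  # the red-channel predictor commutes with rotation, so averaging the
  # inverse-rotated outputs reproduces the plain output exactly
  red <- function(image) image[, , 1]
  img <- array(runif(32 * 32 * 3), c(32, 32, 3))
  plain <- predict_probability(red, img)
  out <- predict_tta(red, img, tta_spec(90, "probability_mean"))
  expect_equal(pmat(out), pmat(plain),
               tolerance = 1e-12)
})

test_that("TTA output stays within [0, 1] on non-square frames", {
  net <- build_network(tiny_arch(c(40, 52), 4), seed = 12)
  img <- array(runif(40 * 52 * 3), c(40, 52, 3))
  out <- predict_tta(net, img, tta_spec(45, "probability_mean"))
  expect_equal(dim(out), c(40L, 52L))
  expect_true(all(out >= 0 & out <= 1))
})

test_that("postprocess thresholds, opens, and fills holes as specified", {
  # uniform high map: everything survives
  u <- matrix(0.9, 12, 12)
  expect_true(all(postprocess(u, postprocess_spec()) == 1))
  # single isolated pixel dies under a radius-2 opening
  lone <- matrix(0, 10, 10); lone[5, 5] <- 0.9
  expect_true(all(postprocess(lone, postprocess_spec(
    opening_radius = 2L)) == 0))
  # interior hole: filled when fill_holes is on, kept when off
  disc <- disc_mask(21, 7) * 0.9
  disc[11, 11] <- 0
  filled <- postprocess(disc, postprocess_spec(opening_radius = 0L,
                                               fill_holes = TRUE))
  kept <- postprocess(disc, postprocess_spec(opening_radius = 0L,
                                             fill_holes = FALSE))
  expect_equal(filled[11, 11], 1)
  expect_equal(kept[11, 11], 0)
  expect_equal(sum(filled) - sum(kept), 1)
})

test_that("postprocess is idempotent", {
  set.seed(14)
  pm <- matrix(runif(30 * 30), 30, 30)
  for (spec in list(postprocess_spec(),
                    postprocess_spec(threshold = 0.3, opening_radius = 1L),
                    postprocess_spec(fill_holes = FALSE))) {
    once <- postprocess(pm, spec)
    twice <- postprocess(once, spec)
    expect_identical(once, twice)
  }
})

test_that("postprocess_spec validates the threshold range", {
  expect_error(postprocess_spec(threshold = 0), "threshold")
  expect_error(postprocess_spec(threshold = 1), "threshold")
})

test_that("rotation TTA does not degrade phantom segmentation (non-inferiority)", {
  # a trained toy network scored on 56 held-out phantoms: the median Dice
  # with 8-view TTA must be within 2% of the plain median
  corpus <- generate_corpus(phantom_spec(
    image_height = 64, image_width = 64, n_sequences = 6,
    frames_per_sequence = 14, polyp_radius_range = c(10, 16), seed = 77))
  arch <- architecture_spec(backbone_depth = 14L, input_size = c(64L, 64L),
                            path_channels = 16L, dropout_rate = 0.1)
  net <- build_network(arch, seed = 2)
  ts <- training_spec(epochs = 6, initial_learning_rate = 1e-3,
                      decay_every = 100, batch_size = 2,
                      class_weighting = "balanced", seed = 5)
  fit <- train_network(net, corpus[1:28], ts)
  held <- corpus[29:84]
  post <- postprocess_spec(opening_radius = 1L)
  dice_of <- function(tta) vapply(held, function(s) {
    pm <- if (is.null(tta)) predict_probability(fit$network, s$image)
          else predict_tta(fit$network, s$image, tta)
    dice_coefficient(confusion_counts(postprocess(pm, post), s$mask))
  }, numeric(1))
  d_plain <- dice_of(NULL)
  d_tta <- dice_of(tta_spec(45, "binary_mean"))
  expect_gte(median(d_tta), median(d_plain) - 0.02)
})
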