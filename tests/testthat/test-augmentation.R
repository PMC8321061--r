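make_sample <- function(h, w, seed = 1) {
  set.seed(seed)
  img <- array(runif(h * w * 3), c(h, w, 3))
  msk <- disc_mask(min(h, w), min(h, w) %/% 4)
  full <- matrix(0, h, w)
  full[seq_len(nrow(msk)), seq_len(ncol(msk))] <- msk
  segmentation_sample(img, full, "seqA", "f1")
}

test_that("rescale_and_crop reaches the target size with isotropic scaling", {
  # 500x574 -> 250x287: exact factor 1/2, no crop freedom
  s <- make_sample(500, 574)
  out <- rescale_and_crop(s, c(250, 287), seed = 3)
  expect_equal(dim(out$image), c(250L, 287L, 3L))
  expect_equal(dim(out$mask), c(250L, 287L))
  expect_true(all(out$mask %in% c(0, 1)))
  # identity case: already at target, crop offset must be (0,0)
  s2 <- make_sample(250, 287)
  out2 <- rescale_and_crop(s2, c(250, 287), seed = 1)
  expect_equal(out2$mask, s2$mask)
  # 288x384 -> 250x287: height is the binding dimension, width overhang
  s3 <- make_sample(288, 384)
  out3 <- rescale_and_crop(s3, c(250, 287), seed = 2)
  expect_equal(dim(out3$image)[1:2], c(250L, 287L))
  expect_true(all(out3$mask %in% c(0, 1)))
  # upscaling permitted for smaller inputs
  s4 <- make_sample(100, 100)
  expect_equal(dim(rescale_and_crop(s4, c(250, 287), seed = 1)$image)[1:2],
               c(250L, 287L))
})

test_that("rotation is the identity at 0 and 360 degrees and preserves disc area", {
  s <- make_sample(64, 64)
  expect_identical(rotate_pair(s, 0)$image, s$image)
  expect_identical(rotate_pair(s, 360)$image, s$image)
  # rotation-symmetric mask: foreground area preserved within 2%
  disc <- segmentation_sample(array(0.5, c(65, 65, 3)),
                              disc_mask(65, 20), "s", "f")
  for (ang in c(33, 90, 215)) {
    r <- rotate_pair(disc, ang)
    expect_lt(abs(sum(r$mask) - sum(disc$mask)) / sum(disc$mask), 0.02)
    expect_true(all(r$mask %in% c(0, 1)))
  }
})

test_that("geometric transforms move image and mask with one shared warp", {
  # encode the mask into an image channel; transforming both must keep the
  # channel consistent with the transformed mask wherever sampling is exact
  s <- make_sample(48, 48)
  s$image[, , 3] <- s$mask  # third channel mirrors the mask
  for (out in list(rotate_pair(s, 123), scale_pair(s, 1.15),
                   tps_deform_pair(s, c(4, 4), 3, seed = 9))) {
    inter <- out$image[, , 3]
    agree <- mean((inter > 0.5) == (out$mask == 1))
    expect_gt(agree, 0.97)  # disagreement only at interpolated boundaries
    expect_true(all(out$mask %in% c(0, 1)))
  }
})

test_that("TPS displacement field interpolates bounded control displacements", {
  fld <- tps_displacement_field(c(40, 44), c(5, 5), 4, seed = 31)
  expect_true(all(abs(fld$disp) <= 4))
  # the field interpolates: at control points it equals the displacement
  at_ctrl_y <- fld$dy[cbind(round(fld$control[, 1]) + 1,
                            round(fld$control[, 2]) + 1)]
  expect_equal(at_ctrl_y, fld$disp[, 1], tolerance = 0.15)
  # interior displacement magnitudes stay within the TPS bound over the
  # displaced control points (no wild extrapolation)
  expect_lt(max(abs(fld$dy)), 4 * 2.5)
  # determinism
  fld2 <- tps_displacement_field(c(40, 44), c(5, 5), 4, seed = 31)
  expect_identical(fld$dy, fld2$dy)
  # zero displacement is the identity
  fld0 <- tps_displacement_field(c(20, 20), c(4, 4), 0, seed = 1)
  expect_true(all(fld0$dy == 0) && all(fld0$dx == 0))
  s <- make_sample(40, 40)
  expect_identical(tps_deform_pair(s, c(5, 5), 0, seed = 1), s)
})

test_that("TPS deformation keeps the mask binary and essentially connected", {
  s <- make_sample(64, 64)
  out <- tps_deform_pair(s, c(10, 10), 4, seed = 77)
  expect_true(all(out$mask %in% c(0, 1)))
  lab <- EBImage::bwlabel(out$mask)
  sizes <- table(lab[lab > 0])
  # one dominant component; anything else is a rasterization sliver
  expect_gt(max(sizes) / sum(sizes), 0.98)
})

test_that("HSV jitter model is degenerate on identical images, bounded otherwise", {
  s <- make_sample(24, 24)
  model <- fit_hsv_jitter(list(s, s, s))
  shift <- sample_hsv_shift(model, seed = 2)
  expect_equal(unname(shift), c(0, 0, 0), tolerance = 1e-12)
  # two-image corpus with value means differing by d: shifts bounded by d
  dark <- s; dark$image <- s$image * 0.5
  d <- abs(mean(apply(s$image, 3, mean)) - mean(apply(dark$image, 3, mean)))
  m2 <- fit_hsv_jitter(list(s, dark))
  for (sd_ in 1:20) {
    sh <- sample_hsv_shift(m2, seed = sd_)
    expect_lte(abs(sh[["v"]]), d + 1e-9)
  }
  # all-gray frame stays valid 8-bit RGB (hue undefined)
  gray <- segmentation_sample(array(0.5, c(16, 16, 3)),
                              matrix(0, 16, 16), "s", "f")
  out <- apply_hsv_jitter(gray, m2, seed = 3)
  expect_false(anyNA(out$image))
  expect_true(all(out$image >= 0 & out$image <= 1))
})

test_that("augment_subset honours counts, determinism and ablation configs", {
  corpus <- tiny_corpus(n_seq = 2, frames = 5, hw = c(48, 52))
  spec <- augmentation_spec(target_size = c(48L, 52L), tps_grid = c(5L, 5L),
                            augmented_count_per_subset = 25L, seed = 4)
  aug <- augment_subset(corpus, spec)
  expect_length(aug, 25)
  # every original represented at least once (frame ids carry provenance)
  origin <- sub("_aug.*", "", vapply(aug, function(s) s$frame_id,
                                     character(1)))
  expect_setequal(origin, vapply(corpus, function(s) s$frame_id,
                                 character(1)))
  # sequence ids retained
  expect_true(all(vapply(aug, function(s) s$sequence_id, character(1)) %in%
                    c("seq01", "seq02")))
  # masks binary, shapes exact
  for (s in aug) {
    expect_equal(dim(s$image)[1:2], c(48L, 52L))
    expect_true(all(s$mask %in% c(0, 1)))
  }
  # determinism
  aug2 <- augment_subset(corpus, spec)
  expect_identical(aug[[7]]$image, aug2[[7]]$image)
  # count below originals rejected
  expect_error(augment_subset(corpus, augmentation_spec(
    target_size = c(48L, 52L), augmented_count_per_subset = 5L)),
    "at least")
  # ablation configurations all yield schema-valid corpora
  configs <- list(
    rotation = c(TRUE, FALSE, FALSE, FALSE),
    scale = c(FALSE, TRUE, FALSE, FALSE),
    tps = c(FALSE, FALSE, TRUE, FALSE),
    jitter = c(FALSE, FALSE, FALSE, TRUE),
    combined = c(TRUE, TRUE, TRUE, TRUE),
    none = c(FALSE, FALSE, FALSE, FALSE))
  for (nm in names(configs)) {
    en <- configs[[nm]]
    sp <- augmentation_spec(target_size = c(48L, 52L), tps_grid = c(5L, 5L),
                            enable_rotation = en[1], enable_scale = en[2],
                            enable_tps = en[3], enable_jitter = en[4],
                            augmented_count_per_subset = 12L, seed = 9)
    out <- augment_subset(corpus, sp)
    expect_length(out, 12)
    expect_true(all(vapply(out, function(s) all(s$mask %in% c(0, 1)),
                           logical(1))))
  }
})

test_that("disabling one transform does not perturb the others' draws", {
  corpus <- tiny_corpus(n_seq = 1, frames = 3, hw = c(40, 40))
  geom <- augmentation_spec(target_size = c(40L, 40L), tps_grid = c(4L, 4L),
                            enable_jitter = FALSE,
                            augmented_count_per_subset = 6L, seed = 13)
  with_jit <- geom; with_jit$enable_jitter <- TRUE
  a <- augment_subset(corpus, geom)
  b <- augment_subset(corpus, with_jit)
  # colour jitter leaves geometry alone: the same rotation/scale/TPS draws
  # are used, so the masks coincide exactly
  for (i in seq_along(a)) expect_identical(a[[i]]$mask, b[[i]]$mask)
})

test_that("augmentation spec validation catches bad ranges", {
  expect_error(augmentation_spec(scale_range = c(1.2, 0.8)), "scale_range")
  expect_error(augmentation_spec(tps_grid = c(1L, 5L)), "tps_grid")
  expect_error(augmentation_spec(tps_max_displacement = -1),
               "tps_max_displacement")
  expect_error(fit_hsv_jitter(list()), "at least 1")
})
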