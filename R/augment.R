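# Paired image/mask training augmentation: aspect-preserving rescale with
# random crop, rotation, scaling, thin-plate-spline deformation and
# corpus-statistics HSV jitter. Every geometric transform is applied once
# and shared between the image (bilinear, reflected border) and the mask
# (nearest-neighbour, zero border), so masks stay binary and paired.

#' Specify the augmentation pipeline
#'
#' @param target_size `c(height, width)` common training resolution reached
#'   by aspect-preserving rescale plus random crop.
#' @param rotation_range `c(min, max)` rotation angles in degrees within
#'   `[0, 360)`.
#' @param scale_range `c(min, max)` multiplicative scale factors.
#' @param tps_grid `c(rows, cols)` thin-plate-spline control grid.
#' @param tps_max_displacement maximum per-axis control-point displacement
#'   in pixels.
#' @param enable_rotation,enable_scale,enable_tps,enable_jitter per-transform
#'   switches; disabling all reduces the pipeline to rescale + crop.
#' @param augmented_count_per_subset number of augmented samples produced by
#'   [augment_subset()]; default (`NULL`) is twice the number of originals.
#' @param seed integer seed driving all pipeline randomness.
#' @return An object of class `augmentation_spec`.
#' @export
augmentation_spec <- function(target_size = c(250L, 287L),
                              rotation_range = c(0, 360),
                              scale_range = c(0.8, 1.2),
                              tps_grid = c(10L, 10L),
                              tps_max_displacement = 4,
                              enable_rotation = TRUE,
                              enable_scale = TRUE,
                              enable_tps = TRUE,
                              enable_jitter = TRUE,
                              augmented_count_per_subset = NULL,
                              seed = 1L) {
  check_number(target_size, "target_size", lower = 8, len = 2L, integer = TRUE)
  check_number(rotation_range, "rotation_range", lower = 0, upper = 360,
               len = 2L)
  check_number(scale_range, "scale_range", len = 2L)
  if (scale_range[1] <= 0 || scale_range[1] >= scale_range[2])
    stop_param("scale_range must satisfy 0 < min < max")
  check_number(tps_grid, "tps_grid", lower = 2, len = 2L, integer = TRUE)
  check_number(tps_max_displacement, "tps_max_displacement", lower = 0)
  if (!is.null(augmented_count_per_subset))
    check_number(augmented_count_per_subset, "augmented_count_per_subset",
                 lower = 1, integer = TRUE)
  structure(
    list(target_size = as.integer(target_size),
         rotation_range = rotation_range,
         scale_range = scale_range,
         tps_grid = as.integer(tps_grid),
         tps_max_displacement = tps_max_displacement,
         enable_rotation = isTRUE(enable_rotation),
         enable_scale = isTRUE(enable_scale),
         enable_tps = isTRUE(enable_tps),
         enable_jitter = isTRUE(enable_jitter),
         augmented_count_per_subset = augmented_count_per_subset,
         seed = as.integer(seed)),
    class = "augmentation_spec")
}

# Shared warping core: src coordinates are 0-based maps over the output
# grid. Image sampled bilinearly with reflected border; mask
# nearest-neighbour with zero (background) fill.
warp_pair <- function(sample, map_y, map_x) {
  img <- cpp_remap(sample$image, map_y, map_x, TRUE, 1L, 0)
  msk <- cpp_remap(array(sample$mask, c(dim(sample$mask), 1L)),
                   map_y, map_x, FALSE, 0L, 0)[, , 1]
  segmentation_sample(img, msk, sample$sequence_id, sample$frame_id)
}

#' Aspect-preserving rescale to a common size with (random) crop
#'
#' The image is scaled isotropically by the smallest factor that makes both
#' dimensions at least the target, then the residual extent is removed by a
#' crop whose offset is drawn uniformly (translation augmentation); with
#' `random = FALSE` the crop is centered (the deterministic variant used at
#' validation time). The mask travels through the identical transform with
#' nearest-neighbour sampling.
#'
#' @param sample a [segmentation_sample].
#' @param target_size `c(height, width)`.
#' @param seed integer seed for the crop offset.
#' @param random logical; `FALSE` gives a centered crop.
#' @return A [segmentation_sample] of exactly `target_size`.
#' @export
rescale_and_crop <- function(sample, target_size = c(250L, 287L),
                             seed = NULL, random = TRUE) {
  d <- dim(sample$image)
  th <- target_size[1]; tw <- target_size[2]
  f <- max(th / d[1], tw / d[2])
  sh <- max(th, round(d[1] * f))
  sw <- max(tw, round(d[2] * f))
  with_seed(seed, {
    oy <- if (random) sample.int(sh - th + 1L, 1L) - 1L
          else (sh - th) %/% 2L
    ox <- if (random) sample.int(sw - tw + 1L, 1L) - 1L
          else (sw - tw) %/% 2L
    # map output pixel (0-based) through crop then inverse scaling
    ys <- (((0:(th - 1)) + oy) + 0.5) * d[1] / sh - 0.5
    xs <- (((0:(tw - 1)) + ox) + 0.5) * d[2] / sw - 0.5
    warp_pair(sample, matrix(ys, th, tw), matrix(xs, th, tw, byrow = TRUE))
  })
}

rotation_maps <- function(h, w, angle_deg) {
  a <- angle_deg * pi / 180
  cy <- (h - 1) / 2; cx <- (w - 1) / 2
  yy <- matrix(0:(h - 1), h, w) - cy
  xx <- matrix(0:(w - 1), h, w, byrow = TRUE) - cx
  # inverse rotation: output pixel pulled from source rotated by -angle
  list(y = cy + (-sin(-a)) * xx + cos(-a) * yy,
       x = cx + cos(-a) * xx + sin(-a) * yy)
}

# Exact right-angle rotation of a square H x H array by k*90 degrees
# (counter-clockwise in the row/col sense used throughout).
rot90_exact <- function(x, k) {
  k <- ((k %% 4) + 4) %% 4
  if (k == 0) return(x)
  perm3 <- function(a) {
    if (length(dim(a)) == 2L) a <- array(a, c(dim(a), 1L))
    a
  }
  a <- perm3(x)
  for (i in seq_len(k)) {
    n <- dim(a)[1]
    a <- aperm(a, c(2, 1, 3))[n:1, , , drop = FALSE]
  }
  if (length(dim(x)) == 2L) a[, , 1] else a
}

#' Rotate an image/mask pair about the frame center
#'
#' Bilinear resampling with reflected border for the image; the identical
#' rotation with nearest-neighbour sampling and zero fill for the mask.
#' Output size is unchanged. Square frames rotated by multiples of 90
#' degrees use exact index permutations.
#'
#' @param sample a [segmentation_sample].
#' @param angle rotation angle in degrees.
#' @return A [segmentation_sample].
#' @export
rotate_pair <- function(sample, angle) {
  angle <- angle %% 360
  if (angle == 0) return(sample)
  d <- dim(sample$image)
  if (d[1] == d[2] && angle %% 90 == 0) {
    k <- as.integer(angle / 90)
    return(segmentation_sample(rot90_exact(sample$image, k),
                               rot90_exact(sample$mask, k),
                               sample$sequence_id, sample$frame_id))
  }
  m <- rotation_maps(d[1], d[2], angle)
  warp_pair(sample, m$y, m$x)
}

#' Scale an image/mask pair about the frame center
#'
#' Zooms by `factor` keeping the canvas size; content moving out of frame is
#' lost, content moving in is reflected (image) or background (mask).
#'
#' @param sample a [segmentation_sample].
#' @param factor scale factor (> 0).
#' @return A [segmentation_sample].
#' @export
scale_pair <- function(sample, factor) {
  check_number(factor, "factor", lower = 1e-6)
  if (factor == 1) return(sample)
  d <- dim(sample$image)
  cy <- (d[1] - 1) / 2; cx <- (d[2] - 1) / 2
  ys <- cy + ((0:(d[1] - 1)) - cy) / factor
  xs <- cx + ((0:(d[2] - 1)) - cx) / factor
  warp_pair(sample, matrix(ys, d[1], d[2]),
            matrix(xs, d[1], d[2], byrow = TRUE))
}

tps_kernel <- function(d2) ifelse(d2 > 0, 0.5 * d2 * log(d2), 0)

tps_fit <- function(points, values) {
  n <- nrow(points)
  d2 <- as.matrix(stats::dist(points))^2
  K <- tps_kernel(d2)
  P <- cbind(1, points)
  A <- rbind(cbind(K, P), cbind(t(P), matrix(0, 3, 3)))
  rhs <- c(values, rep(0, 3))
  coef <- solve(A, rhs)
  list(w = coef[seq_len(n)], a = coef[n + 1:3], points = points)
}

tps_eval <- function(fit, query, chunk = 20000L) {
  out <- numeric(nrow(query))
  for (start in seq(1L, nrow(query), by = chunk)) {
    idx <- start:min(start + chunk - 1L, nrow(query))
    q <- query[idx, , drop = FALSE]
    d2 <- outer(q[, 1], fit$points[, 1], "-")^2 +
      outer(q[, 2], fit$points[, 2], "-")^2
    out[idx] <- drop(tps_kernel(d2) %*% fit$w) +
      fit$a[1] + fit$a[2] * q[, 1] + fit$a[3] * q[, 2]
  }
  out
}

#' Thin-plate-spline displacement field
#'
#' Places a regular `grid` of control points over an `size[1] x size[2]`
#' canvas, displaces each by a uniform random vector with per-axis magnitude
#' at most `max_displacement`, and interpolates the displacements with a
#' thin-plate spline evaluated at every pixel.
#'
#' @param size `c(height, width)`.
#' @param grid `c(rows, cols)` control grid.
#' @param max_displacement maximum per-axis displacement in pixels.
#' @param seed integer seed.
#' @return List with `dy`, `dx` (H x W displacement matrices), `control`
#'   (control-point coordinates) and `disp` (their displacements).
#' @export
tps_displacement_field <- function(size, grid = c(10L, 10L),
                                   max_displacement = 4, seed = NULL) {
  check_number(grid, "grid", lower = 2, len = 2L, integer = TRUE)
  check_number(max_displacement, "max_displacement", lower = 0)
  h <- size[1]; w <- size[2]
  gy <- seq(0, h - 1, length.out = grid[1])
  gx <- seq(0, w - 1, length.out = grid[2])
  control <- as.matrix(expand.grid(y = gy, x = gx))
  n <- nrow(control)
  disp <- with_seed(seed, matrix(runif(2 * n, -max_displacement,
                                       max_displacement), n, 2))
  if (max_displacement == 0)
    return(list(dy = matrix(0, h, w), dx = matrix(0, h, w),
                control = control, disp = disp))
  query <- as.matrix(expand.grid(y = 0:(h - 1), x = 0:(w - 1)))
  fy <- tps_fit(control, disp[, 1])
  fx <- tps_fit(control, disp[, 2])
  list(dy = matrix(tps_eval(fy, query), h, w),
       dx = matrix(tps_eval(fx, query), h, w),
       control = control, disp = disp)
}

#' Thin-plate-spline deformation of an image/mask pair
#'
#' @param sample a [segmentation_sample].
#' @param grid `c(rows, cols)` control grid (default 10 x 10).
#' @param max_displacement maximum per-axis control displacement in pixels
#'   (default 4).
#' @param seed integer seed.
#' @return A [segmentation_sample].
#' @export
tps_deform_pair <- function(sample, grid = c(10L, 10L),
                            max_displacement = 4, seed = NULL) {
  if (max_displacement == 0) return(sample)
  d <- dim(sample$image)
  fld <- tps_displacement_field(d[1:2], grid, max_displacement, seed)
  yy <- matrix(0:(d[1] - 1), d[1], d[2])
  xx <- matrix(0:(d[2] - 1), d[1], d[2], byrow = TRUE)
  warp_pair(sample, yy + fld$dy, xx + fld$dx)
}

#' Fit the HSV colour-jitter model from a training corpus
#'
#' Computes each image's mean hue, saturation and value and stores their
#' deviations from the corpus means. Jitter shifts are later drawn by
#' resampling these observed deviations, so sampled shifts always stay
#' within the support seen in the corpus, and a corpus of identical images
#' yields a degenerate (all-zero) shift distribution.
#'
#' @param corpus non-empty list of [segmentation_sample] objects.
#' @return An object of class `hsv_jitter_model`.
#' @export
fit_hsv_jitter <- function(corpus) {
  if (length(corpus) == 0) stop_param("corpus must contain at least 1 image")
  stats <- t(vapply(corpus, function(s) {
    m <- matrix(aperm(s$image, c(3, 1, 2)), nrow = 3)
    hsv <- rgb2hsv(m, maxColorValue = 1)
    # circular mean for hue
    hm <- atan2(mean(sin(2 * pi * hsv[1, ])),
                mean(cos(2 * pi * hsv[1, ]))) / (2 * pi)
    c(h = hm %% 1, s = mean(hsv[2, ]), v = mean(hsv[3, ]))
  }, numeric(3)))
  circ_diff <- function(a, b) {
    d <- (a - b) %% 1
    ifelse(d > 0.5, d - 1, d)
  }
  hm <- atan2(mean(sin(2 * pi * stats[, "h"])),
              mean(cos(2 * pi * stats[, "h"]))) / (2 * pi)
  structure(
    list(dev = cbind(h = circ_diff(stats[, "h"], hm %% 1),
                     s = stats[, "s"] - mean(stats[, "s"]),
                     v = stats[, "v"] - mean(stats[, "v"])),
         n = length(corpus)),
    class = "hsv_jitter_model")
}

#' Sample one HSV shift from a fitted jitter model
#'
#' @param model an [fit_hsv_jitter()] model.
#' @param seed integer seed.
#' @return Named numeric vector `c(h, s, v)`.
#' @export
sample_hsv_shift <- function(model, seed = NULL) {
  stopifnot(inherits(model, "hsv_jitter_model"))
  with_seed(seed, {
    i <- sample.int(nrow(model$dev), 1L)
    c(h = unname(model$dev[i, "h"]), s = unname(model$dev[i, "s"]),
      v = unname(model$dev[i, "v"]))
  })
}

#' Apply HSV colour jitter to a sample
#'
#' Hue shifts wrap around the colour circle; saturation and value shifts are
#' clamped to `[0, 1]`. The mask is untouched. Grey pixels (undefined hue)
#' remain valid 8-bit RGB.
#'
#' @param sample a [segmentation_sample].
#' @param model an [fit_hsv_jitter()] model.
#' @param seed integer seed for the shift draw.
#' @return A [segmentation_sample].
#' @export
apply_hsv_jitter <- function(sample, model, seed = NULL) {
  shift <- sample_hsv_shift(model, seed)
  d <- dim(sample$image)
  m <- matrix(aperm(sample$image, c(3, 1, 2)), nrow = 3)
  hsv <- rgb2hsv(m, maxColorValue = 1)
  rgb <- hsv_to_rgb((hsv[1, ] + shift["h"]) %% 1,
                    clamp(hsv[2, ] + shift["s"], 0, 1),
                    clamp(hsv[3, ] + shift["v"], 0, 1))
  img <- aperm(array(rbind(rgb$r, rgb$g, rgb$b), c(3, d[1], d[2])),
               c(2, 3, 1))
  segmentation_sample(quantize8(img), sample$mask,
                      sample$sequence_id, sample$frame_id)
}

#' Build an augmented training subset
#'
#' Each output sample is produced by aspect-preserving rescale + random
#' crop followed by an independently sampled composition of the enabled
#' transforms, in the order rotation, scale, thin-plate-spline deformation,
#' HSV jitter. Originals are represented as evenly as possible (each at
#' least once); the sequence identifier is retained on every augmented
#' frame. Fully deterministic given `spec$seed`.
#'
#' @param samples non-empty list of [segmentation_sample] objects.
#' @param spec an [augmentation_spec()].
#' @return List of `augmented_count_per_subset` samples at `target_size`.
#' @export
augment_subset <- function(samples, spec) {
  stopifnot(inherits(spec, "augmentation_spec"))
  n <- length(samples)
  if (n == 0) stop_param("samples must be non-empty")
  n_out <- spec$augmented_count_per_subset
  if (is.null(n_out)) n_out <- 2L * n
  if (n_out < n)
    stop_param("augmented_count_per_subset (", n_out,
               ") must be at least the number of originals (", n, ")")
  model <- if (spec$enable_jitter) fit_hsv_jitter(samples) else NULL
  origin <- rep(seq_len(n), length.out = n_out)
  out <- vector("list", n_out)
  for (i in seq_len(n_out)) {
    s0 <- samples[[origin[i]]]
    sd_i <- derive_seed(spec$seed, i)
    s <- rescale_and_crop(s0, spec$target_size, seed = sd_i)
    draws <- with_seed(derive_seed(spec$seed, i + n_out), {
      list(angle = runif(1, spec$rotation_range[1], spec$rotation_range[2]),
           scale = runif(1, spec$scale_range[1], spec$scale_range[2]),
           tps_seed = sample.int(2^30, 1),
           jitter_seed = sample.int(2^30, 1))
    })
    if (spec$enable_rotation) s <- rotate_pair(s, draws$angle)
    if (spec$enable_scale) s <- scale_pair(s, draws$scale)
    if (spec$enable_tps)
      s <- tps_deform_pair(s, spec$tps_grid, spec$tps_max_displacement,
                           seed = draws$tps_seed)
    if (spec$enable_jitter)
      s <- apply_hsv_jitter(s, model, seed = draws$jitter_seed)
    s$frame_id <- sprintf("%s_aug%04d", s0$frame_id, i)
    out[[i]] <- s
  }
  out
}
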