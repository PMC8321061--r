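# Inference: forward pass to a polyp-probability map, optional rotation
# test-time augmentation (24 views at 15-degree steps by default, outputs
# averaged back in the original frame), and threshold + morphological
# opening + hole-filling post-processing to a binary mask.

new_probability_map <- function(m, tta = FALSE, n_views = 1L) {
  structure(m, tta = tta, n_views = as.integer(n_views),
            class = c("probability_map", "matrix", "array"))
}

#' Polyp probability map from a predictor
#'
#' Generic over predictors: for a `dresfcn` network the two-class fused
#' score map is passed through a per-pixel softmax and the polyp-class
#' plane is returned; a plain function is treated as a dummy predictor
#' mapping an image to an `H x W` probability matrix (useful for testing).
#'
#' @param object a `dresfcn` network or a `function(image) -> matrix`.
#' @param image `H x W x 3` array with values in `[0, 1]`.
#' @param ... unused.
#' @return A `probability_map` (`H x W` matrix in `[0, 1]`).
#' @export
predict_probability <- function(object, image, ...) {
  UseMethod("predict_probability")
}

#' @export
predict_probability.dresfcn <- function(object, image, ...) {
  fwd <- network_forward(object, image, train = FALSE)
  z <- fwd$scores
  # stable softmax, polyp class = plane 2
  p <- 1 / (1 + exp(z[, , 1] - z[, , 2]))
  new_probability_map(p)
}

#' @export
predict_probability.function <- function(object, image, ...) {
  p <- object(image)
  stopifnot(is.matrix(p), all(dim(p) == dim(image)[1:2]))
  new_probability_map(p)
}

#' Specify rotation test-time augmentation
#'
#' @param angle_step degrees between views; must divide 360. The default 15
#'   gives 24 views.
#' @param aggregation `"binary_mean"` (each view thresholded at
#'   `view_threshold` before averaging; the aggregated map lives on the
#'   lattice `{0, 1/n, ..., 1}`) or `"probability_mean"` (average of raw
#'   probabilities; the identity for a single view).
#' @param view_threshold threshold used by `binary_mean`.
#' @return An object of class `tta_spec`.
#' @export
tta_spec <- function(angle_step = 15,
                     aggregation = c("binary_mean", "probability_mean"),
                     view_threshold = 0.5) {
  check_number(angle_step, "angle_step", lower = 1e-9, upper = 360)
  if (360 %% angle_step != 0)
    stop_param("angle_step must divide 360")
  aggregation <- match.arg(aggregation)
  check_number(view_threshold, "view_threshold", lower = 0, upper = 1)
  structure(list(angle_step = angle_step, aggregation = aggregation,
                 view_threshold = view_threshold,
                 n_views = as.integer(360 / angle_step)),
            class = "tta_spec")
}

# Rotate a single matrix by `angle` degrees about its center; exact index
# permutation for square inputs at right angles.
rotate_matrix <- function(m, angle, bilinear = TRUE, fill = 0) {
  angle <- angle %% 360
  if (angle == 0) return(m)
  d <- dim(m)
  if (d[1] == d[2] && angle %% 90 == 0)
    return(rot90_exact(m, as.integer(angle / 90)))
  maps <- rotation_maps(d[1], d[2], angle)
  cpp_remap(array(m, c(d, 1L)), maps$y, maps$x, bilinear, 0L, fill)[, , 1]
}

pad_reflect_image <- function(image, top, bottom, left, right) {
  d <- dim(image)
  ridx <- function(n, pre, post) {
    idx <- c(rev(seq_len(pre) + 1L), seq_len(n), n - seq_len(post))
    clamp(idx, 1L, n)
  }
  image[ridx(d[1], top, bottom), ridx(d[2], left, right), , drop = FALSE]
}

#' Predict with rotation test-time augmentation
#'
#' The frame is padded to its enclosing square (reflected tissue for the
#' image), rotated to each view angle, segmented, and each output is
#' rotated back into the original frame. Per-pixel aggregation divides by
#' the number of views whose valid (non-padded) region covers that pixel.
#' A single view (`angle_step = 360`) with `probability_mean` aggregation
#' is identical to [predict_probability()].
#'
#' @param object a `dresfcn` network or dummy predictor function.
#' @param image `H x W x 3` array.
#' @param tta a [tta_spec()].
#' @return A `probability_map` with attributes `tta = TRUE` and `n_views`.
#' @export
predict_tta <- function(object, image, tta = tta_spec()) {
  stopifnot(inherits(tta, "tta_spec"))
  d <- dim(image)
  angles <- seq(0, 360 - tta$angle_step, by = tta$angle_step)
  if (length(angles) == 1L) {
    p <- predict_probability(object, image)
    if (tta$aggregation == "binary_mean")
      p[] <- (p >= tta$view_threshold) * 1
    return(new_probability_map(as.matrix(unclass(p)), tta = TRUE,
                               n_views = 1L))
  }
  S <- max(d[1], d[2])
  top <- (S - d[1]) %/% 2L; bottom <- S - d[1] - top
  left <- (S - d[2]) %/% 2L; right <- S - d[2] - left
  padded <- pad_reflect_image(image, top, bottom, left, right)
  valid0 <- matrix(0, S, S)
  valid0[top + seq_len(d[1]), left + seq_len(d[2])] <- 1
  acc <- matrix(0, d[1], d[2])
  cov <- matrix(0, d[1], d[2])
  for (a in angles) {
    img_rot <- if (a == 0) padded else {
      if (a %% 90 == 0) rot90_exact(padded, as.integer(a / 90)) else {
        maps <- rotation_maps(S, S, a)
        cpp_remap(padded, maps$y, maps$x, TRUE, 1L, 0)
      }
    }
    v_rot <- rotate_matrix(valid0, a, bilinear = FALSE)
    p <- as.matrix(unclass(predict_probability(object, img_rot)))
    p_back <- rotate_matrix(p, -a, bilinear = TRUE, fill = 0)
    v_back <- rotate_matrix(v_rot, -a, bilinear = FALSE)
    p_crop <- p_back[top + seq_len(d[1]), left + seq_len(d[2])]
    v_crop <- v_back[top + seq_len(d[1]), left + seq_len(d[2])]
    if (tta$aggregation == "binary_mean")
      p_crop <- (p_crop >= tta$view_threshold) * 1
    acc <- acc + p_crop * v_crop
    cov <- cov + v_crop
  }
  out <- ifelse(cov > 0, acc / pmax(cov, 1), 0)
  new_probability_map(clamp(out, 0, 1), tta = TRUE,
                      n_views = length(angles))
}

#' Specify binarization post-processing
#'
#' @param threshold probability threshold in `(0, 1)`.
#' @param opening_radius radius (pixels) of the disc structuring element of
#'   the morphological opening; 0 disables opening. The default 2 is sized
#'   for 250 x 287 frames; scale proportionally for other resolutions.
#' @param fill_holes fill enclosed background holes.
#' @return An object of class `postprocess_spec`.
#' @export
postprocess_spec <- function(threshold = 0.5, opening_radius = 2L,
                             fill_holes = TRUE) {
  check_number(threshold, "threshold")
  if (threshold <= 0 || threshold >= 1)
    stop_param("threshold must be in (0, 1)")
  check_number(opening_radius, "opening_radius", lower = 0, integer = TRUE)
  structure(list(threshold = threshold,
                 opening_radius = as.integer(opening_radius),
                 fill_holes = isTRUE(fill_holes)),
            class = "postprocess_spec")
}

#' Binarize a probability map
#'
#' Thresholds the map, removes small speckle with a morphological opening
#' (disc structuring element) and optionally fills enclosed holes. The
#' operation is idempotent: applying it to its own output returns the same
#' mask.
#'
#' @param pmap `H x W` probability matrix (a `probability_map` or plain
#'   matrix).
#' @param spec a [postprocess_spec()].
#' @return `H x W` binary (0/1) matrix.
#' @export
postprocess <- function(pmap, spec = postprocess_spec()) {
  stopifnot(inherits(spec, "postprocess_spec"))
  bw <- (as.matrix(unclass(pmap)) >= spec$threshold) * 1
  if (spec$opening_radius > 0 && any(bw > 0)) {
    brush <- EBImage::makeBrush(2L * spec$opening_radius + 1L, "disc")
    bw <- EBImage::imageData(EBImage::opening(bw, brush)) * 1
  }
  if (spec$fill_holes && any(bw > 0))
    bw <- EBImage::imageData(EBImage::fillHull(bw)) * 1
  matrix(as.numeric(bw > 0.5), nrow(bw), ncol(bw))
}

#' Segment an image with a trained network
#'
#' Convenience wrapper: probability map (optionally with rotation
#' test-time augmentation) followed by binarization.
#'
#' @param object a `dresfcn` network.
#' @param image `H x W x 3` array.
#' @param tta optional [tta_spec()]; `NULL` disables test-time augmentation.
#' @param post a [postprocess_spec()].
#' @param ... unused.
#' @return List with `probability` (probability_map) and `mask` (binary
#'   matrix).
#' @export
predict.dresfcn <- function(object, image, tta = NULL,
                            post = postprocess_spec(), ...) {
  pm <- if (is.null(tta)) predict_probability(object, image)
        else predict_tta(object, image, tta)
  list(probability = pm, mask = postprocess(pm, post))
}
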