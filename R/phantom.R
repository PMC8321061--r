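# Seeded colonoscopy-like phantom generator. Frames show a single smooth
# protruding blob (the "polyp") on a textured mucosa-like background with
# multiplicative vignetting, optional saturated specular highlights and
# additive Gaussian noise - the confounders that make real endoscopy frames
# hard - without any claim of photorealism. Frames are grouped into
# "videos": all frames of a sequence share one polyp identity (size, shape,
# colour) and differ by pose and illumination, mirroring how consecutive
# colonoscopy frames are correlated.

#' Specify a phantom corpus
#'
#' Defaults emulate the structure of the standard-definition training
#' corpus the segmentation study was built on: 15 video sequences with 20
#' frames each (300 frames), one polyp per frame, rendered at the 250 x 287
#' training resolution.
#'
#' @param image_height,image_width canvas size in pixels.
#' @param n_sequences number of simulated video sequences.
#' @param frames_per_sequence frames per sequence.
#' @param polyp_radius_range `c(min, max)` nominal polyp radius in pixels;
#'   radii are drawn log-uniformly so the quartile-based size strata are
#'   populated.
#' @param eccentricity_range `c(min, max)` in `[0, 1)`: 0 gives a circular
#'   blob, larger values an elongated one (area-preserving ellipse).
#' @param roughness_range `c(min, max)` boundary roughness in `[0, 1]`;
#'   larger values give more irregular, less circular outlines.
#' @param highlight_count_range `c(min, max)` specular highlights per frame.
#' @param vignette_strength multiplicative corner darkening in `[0, 1]`.
#' @param noise_sigma additive Gaussian noise standard deviation on the
#'   `[0, 1]` intensity scale.
#' @param seed integer seed; the (spec, seed) pair fully determines the
#'   corpus, bit for bit.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(image_height = 250L, image_width = 287L,
                         n_sequences = 15L, frames_per_sequence = 20L,
                         polyp_radius_range = c(18, 60),
                         eccentricity_range = c(0, 0.6),
                         roughness_range = c(0, 0.5),
                         highlight_count_range = c(0L, 3L),
                         vignette_strength = 0.3,
                         noise_sigma = 0.015,
                         seed = 1L) {
  check_number(image_height, "image_height", lower = 32, integer = TRUE)
  check_number(image_width, "image_width", lower = 32, integer = TRUE)
  check_number(n_sequences, "n_sequences", lower = 1, integer = TRUE)
  check_number(frames_per_sequence, "frames_per_sequence", lower = 1,
               integer = TRUE)
  check_number(polyp_radius_range, "polyp_radius_range", lower = 3, len = 2L)
  check_number(eccentricity_range, "eccentricity_range", lower = 0,
               upper = 0.95, len = 2L)
  check_number(roughness_range, "roughness_range", lower = 0, upper = 1,
               len = 2L)
  check_number(highlight_count_range, "highlight_count_range", lower = 0,
               len = 2L, integer = TRUE)
  check_number(vignette_strength, "vignette_strength", lower = 0, upper = 1)
  check_number(noise_sigma, "noise_sigma", lower = 0)
  for (nm in c("polyp_radius_range", "eccentricity_range", "roughness_range",
               "highlight_count_range")) {
    rg <- get(nm)
    if (rg[1] > rg[2]) stop_param(nm, ": min must not exceed max")
  }
  structure(
    list(image_height = as.integer(image_height),
         image_width = as.integer(image_width),
         n_sequences = as.integer(n_sequences),
         frames_per_sequence = as.integer(frames_per_sequence),
         polyp_radius_range = polyp_radius_range,
         eccentricity_range = eccentricity_range,
         roughness_range = roughness_range,
         highlight_count_range = as.integer(highlight_count_range),
         vignette_strength = vignette_strength,
         noise_sigma = noise_sigma,
         seed = as.integer(seed)),
    class = "phantom_spec")
}

# Radial boundary function of a blob: an area-preserving ellipse modulated
# by a band-limited harmonic perturbation. `theta` in radians; returns the
# boundary radius at each angle.
blob_radius_fun <- function(radius, eccentricity, roughness, harmonics) {
  s <- (1 - eccentricity^2)^(1 / 4)
  a <- radius / s
  b <- radius * s
  amp <- 0.3 * roughness
  function(theta) {
    th <- theta - harmonics$orientation
    re <- a * b / sqrt((b * cos(th))^2 + (a * sin(th))^2)
    pert <- rep(0, length(theta))
    for (i in seq_along(harmonics$order))
      pert <- pert + harmonics$coef[i] *
        cos(harmonics$order[i] * theta + harmonics$phase[i])
    re * (1 + amp * pert)
  }
}

sample_harmonics <- function() {
  order <- 2:5
  coef <- abs(rnorm(length(order)))
  coef <- coef / sum(coef)  # sup of the perturbation is at most 1
  list(order = order, coef = coef, phase = runif(length(order), 0, 2 * pi),
       orientation = runif(1, 0, pi))
}

rasterize_blob <- function(height, width, center, rfun) {
  yy <- matrix(seq_len(height), height, width)
  xx <- matrix(seq_len(width), height, width, byrow = TRUE)
  dy <- yy - center[1]
  dx <- xx - center[2]
  rho <- sqrt(dy * dy + dx * dx)
  theta <- atan2(dy, dx)
  (rho <= rfun(theta)) * 1L
}

#' Generate a single polyp-shaped binary mask
#'
#' The blob is star-convex (a perturbed area-preserving ellipse in polar
#' form), so the rasterized mask is one connected component. Circularity
#' decreases monotonically as `eccentricity` or `boundary_roughness`
#' increases; area scales as the square of `radius`.
#'
#' @param radius nominal radius in pixels (>= 3).
#' @param eccentricity ellipse eccentricity in `[0, 1)`.
#' @param boundary_roughness boundary perturbation strength in `[0, 1]`.
#' @param seed integer seed for the harmonic perturbation.
#' @param height,width canvas size; defaults to a canvas that fits the blob.
#' @param center `c(row, col)` blob center; defaults to the canvas center.
#' @return `height x width` binary matrix.
#' @export
generate_polyp_mask <- function(radius, eccentricity = 0,
                                boundary_roughness = 0, seed = 1L,
                                height = NULL, width = NULL, center = NULL) {
  check_number(radius, "radius", lower = 3)
  check_number(eccentricity, "eccentricity", lower = 0, upper = 0.95)
  check_number(boundary_roughness, "boundary_roughness", lower = 0, upper = 1)
  rmax <- ceiling(radius / (1 - eccentricity^2)^(1 / 4) *
                    (1 + 0.3 * boundary_roughness)) + 2
  if (is.null(height)) height <- 2L * rmax + 5L
  if (is.null(width)) width <- 2L * rmax + 5L
  if (is.null(center)) center <- c((height + 1) / 2, (width + 1) / 2)
  if (2 * rmax + 1 > min(height, width))
    stop_param("radius too large for a ", height, " x ", width, " grid")
  with_seed(seed, {
    h <- sample_harmonics()
    rasterize_blob(height, width, center, blob_radius_fun(
      radius, eccentricity, boundary_roughness, h))
  })
}

# Low-frequency multiplicative texture field, coarse Gaussian grid
# upsampled bilinearly.
texture_field <- function(height, width, cells = c(10L, 12L), amp = 0.08) {
  g <- array(rnorm(cells[1] * cells[2]), c(cells[1], cells[2], 1L))
  1 + amp * cpp_resize_bilinear(g, height, width)[, , 1]
}

render_phantom_frame <- function(spec, identity, frame_seed) {
  with_seed(frame_seed, {
    H <- spec$image_height; W <- spec$image_width
    center <- identity$center + rnorm(2, 0, 5)
    center[1] <- clamp(center[1], identity$margin, H - identity$margin + 1)
    center[2] <- clamp(center[2], identity$margin, W - identity$margin + 1)
    rfun <- blob_radius_fun(identity$radius, identity$eccentricity,
                            identity$roughness, identity$harmonics)
    yy <- matrix(seq_len(H), H, W)
    xx <- matrix(seq_len(W), H, W, byrow = TRUE)
    dy <- yy - center[1]; dx <- xx - center[2]
    rho <- sqrt(dy * dy + dx * dx)
    theta <- atan2(dy, dx)
    rb <- rfun(theta)
    mask <- (rho <= rb) * 1L

    gain <- 1 + rnorm(1, 0, 0.05)
    img <- array(0, c(H, W, 3))
    tex <- texture_field(H, W)
    # dome-like interior shading of the polyp
    d01 <- pmin(rho / pmax(rb, 1e-9), 1)
    shade <- 1 - 0.35 * d01^2
    for (c in 1:3) {
      bg <- identity$bg_color[c] * tex * gain
      fg <- identity$polyp_color[c] * shade * gain
      img[, , c] <- bg * (1 - mask) + fg * mask
    }

    n_high <- if (spec$highlight_count_range[2] > 0)
      sample(spec$highlight_count_range[1]:spec$highlight_count_range[2], 1)
    else 0L
    if (n_high > 0 && sum(mask) > 0) {
      inside <- which(mask == 1)
      for (i in seq_len(n_high)) {
        pos <- inside[sample.int(length(inside), 1)]
        py <- (pos - 1) %% H + 1
        px <- (pos - 1) %/% H + 1
        ry <- runif(1, 1.5, 4); rx <- runif(1, 1.5, 4)
        spot <- ((yy - py) / ry)^2 + ((xx - px) / rx)^2 <= 1
        for (c in 1:3) {
          plane <- img[, , c]
          plane[spot] <- 0.98
          img[, , c] <- plane
        }
      }
    }

    if (spec$vignette_strength > 0) {
      cy <- (H + 1) / 2; cx <- (W + 1) / 2
      r2 <- ((yy - cy) / (H / 2))^2 + ((xx - cx) / (W / 2))^2
      vig <- 1 - spec$vignette_strength * r2 / 2
      for (c in 1:3) img[, , c] <- img[, , c] * vig
    }

    if (spec$noise_sigma > 0)
      img <- img + array(rnorm(length(img), 0, spec$noise_sigma), dim(img))

    list(image = quantize8(img), mask = mask)
  })
}

#' Generate a phantom corpus
#'
#' Produces `n_sequences * frames_per_sequence` samples. All frames of a
#' sequence share one polyp identity (radius, eccentricity, roughness,
#' colour) and differ in pose and illumination; identical (spec, seed)
#' pairs reproduce the corpus bit for bit.
#'
#' @param spec a [phantom_spec()].
#' @return List of [segmentation_sample] objects.
#' @export
generate_corpus <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  H <- spec$image_height; W <- spec$image_width
  samples <- vector("list", spec$n_sequences * spec$frames_per_sequence)
  idx <- 1L
  for (s in seq_len(spec$n_sequences)) {
    identity <- with_seed(derive_seed(spec$seed, s), {
      rr <- spec$polyp_radius_range
      radius <- exp(runif(1, log(rr[1]), log(rr[2])))
      ecc <- runif(1, spec$eccentricity_range[1], spec$eccentricity_range[2])
      rough <- runif(1, spec$roughness_range[1], spec$roughness_range[2])
      margin <- ceiling(radius / (1 - ecc^2)^(1 / 4) * (1 + 0.3 * rough)) + 8
      if (2 * margin >= min(H, W))
        stop_param("polyp_radius_range too large for the canvas")
      list(radius = radius, eccentricity = ecc, roughness = rough,
           harmonics = sample_harmonics(),
           margin = margin,
           center = c(runif(1, margin, H - margin + 1),
                      runif(1, margin, W - margin + 1)),
           polyp_color = c(runif(1, 0.78, 0.92), runif(1, 0.42, 0.55),
                           runif(1, 0.32, 0.45)),
           bg_color = c(runif(1, 0.55, 0.68), runif(1, 0.28, 0.38),
                        runif(1, 0.24, 0.34)))
    })
    for (f in seq_len(spec$frames_per_sequence)) {
      fr <- render_phantom_frame(
        spec, identity, derive_seed(spec$seed, s * 1000L + f))
      samples[[idx]] <- segmentation_sample(
        fr$image, fr$mask,
        sequence_id = sprintf("seq%02d", s),
        frame_id = sprintf("seq%02d_f%03d", s, f))
      idx <- idx + 1L
    }
  }
  samples
}
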