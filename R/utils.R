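#' Evaluate an expression with a temporary RNG seed
#'
#' Runs `expr` under `set.seed(seed)` and restores the caller's RNG state
#' afterwards, so seeded components never perturb global randomness.
#'
#' @param seed integer seed; `NULL` runs `expr` under the current RNG state.
#' @param expr expression to evaluate.
#' @return The value of `expr`.
#' @export
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a child seed from a base seed and a stream index, staying within
# the 32-bit integer range.
derive_seed <- function(seed, index) {
  as.integer((as.double(seed) * 48271 + as.double(index) * 16807) %% 2147483647L)
}

stop_param <- function(...) {
  stop(paste0(...), call. = FALSE)
}

check_number <- function(x, name, lower = -Inf, upper = Inf, len = 1L,
                         integer = FALSE) {
  if (!is.numeric(x) || length(x) != len || anyNA(x))
    stop_param(name, " must be numeric of length ", len)
  if (any(x < lower) || any(x > upper))
    stop_param(name, " must lie in [", lower, ", ", upper, "]")
  if (integer && any(x != round(x)))
    stop_param(name, " must be integer-valued")
  invisible(x)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Construct a segmentation sample
#'
#' Bundles one RGB frame with its binary ground-truth mask and the video
#' sequence it was extracted from. Images are `H x W x 3` arrays with values
#' in `[0, 1]` (8-bit quantized on disk); masks are `H x W` matrices with
#' values in `{0, 1}`.
#'
#' @param image `H x W x 3` numeric array, values in `[0, 1]`.
#' @param mask `H x W` matrix with values 0/1.
#' @param sequence_id identifier of the source video sequence.
#' @param frame_id identifier of the frame.
#' @return An object of class `segmentation_sample`.
#' @export
segmentation_sample <- function(image, mask, sequence_id, frame_id) {
  if (length(dim(image)) != 3L || dim(image)[3] != 3L)
    stop_param("image must be an H x W x 3 array")
  mask <- as.matrix(mask)
  if (!all(dim(mask) == dim(image)[1:2]))
    stop_param("mask shape must equal image shape")
  if (!all(mask %in% c(0, 1)))
    stop_param("mask values must be 0/1")
  structure(
    list(image = image, mask = mask,
         sequence_id = as.character(sequence_id),
         frame_id = as.character(frame_id)),
    class = "segmentation_sample")
}

#' @export
print.segmentation_sample <- function(x, ...) {
  d <- dim(x$image)
  cat(sprintf("<segmentation_sample %s/%s: %dx%d, foreground %.1f%%>\n",
              x$sequence_id, x$frame_id, d[1], d[2], 100 * mean(x$mask)))
  invisible(x)
}

# Vectorized HSV -> RGB on [0,1] channels (numeric counterpart of
# grDevices::rgb2hsv; avoids round-tripping through colour strings).
hsv_to_rgb <- function(h, s, v) {
  h <- (h %% 1) * 6
  i <- floor(h)
  f <- h - i
  p <- v * (1 - s)
  q <- v * (1 - s * f)
  t <- v * (1 - s * (1 - f))
  r <- ifelse(i == 0 | i == 5, v, ifelse(i == 1, q, ifelse(i == 4, t, p)))
  g <- ifelse(i == 1 | i == 2, v, ifelse(i == 0, t, ifelse(i == 3, q, p)))
  b <- ifelse(i == 3 | i == 4, v, ifelse(i == 2, t, ifelse(i == 5, q, p)))
  list(r = r, g = g, b = b)
}

# 8-bit quantization of a [0,1] image array: makes corpora bit-stable on
# disk and in memory.
quantize8 <- function(x) round(clamp(x, 0, 1) * 255) / 255

#' Write a corpus of samples to disk
#'
#' Writes each frame as an RGB PNG, each mask as a single-channel PNG
#' (0/255), and a manifest CSV with columns `frame_id`, `sequence_id`,
#' `image`, `mask` (paths relative to the manifest).
#'
#' @param samples list of [segmentation_sample] objects.
#' @param dir output directory (created if absent).
#' @return Invisibly, the manifest path.
#' @export
write_corpus <- function(samples, dir) {
  dir.create(file.path(dir, "images"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "masks"), recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(samples, function(s) {
    img_rel <- file.path("images", paste0(s$frame_id, ".png"))
    msk_rel <- file.path("masks", paste0(s$frame_id, ".png"))
    png::writePNG(s$image, file.path(dir, img_rel))
    png::writePNG(s$mask + 0, file.path(dir, msk_rel))  # force double storage
    data.frame(frame_id = s$frame_id, sequence_id = s$sequence_id,
               image = img_rel, mask = msk_rel, stringsAsFactors = FALSE)
  })
  manifest <- do.call(rbind, rows)
  path <- file.path(dir, "manifest.csv")
  write.csv(manifest, path, row.names = FALSE)
  invisible(path)
}

#' Read a corpus back from a manifest
#'
#' @param manifest path to a manifest CSV written by [write_corpus()].
#' @return A list of [segmentation_sample] objects.
#' @export
read_corpus <- function(manifest) {
  tab <- read.csv(manifest, stringsAsFactors = FALSE)
  root <- dirname(manifest)
  lapply(seq_len(nrow(tab)), function(i) {
    img <- png::readPNG(file.path(root, tab$image[i]))
    msk <- png::readPNG(file.path(root, tab$mask[i]))
    if (length(dim(msk)) == 3L) msk <- msk[, , 1]
    segmentation_sample(img, (msk > 0.5) * 1L,
                        tab$sequence_id[i], tab$frame_id[i])
  })
}
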