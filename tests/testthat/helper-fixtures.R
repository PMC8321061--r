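# Shared fixtures: all generated in code, at sizes chosen for fast tests.

# a rasterized disc mask on an n x n canvas
disc_mask <- function(n, radius, center = c((n + 1) / 2, (n + 1) / 2)) {
  yy <- matrix(seq_len(n), n, n)
  xx <- matrix(seq_len(n), n, n, byrow = TRUE)
  ((yy - center[1])^2 + (xx - center[2])^2 <= radius^2) * 1
}

square_mask <- function(n, side, top = (n - side) %/% 2) {
  m <- matrix(0, n, n)
  m[top + seq_len(side), top + seq_len(side)] <- 1
  m
}

# small phantom corpus for pipeline tests; polyp size scales with canvas
tiny_corpus <- function(n_seq = 4, frames = 3, hw = c(64, 72), seed = 123,
                        radius = c(min(hw) / 10, min(hw) / 7)) {
  generate_corpus(phantom_spec(
    image_height = hw[1], image_width = hw[2],
    n_sequences = n_seq, frames_per_sequence = frames,
    polyp_radius_range = radius, seed = seed))
}

tiny_arch <- function(hw = c(64, 72), channels = 8) {
  architecture_spec(backbone_depth = 14L, input_size = as.integer(hw),
                    path_channels = as.integer(channels))
}

random_mask <- function(h, w, p = 0.3) {
  matrix(as.numeric(runif(h * w) < p), h, w)
}

# strip probability_map attributes for value-only comparisons
pmat <- function(p) {
  m <- unclass(p)
  attributes(m) <- list(dim = dim(m))
  m
}

# independent R-level all-pairs Hausdorff oracle over boundary point sets
hausdorff_oracle <- function(a, b) {
  if (nrow(a) == 0 || nrow(b) == 0) return(Inf)
  d2 <- outer(a[, 1], b[, 1], "-")^2 + outer(a[, 2], b[, 2], "-")^2
  max(sqrt(max(apply(d2, 1, min))), sqrt(max(apply(d2, 2, min))))
}
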