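# The Dilated ResFCN architecture: a residual feature-extraction backbone
# (Res1..Res5), four parallel multi-resolution classification paths with
# dilated 3x3 kernels tapping Res2..Res5, fixed bilinear upsampling of each
# path's score map to the input size, and additive fusion. The ResFCN
# ablation variant is the same graph with all path dilation rates forced
# to 1.

backbone_profile <- function(depth) {
  switch(as.character(depth),
    "14" = list(blocks = c(1L, 1L, 1L, 1L), mid = c(16L, 32L, 64L, 128L),
                stem = 32L),
    "50" = list(blocks = c(3L, 4L, 6L, 3L), mid = c(64L, 128L, 256L, 512L),
                stem = 64L),
    "101" = list(blocks = c(3L, 4L, 23L, 3L), mid = c(64L, 128L, 256L, 512L),
                 stem = 64L),
    "152" = list(blocks = c(3L, 8L, 36L, 3L), mid = c(64L, 128L, 256L, 512L),
                 stem = 64L),
    stop_param("backbone_depth must be one of 14, 50, 101, 152"))
}

#' Specify a Dilated ResFCN architecture
#'
#' @param backbone_depth residual backbone depth: 50 (default), 101 or 152
#'   are the standard bottleneck partitions; 14 is a slim single-block-per-
#'   stage profile with the same stride structure for CPU-scale experiments.
#' @param path_dilation_rates integer dilation rates for the classification
#'   paths attached to Res2..Res5 (finest to coarsest); must be strictly
#'   decreasing. Default `c(16, 8, 4, 2)`.
#' @param classifier_kernel odd kernel size of the dilated path convolution.
#' @param dropout_rate dropout probability between the dilated convolution
#'   and the 1x1 pixel classifier.
#' @param n_classes number of output classes (2: background, polyp).
#' @param input_size `c(height, width)` training resolution.
#' @param use_dilation `FALSE` builds the ResFCN ablation variant (all path
#'   dilation rates forced to 1).
#' @param path_channels output channels of each path's dilated convolution.
#' @return An object of class `architecture_spec`.
#' @export
architecture_spec <- function(backbone_depth = 50L,
                              path_dilation_rates = c(16L, 8L, 4L, 2L),
                              classifier_kernel = 3L,
                              dropout_rate = 0.5,
                              n_classes = 2L,
                              input_size = c(250L, 287L),
                              use_dilation = TRUE,
                              path_channels = 128L) {
  backbone_profile(backbone_depth)  # validates depth
  check_number(classifier_kernel, "classifier_kernel", lower = 1, integer = TRUE)
  if (classifier_kernel %% 2 == 0)
    stop_param("classifier_kernel must be odd")
  check_number(path_dilation_rates, "path_dilation_rates", lower = 1,
               len = 4L, integer = TRUE)
  if (isTRUE(use_dilation)) {
    if (any(diff(path_dilation_rates) >= 0))
      stop_param("path_dilation_rates must be strictly decreasing ",
                 "from the Res2 path to the Res5 path")
  } else {
    path_dilation_rates <- rep(1L, 4L)
  }
  check_number(dropout_rate, "dropout_rate", lower = 0, upper = 1)
  check_number(n_classes, "n_classes", lower = 2, integer = TRUE)
  check_number(input_size, "input_size", lower = 16, len = 2L, integer = TRUE)
  check_number(path_channels, "path_channels", lower = 1, integer = TRUE)
  structure(
    list(backbone_depth = as.integer(backbone_depth),
         path_dilation_rates = as.integer(path_dilation_rates),
         classifier_kernel = as.integer(classifier_kernel),
         dropout_rate = dropout_rate,
         n_classes = as.integer(n_classes),
         input_size = as.integer(input_size),
         use_dilation = isTRUE(use_dilation),
         path_channels = as.integer(path_channels)),
    class = "architecture_spec")
}

#' Backbone stage table
#'
#' Stride (relative to the input), residual-branch convolutional layer
#' count, and output channel count for the Res2..Res5 stages of a given
#' backbone depth. Projection-shortcut convolutions are not counted, which
#' matches the conventional per-stage layer tally (9/12/18/9 at depth 50).
#'
#' @param backbone_depth backbone depth (14/50/101/152).
#' @return A data.frame with columns `stage`, `stride`, `n_conv_layers`,
#'   `n_channels`.
#' @export
backbone_stage_info <- function(backbone_depth = 50L) {
  pr <- backbone_profile(backbone_depth)
  data.frame(
    stage = paste0("Res", 2:5),
    stride = c(4L, 8L, 16L, 32L),
    n_conv_layers = 3L * pr$blocks,
    n_channels = 4L * pr$mid)
}

#' Analytic backbone output sizes
#'
#' Spatial size of each Res2..Res5 output for a given input size, using the
#' package's convolution (floor, explicit padding) and pooling (ceil)
#' arithmetic.
#'
#' @param input_size `c(height, width)`.
#' @return 4 x 2 integer matrix with rows Res2..Res5.
#' @export
stage_output_sizes <- function(input_size) {
  sz <- as.integer(input_size)
  sz <- c(conv_out_dim(sz[1], 7, 2, 1, 3), conv_out_dim(sz[2], 7, 2, 1, 3))
  sz <- c(pool_out_dim(sz[1], 3, 2), pool_out_dim(sz[2], 3, 2))
  out <- matrix(0L, 4, 2, dimnames = list(paste0("Res", 2:5), c("h", "w")))
  strides <- c(1L, 2L, 2L, 2L)
  for (i in 1:4) {
    sz <- c(conv_out_dim(sz[1], 3, strides[i], 1, 1),
            conv_out_dim(sz[2], 3, strides[i], 1, 1))
    out[i, ] <- as.integer(sz)
  }
  out
}

new_bottleneck <- function(cin, mid, cout, stride, name) {
  b <- list(
    c1 = new_conv(cin, mid, 1L, 1L, name = paste0(name, ".c1")),
    n1 = new_norm(mid, paste0(name, ".n1")),
    c2 = new_conv(mid, mid, 3L, stride, name = paste0(name, ".c2")),
    n2 = new_norm(mid, paste0(name, ".n2")),
    c3 = new_conv(mid, cout, 1L, 1L, name = paste0(name, ".c3")),
    n3 = new_norm(cout, paste0(name, ".n3")),
    proj_conv = NULL, proj_norm = NULL)
  if (stride != 1L || cin != cout) {
    b$proj_conv <- new_conv(cin, cout, 1L, stride,
                            name = paste0(name, ".proj"))
    b$proj_norm <- new_norm(cout, paste0(name, ".projn"))
  }
  b
}

#' Build a Dilated ResFCN segmentation network
#'
#' Constructs the feature-extraction backbone, the four dilated
#' classification paths tapping Res2..Res5, and the bilinear fusion head.
#' Backbone convolutions use He initialization; path convolutions use
#' Xavier initialization.
#'
#' @param spec an [architecture_spec()].
#' @param seed optional integer seed for weight initialization.
#' @return An object of class `dresfcn`.
#' @export
build_network <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "architecture_spec"))
  with_seed(seed, {
    pr <- backbone_profile(spec$backbone_depth)
    stem <- list(conv = new_conv(3L, pr$stem, 7L, 2L, name = "stem.conv"),
                 norm = new_norm(pr$stem, "stem.norm"))
    stages <- vector("list", 4L)
    cin <- pr$stem
    strides <- c(1L, 2L, 2L, 2L)
    for (s in 1:4) {
      cout <- 4L * pr$mid[s]
      blocks <- vector("list", pr$blocks[s])
      for (bi in seq_len(pr$blocks[s])) {
        blocks[[bi]] <- new_bottleneck(
          cin, pr$mid[s], cout, if (bi == 1L) strides[s] else 1L,
          sprintf("res%d.b%d", s + 1L, bi))
        cin <- cout
      }
      stages[[s]] <- blocks
    }
    paths <- vector("list", 4L)
    for (p in 1:4) {
      cs <- 4L * pr$mid[p]
      paths[[p]] <- list(
        dil_conv = new_conv(cs, spec$path_channels, spec$classifier_kernel,
                            1L, dil = spec$path_dilation_rates[p],
                            bias = TRUE, init = "xavier",
                            name = sprintf("path%d.dil", p)),
        cls = new_conv(spec$path_channels, spec$n_classes, 1L, 1L,
                       bias = TRUE, init = "xavier",
                       name = sprintf("path%d.cls", p)),
        rate = spec$path_dilation_rates[p])
    }
    layers <- list(stem$conv, stem$norm)
    for (st in stages) for (b in st) {
      layers <- c(layers, list(b$c1, b$n1, b$c2, b$n2, b$c3, b$n3))
      if (!is.null(b$proj_conv))
        layers <- c(layers, list(b$proj_conv, b$proj_norm))
    }
    for (p in paths) layers <- c(layers, list(p$dil_conv, p$cls))
    structure(
      list(spec = spec, stem = stem, stages = stages, paths = paths,
           layers = layers,
           norm_stats = list(mean = rep(0.5, 3), sd = rep(0.25, 3))),
      class = "dresfcn")
  })
}

#' @export
print.dresfcn <- function(x, ...) {
  cat(sprintf(
    "<dresfcn depth-%d%s, rates %s, %s parameters>\n",
    x$spec$backbone_depth,
    if (x$spec$use_dilation) "" else " (no dilation)",
    paste(x$spec$path_dilation_rates, collapse = "/"),
    format(parameter_count(x), big.mark = ",")))
  invisible(x)
}

#' Total number of trainable parameters
#'
#' @param x a `dresfcn` network or an [architecture_spec()] (counted
#'   analytically without allocating weights).
#' @return Numeric parameter count.
#' @export
parameter_count <- function(x) {
  if (inherits(x, "dresfcn"))
    return(sum(vapply(x$layers, layer_param_count, numeric(1))))
  stopifnot(inherits(x, "architecture_spec"))
  pr <- backbone_profile(x$backbone_depth)
  total <- 7 * 7 * 3 * pr$stem + 2 * pr$stem  # stem conv + norm
  cin <- pr$stem
  strides <- c(1L, 2L, 2L, 2L)
  for (s in 1:4) {
    mid <- pr$mid[s]; cout <- 4 * mid
    for (bi in seq_len(pr$blocks[s])) {
      total <- total + cin * mid + 2 * mid +        # c1 + n1
        9 * mid * mid + 2 * mid +                   # c2 + n2
        mid * cout + 2 * cout                       # c3 + n3
      if (bi == 1L && (strides[s] != 1L || cin != cout))
        total <- total + cin * cout + 2 * cout      # projection
      cin <- cout
    }
  }
  k2 <- x$classifier_kernel^2
  for (s in 1:4) {
    cs <- 4 * pr$mid[s]
    total <- total + k2 * cs * x$path_channels + x$path_channels +
      x$path_channels * x$n_classes + x$n_classes
  }
  total
}

block_forward <- function(b, x, retain = FALSE) {
  o <- conv_forward(b$c1, x, retain)
  o <- norm_forward(b$n1, o, retain)
  r1 <- relu_forward(o)
  o <- conv_forward(b$c2, r1$y, retain)
  o <- norm_forward(b$n2, o, retain)
  r2 <- relu_forward(o)
  o <- conv_forward(b$c3, r2$y, retain)
  o <- norm_forward(b$n3, o, retain)
  if (!is.null(b$proj_conv)) {
    s <- conv_forward(b$proj_conv, x, retain)
    s <- norm_forward(b$proj_norm, s, retain)
  } else s <- x
  r3 <- relu_forward(o + s)
  cache <- if (retain) list(m1 = r1$mask, m2 = r2$mask, m3 = r3$mask) else NULL
  list(y = r3$y, cache = cache)
}

block_backward <- function(b, cache, dy) {
  dy <- relu_backward(dy, cache$m3)
  d <- norm_backward(b$n3, dy)
  d <- conv_backward(b$c3, d)
  d <- relu_backward(d, cache$m2)
  d <- norm_backward(b$n2, d)
  d <- conv_backward(b$c2, d)
  d <- relu_backward(d, cache$m1)
  d <- norm_backward(b$n1, d)
  d <- conv_backward(b$c1, d)
  if (!is.null(b$proj_conv)) {
    dp <- norm_backward(b$proj_norm, dy)
    dp <- conv_backward(b$proj_conv, dp)
    d + dp
  } else d + dy
}

#' Forward pass of a Dilated ResFCN network
#'
#' Maps an `H x W x 3` image (values in `[0, 1]`) to an
#' `H x W x n_classes` fused score map. Fully convolutional: any input size
#' at least 32 pixels per side is accepted.
#'
#' @param net a `dresfcn` network.
#' @param image `H x W x 3` array.
#' @param train logical; enables dropout and retains caches for
#'   [network_backward()].
#' @param return_stages logical; additionally return the dimensions of the
#'   Res2..Res5 feature maps measured on this forward pass.
#' @return List with `scores` (`H x W x n_classes` array), optionally
#'   `stage_dims`, and, when `train = TRUE`, the structures needed for the
#'   backward pass.
#' @export
network_forward <- function(net, image, train = FALSE,
                            return_stages = FALSE) {
  d <- dim(image)
  if (length(d) != 3L || d[3] != 3L)
    stop_param("image must be an H x W x 3 array")
  x <- sweep(sweep(image, 3, net$norm_stats$mean), 3, net$norm_stats$sd, "/")
  retain <- train
  x <- conv_forward(net$stem$conv, x, retain)
  x <- norm_forward(net$stem$norm, x, retain)
  r0 <- relu_forward(x)
  pool <- maxpool_forward(r0$y, 3L, 2L, retain)
  x <- pool$y
  stage_caches <- vector("list", 4L)
  stage_outputs <- vector("list", 4L)
  for (s in 1:4) {
    bc <- vector("list", length(net$stages[[s]]))
    for (bi in seq_along(net$stages[[s]])) {
      r <- block_forward(net$stages[[s]][[bi]], x, retain)
      x <- r$y
      bc[[bi]] <- r$cache
    }
    stage_caches[[s]] <- bc
    stage_outputs[[s]] <- x
  }
  scores <- 0
  path_caches <- vector("list", 4L)
  for (p in 1:4) {
    pa <- net$paths[[p]]
    f <- conv_forward(pa$dil_conv, stage_outputs[[p]], retain)
    rr <- relu_forward(f)
    dr <- dropout_forward(rr$y, net$spec$dropout_rate, train)
    z <- conv_forward(pa$cls, dr$y, retain)
    scores <- scores + cpp_resize_bilinear(z, d[1], d[2])
    path_caches[[p]] <- if (retain)
      list(relu = rr$mask, drop = dr$mask, z_dim = dim(z)) else NULL
  }
  stage_dims <- lapply(stage_outputs, dim)
  names(stage_dims) <- paste0("Res", 2:5)
  out <- list(scores = scores)
  if (return_stages) out$stage_dims <- stage_dims
  if (!retain) return(out)
  c(out, list(
    cache = list(stage_caches = stage_caches, path_caches = path_caches,
                 pool = pool, stem_mask = r0$mask)))
}

# Backward pass matching network_forward(train = TRUE); accumulates
# parameter gradients into the layer environments.
network_backward <- function(net, cache, dscores) {
  stage_grads <- vector("list", 4L)
  for (p in 1:4) {
    pa <- net$paths[[p]]
    pc <- cache$path_caches[[p]]
    dz <- cpp_resize_bilinear_backward(dscores, pc$z_dim[1], pc$z_dim[2])
    dd <- conv_backward(pa$cls, dz)
    if (!is.null(pc$drop)) dd <- dd * pc$drop
    dd <- relu_backward(dd, pc$relu)
    stage_grads[[p]] <- conv_backward(pa$dil_conv, dd)
  }
  dx <- stage_grads[[4]]
  for (s in 4:1) {
    blocks <- net$stages[[s]]
    for (bi in rev(seq_along(blocks)))
      dx <- block_backward(blocks[[bi]], cache$stage_caches[[s]][[bi]], dx)
    if (s > 1) dx <- dx + stage_grads[[s - 1]]
  }
  dx <- maxpool_backward(dx, cache$pool$arg, cache$pool$in_dim)
  dx <- relu_backward(dx, cache$stem_mask)
  dx <- norm_backward(net$stem$norm, dx)
  conv_backward(net$stem$conv, dx)
  invisible(NULL)
}

#' Effective spatial span of a dilated kernel
#'
#' A `k x k` kernel at dilation rate `r` covers `(k - 1) * r + 1` pixels per
#' side: 5 at rate 2, 9 at rate 4, 17 at rate 8, 33 at rate 16 for the
#' default 3x3 kernel.
#'
#' @param kernel odd kernel size.
#' @param rate dilation rate (>= 1).
#' @return Integer span in pixels.
#' @export
effective_kernel_span <- function(kernel, rate) {
  check_number(kernel, "kernel", lower = 1, integer = TRUE)
  check_number(rate, "rate", lower = 1, integer = TRUE)
  if (kernel %% 2 == 0) stop_param("kernel must be odd")
  as.integer((kernel - 1) * rate + 1)
}

#' Valid-weight histogram of a dilated kernel on a finite map
#'
#' For every output position of a same-padded dilated convolution on an
#' `h x w` feature map, counts how many kernel taps land inside the map
#' (the "valid" weights). At high dilation rates on small maps the kernel
#' degenerates: e.g. a 3x3 kernel at rate >= 9 on an 8 x 9 map has exactly
#' one valid weight everywhere.
#'
#' @param map_size `c(h, w)` feature-map size.
#' @param kernel odd kernel size.
#' @param rate dilation rate.
#' @return List with `histogram` (named integer vector: valid-count ->
#'   number of positions), `counts` (`h x w` matrix of per-position valid
#'   counts), `span`, `rate`, and `fraction_ge4` (share of positions with
#'   at least 4 valid weights).
#' @export
valid_weight_histogram <- function(map_size, kernel = 3L, rate = 1L) {
  check_number(map_size, "map_size", lower = 1, len = 2L, integer = TRUE)
  span <- effective_kernel_span(kernel, rate)
  h <- map_size[1]; w <- map_size[2]
  half <- (kernel - 1) / 2
  offs <- (-half:half) * rate
  vr <- vapply(seq_len(h), function(i) sum(i + offs >= 1 & i + offs <= h),
               numeric(1))
  vc <- vapply(seq_len(w), function(j) sum(j + offs >= 1 & j + offs <= w),
               numeric(1))
  counts <- outer(vr, vc)
  tab <- table(factor(counts, levels = seq_len(kernel^2)))
  hist <- setNames(as.integer(tab), names(tab))
  list(histogram = hist, counts = counts, span = span, rate = as.integer(rate),
       fraction_ge4 = mean(counts >= 4))
}

#' Fraction of polyps representable within a path's receptive span
#'
#' The design statistic used to select the coarsest path's dilation rate:
#' the share of polyps whose linear extent, expressed at the path's
#' feature-map resolution (`extent / stride`), fits within the effective
#' kernel span.
#'
#' @param polyp_sizes numeric vector of polyp linear extents in input
#'   pixels.
#' @param span effective kernel span (feature-map pixels).
#' @param stride the path's stride relative to the input.
#' @return Fraction in `[0, 1]`.
#' @export
coverage_fraction <- function(polyp_sizes, span, stride) {
  if (length(polyp_sizes) == 0) stop_param("polyp_sizes must be non-empty")
  check_number(span, "span", lower = 1)
  check_number(stride, "stride", lower = 1)
  mean(polyp_sizes / stride <= span)
}

#' Receptive-field design report for the classification paths
#'
#' For each of the four classification paths, tabulates its dilation rate,
#' effective kernel span, valid-weight histogram on the path's feature map,
#' and the share of positions retaining at least 4 of the kernel's weights.
#'
#' @param spec an [architecture_spec()].
#' @param input_size `c(height, width)`; defaults to the spec's input size.
#' @return An object of class `receptive_field_report` (a data.frame plus a
#'   `histograms` attribute).
#' @export
receptive_field_report <- function(spec, input_size = spec$input_size) {
  stopifnot(inherits(spec, "architecture_spec"))
  sizes <- stage_output_sizes(input_size)
  rows <- lapply(1:4, function(p) {
    vh <- valid_weight_histogram(sizes[p, ], spec$classifier_kernel,
                                 spec$path_dilation_rates[p])
    data.frame(path = paste0("Res", p + 1L),
               map_h = sizes[p, 1], map_w = sizes[p, 2],
               rate = vh$rate, span = vh$span,
               fraction_ge4 = vh$fraction_ge4)
  })
  rep_df <- do.call(rbind, rows)
  hists <- lapply(1:4, function(p)
    valid_weight_histogram(sizes[p, ], spec$classifier_kernel,
                           spec$path_dilation_rates[p])$histogram)
  names(hists) <- rep_df$path
  structure(rep_df, histograms = hists,
            class = c("receptive_field_report", "data.frame"))
}

#' Save / load a network checkpoint
#'
#' The checkpoint is the host serialization (RDS) of the parameter arrays;
#' a JSON sidecar records the architecture spec so checkpoints are
#' self-describing.
#'
#' @param net a `dresfcn` network.
#' @param path checkpoint path (`.rds`).
#' @return `save_checkpoint` invisibly returns `path`; `load_checkpoint`
#'   returns a `dresfcn`.
#' @export
save_checkpoint <- function(net, path) {
  params <- lapply(net$layers, function(e) {
    out <- lapply(e$params, function(p) e[[p]])
    names(out) <- e$params
    out
  })
  names(params) <- vapply(net$layers, function(e) e$name, character(1))
  saveRDS(list(spec = unclass(net$spec), params = params,
               norm_stats = net$norm_stats), path)
  jsonlite::write_json(unclass(net$spec), paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  spec <- do.call(architecture_spec, ck$spec)
  net <- build_network(spec, seed = 0L)
  for (e in net$layers) {
    stored <- ck$params[[e$name]]
    if (is.null(stored)) stop_param("checkpoint missing layer ", e$name)
    for (p in e$params) e[[p]] <- stored[[p]]
  }
  net$norm_stats <- ck$norm_stats
  net
}
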