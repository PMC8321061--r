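# Minimal CPU neural-network layer toolkit backing the segmentation
# architecture. Layers are environments holding parameters, accumulated
# gradients and Adam state; forward passes optionally retain caches for a
# single subsequent backward pass. Tensors are plain R arrays (H, W, C).

conv_out_dim <- function(n, k, stride, dil, pad) {
  # floor convention with explicit symmetric padding (Caffe convolution)
  floor((n + 2 * pad - dil * (k - 1) - 1) / stride) + 1
}

pool_out_dim <- function(n, k, stride) {
  # ceil convention (Caffe pooling), window clipped to the valid region
  ceiling((n - k) / stride) + 1
}

new_conv <- function(cin, cout, k = 3L, stride = 1L, dil = 1L,
                     bias = FALSE, init = c("he", "xavier"), name = "conv") {
  init <- match.arg(init)
  fan_in <- k * k * cin
  fan_out <- k * k * cout
  w <- if (init == "he") {
    matrix(rnorm(fan_in * cout, sd = sqrt(2 / fan_in)), fan_in, cout)
  } else {
    lim <- sqrt(6 / (fan_in + fan_out))
    matrix(runif(fan_in * cout, -lim, lim), fan_in, cout)
  }
  e <- new.env(parent = emptyenv())
  e$type <- "conv"; e$name <- name
  e$cin <- cin; e$cout <- cout; e$k <- as.integer(k)
  e$stride <- as.integer(stride); e$dil <- as.integer(dil)
  e$pad <- as.integer(dil * (k - 1) / 2)
  e$w <- w
  e$params <- "w"
  if (bias) { e$b <- numeric(cout); e$params <- c("w", "b") }
  e
}

conv_forward <- function(e, x, retain = FALSE) {
  d <- dim(x)
  oh <- conv_out_dim(d[1], e$k, e$stride, e$dil, e$pad)
  ow <- conv_out_dim(d[2], e$k, e$stride, e$dil, e$pad)
  cols <- cpp_im2col(x, e$k, e$k, e$stride, e$dil, e$pad, e$pad, oh, ow)
  y <- crossprod(cols, e$w)
  if (!is.null(e$b)) y <- sweep(y, 2, e$b, "+")
  dim(y) <- c(oh, ow, e$cout)
  if (retain) e$cache <- list(x_dim = d, cols = cols, oh = oh, ow = ow)
  y
}

conv_backward <- function(e, dy) {
  cc <- e$cache
  dy_mat <- matrix(dy, cc$oh * cc$ow, e$cout)
  e$gw <- e$gw + cc$cols %*% dy_mat
  if (!is.null(e$b)) e$gb <- e$gb + colSums(dy_mat)
  dcols <- e$w %*% t(dy_mat)
  dx <- cpp_col2im(dcols, cc$x_dim[1], cc$x_dim[2], cc$x_dim[3],
                   e$k, e$k, e$stride, e$dil, e$pad, e$pad, cc$oh, cc$ow)
  e$cache <- NULL
  dx
}

# Per-sample channel normalization (instance norm): normalizes each channel
# over its spatial support with learned scale/shift. Used wherever a
# residual backbone would place batch normalization; deterministic and
# batch-size independent.
new_norm <- function(c, name = "norm") {
  e <- new.env(parent = emptyenv())
  e$type <- "norm"; e$name <- name
  e$gamma <- rep(1, c); e$beta <- numeric(c)
  e$eps <- 1e-5
  e$params <- c("gamma", "beta")
  e
}

norm_forward <- function(e, x, retain = FALSE) {
  d <- dim(x)
  n <- d[1] * d[2]
  xm <- matrix(x, n, d[3])
  mu <- colMeans(xm)
  xc <- sweep(xm, 2, mu)
  v <- colMeans(xc * xc)
  inv_std <- 1 / sqrt(v + e$eps)
  xhat <- sweep(xc, 2, inv_std, "*")
  y <- sweep(sweep(xhat, 2, e$gamma, "*"), 2, e$beta, "+")
  dim(y) <- d
  if (retain) e$cache <- list(xhat = xhat, inv_std = inv_std, d = d)
  y
}

norm_backward <- function(e, dy) {
  cc <- e$cache
  d <- cc$d
  n <- d[1] * d[2]
  dym <- matrix(dy, n, d[3])
  e$ggamma <- e$ggamma + colSums(dym * cc$xhat)
  e$gbeta <- e$gbeta + colSums(dym)
  dxhat <- sweep(dym, 2, e$gamma, "*")
  # dx = inv_std * (dxhat - mean(dxhat) - xhat * mean(dxhat * xhat))
  m1 <- colMeans(dxhat)
  m2 <- colMeans(dxhat * cc$xhat)
  dx <- sweep(dxhat, 2, m1) - sweep(cc$xhat, 2, m2, "*")
  dx <- sweep(dx, 2, cc$inv_std, "*")
  dim(dx) <- d
  e$cache <- NULL
  dx
}

relu_forward <- function(x) {
  m <- x > 0
  list(y = x * m, mask = m)
}

relu_backward <- function(dy, mask) dy * mask

maxpool_forward <- function(x, k = 3L, stride = 2L, retain = FALSE) {
  d <- dim(x)
  oh <- pool_out_dim(d[1], k, stride)
  ow <- pool_out_dim(d[2], k, stride)
  r <- cpp_maxpool(x, k, stride, oh, ow)
  list(y = r$y, arg = if (retain) r$arg else NULL, in_dim = d)
}

maxpool_backward <- function(dy, arg, in_dim) {
  cpp_maxpool_backward(dy, arg, in_dim[1], in_dim[2])
}

dropout_forward <- function(x, rate, train) {
  if (!train || rate <= 0) return(list(y = x, mask = NULL))
  mask <- array((runif(length(x)) >= rate) / (1 - rate), dim(x))
  list(y = x * mask, mask = mask)
}

# Walk a flat list of parameter-layer environments, applying one Adam step
# and clearing gradients. `t` is the global step counter (1-based).
adam_step <- function(layers, lr, t, beta1 = 0.9, beta2 = 0.999, eps = 1e-8,
                      scale = 1) {
  for (e in layers) {
    for (p in e$params) {
      g <- e[[paste0("g", p)]] * scale
      mk <- paste0("m_", p); vk <- paste0("v_", p)
      if (is.null(e[[mk]])) { e[[mk]] <- g * 0; e[[vk]] <- g * 0 }
      e[[mk]] <- beta1 * e[[mk]] + (1 - beta1) * g
      e[[vk]] <- beta2 * e[[vk]] + (1 - beta2) * g * g
      mhat <- e[[mk]] / (1 - beta1^t)
      vhat <- e[[vk]] / (1 - beta2^t)
      e[[p]] <- e[[p]] - lr * mhat / (sqrt(vhat) + eps)
    }
  }
  invisible(NULL)
}

zero_grads <- function(layers) {
  for (e in layers) for (p in e$params) e[[paste0("g", p)]] <- e[[p]] * 0
  invisible(NULL)
}

# Per-pixel 2-class softmax cross-entropy on a fused score map.
# scores: (H, W, 2); target: H x W in {0,1}; class_weights: length-2
# (background, polyp). Returns loss and the gradient wrt scores.
softmax_ce <- function(scores, target, class_weights = c(1, 1)) {
  d <- dim(scores)
  z <- matrix(scores, d[1] * d[2], 2)
  zmax <- pmax(z[, 1], z[, 2])
  ez <- exp(z - zmax)
  denom <- ez[, 1] + ez[, 2]
  p <- ez / denom
  t1 <- as.numeric(target)
  w <- ifelse(t1 > 0.5, class_weights[2], class_weights[1])
  wsum <- sum(w)
  py <- ifelse(t1 > 0.5, p[, 2], p[, 1])
  loss <- -sum(w * log(pmax(py, 1e-12))) / wsum
  grad <- p
  grad[, 1] <- (grad[, 1] - (1 - t1)) * w / wsum
  grad[, 2] <- (p[, 2] - t1) * w / wsum
  dim(grad) <- d
  list(loss = loss, grad = grad, prob = p)
}

layer_param_count <- function(e) {
  sum(vapply(e$params, function(p) length(e[[p]]), numeric(1)))
}
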