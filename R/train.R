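# Training: Adam with a stepped learning-rate schedule (initial 1e-4,
# multiplied by 0.1 every 10 epochs by default), per-pixel 2-class softmax
# cross-entropy on the fused score map, and video-grouped k-fold
# cross-validation so correlated frames never straddle the train/validation
# boundary.

#' Specify a training run
#'
#' @param epochs number of passes over the training set.
#' @param initial_learning_rate Adam learning rate at epoch 0.
#' @param decay_factor multiplicative learning-rate decay.
#' @param decay_every epochs between decays; the learning rate at (0-based)
#'   epoch `e` is `initial_learning_rate * decay_factor^floor(e / decay_every)`.
#' @param batch_size samples per gradient step.
#' @param optimizer only `"adam"` is implemented.
#' @param loss only per-pixel `"cross_entropy"` is implemented.
#' @param class_weighting `"none"` (default) or `"balanced"`
#'   (inverse-frequency weights estimated from the training corpus; useful
#'   when the polyp occupies a small fraction of the frame).
#' @param seed integer seed for shuffling, dropout and weight
#'   initialization downstream.
#' @return An object of class `training_spec`.
#' @export
training_spec <- function(epochs = 30L, initial_learning_rate = 1e-4,
                          decay_factor = 0.1, decay_every = 10L,
                          batch_size = 8L, optimizer = "adam",
                          loss = "cross_entropy",
                          class_weighting = c("none", "balanced"),
                          seed = 1L) {
  check_number(epochs, "epochs", lower = 1, integer = TRUE)
  check_number(initial_learning_rate, "initial_learning_rate", lower = 1e-12)
  check_number(decay_factor, "decay_factor", lower = 1e-12, upper = 1)
  check_number(decay_every, "decay_every", lower = 1, integer = TRUE)
  check_number(batch_size, "batch_size", lower = 1, integer = TRUE)
  if (!identical(optimizer, "adam")) stop_param("optimizer must be 'adam'")
  if (!identical(loss, "cross_entropy"))
    stop_param("loss must be 'cross_entropy'")
  class_weighting <- match.arg(class_weighting)
  structure(
    list(epochs = as.integer(epochs),
         initial_learning_rate = initial_learning_rate,
         decay_factor = decay_factor,
         decay_every = as.integer(decay_every),
         batch_size = as.integer(batch_size),
         optimizer = optimizer, loss = loss,
         class_weighting = class_weighting,
         seed = as.integer(seed)),
    class = "training_spec")
}

#' Learning rate at a given epoch
#'
#' @param spec a [training_spec()].
#' @param epoch 0-based epoch index (vectorized).
#' @return Learning rate(s).
#' @export
learning_rate_at <- function(spec, epoch) {
  spec$initial_learning_rate *
    spec$decay_factor^floor(epoch / spec$decay_every)
}

#' Assign video sequences to cross-validation folds
#'
#' Whole sequences are assigned to folds (frames from one video never
#' straddle folds), balancing per-fold frame counts greedily as evenly as
#' sequence sizes allow.
#'
#' @param samples list of [segmentation_sample] objects.
#' @param k number of folds.
#' @param seed integer seed (breaks ties among equally-sized sequences).
#' @return An object of class `fold_plan`: list with `assignment` (named
#'   integer vector, sequence_id -> fold) and `frame_counts`.
#' @export
make_fold_plan <- function(samples, k, seed = 1L) {
  check_number(k, "k", lower = 1, integer = TRUE)
  seq_ids <- vapply(samples, function(s) s$sequence_id, character(1))
  sizes <- table(seq_ids)
  if (length(sizes) < k)
    stop_param("need at least k = ", k, " distinct sequences, got ",
               length(sizes))
  ord <- with_seed(seed, sample(names(sizes)))
  ord <- ord[order(-as.integer(sizes[ord]))]  # big sequences first
  fold_counts <- numeric(k)
  assignment <- integer(length(sizes))
  names(assignment) <- ord
  for (sq in ord) {
    f <- which.min(fold_counts)
    assignment[sq] <- f
    fold_counts[f] <- fold_counts[f] + sizes[sq]
  }
  assignment <- assignment[sort(names(assignment))]
  structure(list(assignment = assignment,
                 frame_counts = setNames(fold_counts, paste0("fold", 1:k)),
                 k = as.integer(k)),
            class = "fold_plan")
}

#' @export
print.fold_plan <- function(x, ...) {
  cat(sprintf("<fold_plan: %d folds, frames %s>\n", x$k,
              paste(x$frame_counts, collapse = "/")))
  invisible(x)
}

estimate_class_weights <- function(samples) {
  fg <- mean(vapply(samples, function(s) mean(s$mask), numeric(1)))
  fg <- clamp(fg, 1e-4, 1 - 1e-4)
  c(0.5 / (1 - fg), 0.5 / fg)
}

#' Train a segmentation network
#'
#' Runs Adam over the fused-map per-pixel cross-entropy with the stepped
#' learning-rate schedule. Input normalization statistics (per-channel
#' mean/sd) are estimated from the training corpus and stored in the
#' network. All randomness (shuffling, dropout) derives from `spec$seed`.
#'
#' @param net a `dresfcn` network from [build_network()].
#' @param train_samples non-empty list of [segmentation_sample] objects,
#'   all at the same resolution.
#' @param spec a [training_spec()].
#' @param verbose print per-epoch progress.
#' @return List with `network` (trained, also modified in place) and
#'   `trace` (data.frame: epoch, lr, loss).
#' @export
train_network <- function(net, train_samples, spec, verbose = FALSE) {
  stopifnot(inherits(net, "dresfcn"), inherits(spec, "training_spec"))
  n <- length(train_samples)
  if (n == 0) stop_param("train_samples must be non-empty")
  ch_stats <- vapply(train_samples, function(s)
    c(apply(s$image, 3, mean), apply(s$image, 3, sd)), numeric(6))
  net$norm_stats <- list(mean = rowMeans(ch_stats)[1:3],
                         sd = pmax(rowMeans(ch_stats)[4:6], 1e-3))
  cw <- if (spec$class_weighting == "balanced")
    estimate_class_weights(train_samples) else c(1, 1)
  trace <- data.frame(epoch = integer(), lr = numeric(), loss = numeric())
  step <- 0L
  with_seed(spec$seed, {
    for (e in seq_len(spec$epochs) - 1L) {
      lr <- learning_rate_at(spec, e)
      order_e <- sample.int(n)
      losses <- numeric(0)
      b_idx <- split(order_e, ceiling(seq_along(order_e) / spec$batch_size))
      for (b in seq_along(b_idx)) {
        zero_grads(net$layers)
        batch <- b_idx[[b]]
        for (i in batch) {
          s <- train_samples[[i]]
          fwd <- network_forward(net, s$image, train = TRUE)
          sm <- softmax_ce(fwd$scores, s$mask, cw)
          if (!is.finite(sm$loss))
            stop(sprintf(
              "non-finite training loss at epoch %d, batch %d (frame %s)",
              e, b, s$frame_id), call. = FALSE)
          losses <- c(losses, sm$loss)
          network_backward(net, fwd$cache, sm$grad)
        }
        step <- step + 1L
        adam_step(net$layers, lr, step, scale = 1 / length(batch))
      }
      trace <- rbind(trace,
                     data.frame(epoch = e, lr = lr, loss = mean(losses)))
      if (verbose)
        message(sprintf("epoch %d: lr %.2g, loss %.4f", e, lr, mean(losses)))
    }
  })
  list(network = net, trace = trace)
}

fold_metrics <- function(net, val_samples, post_spec, input_size) {
  recs <- lapply(val_samples, function(s) {
    d <- dim(s$image)
    if (!all(d[1:2] == input_size))
      s <- rescale_and_crop(s, input_size, random = FALSE)
    pm <- predict_probability(net, s$image)
    pred <- postprocess(pm, post_spec)
    metrics_record(pred, s$mask, s$frame_id, sequence_id = s$sequence_id)
  })
  do.call(rbind, recs)
}

#' Video-grouped k-fold cross-validation
#'
#' For each fold, the training-side frames are augmented with
#' [augment_subset()], a fresh network is trained, and the untouched
#' validation frames are segmented and scored. Validation frames are never
#' seen (in any augmented form) by the network that scores them, enforced
#' at the sequence level.
#'
#' @param samples the full corpus (list of [segmentation_sample]).
#' @param arch_spec an [architecture_spec()].
#' @param train_spec a [training_spec()].
#' @param aug_spec an [augmentation_spec()]; its `target_size` should equal
#'   the architecture's `input_size`.
#' @param k number of folds.
#' @param post_spec a [postprocess_spec()] applied to validation
#'   predictions.
#' @param verbose print progress.
#' @return An object of class `cv_result`: list with `records` (per-frame
#'   metrics data.frame with a `fold` column, size/circularity groups
#'   assigned from each fold's training distribution), `fold_plan`, and
#'   `traces` (per-fold loss traces).
#' @export
cross_validate <- function(samples, arch_spec, train_spec, aug_spec,
                           k = 4L, post_spec = postprocess_spec(),
                           verbose = FALSE) {
  plan <- make_fold_plan(samples, k, train_spec$seed)
  seq_ids <- vapply(samples, function(s) s$sequence_id, character(1))
  folds <- plan$assignment[seq_ids]
  all_records <- list()
  traces <- list()
  for (f in seq_len(k)) {
    val <- samples[folds == f]
    tr <- samples[folds != f]
    if (k == 1L) { val <- samples; tr <- samples }
    aug_f <- aug_spec
    aug_f$seed <- derive_seed(train_spec$seed, 7000L + f)
    aug <- augment_subset(tr, aug_f)
    net <- build_network(arch_spec,
                         seed = derive_seed(train_spec$seed, 9000L + f))
    ts_f <- train_spec
    ts_f$seed <- derive_seed(train_spec$seed, 5000L + f)
    fit <- train_network(net, aug, ts_f, verbose = verbose)
    traces[[f]] <- fit$trace
    recs <- fold_metrics(fit$network, val, post_spec, arch_spec$input_size)
    ref_areas <- vapply(tr, function(s) sum(s$mask), numeric(1))
    ref_circ <- vapply(tr, function(s) circularity(s$mask), numeric(1))
    recs <- stratify(recs, ref_areas, ref_circ)
    recs$fold <- f
    all_records[[f]] <- recs
    if (verbose)
      message(sprintf("fold %d/%d: mean validation Dice %.3f", f, k,
                      mean(recs$dice)))
  }
  structure(list(records = do.call(rbind, all_records),
                 fold_plan = plan, traces = traces),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result: %d folds, %d frames, mean Dice %.3f, median %.3f>\n",
              x$fold_plan$k, nrow(x$records), mean(x$records$dice),
              median(x$records$dice)))
  invisible(x)
}
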