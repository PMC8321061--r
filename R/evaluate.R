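# Evaluation: pixel-overlap metrics (Dice, precision, recall, Jaccard),
# boundary Hausdorff distance, ground-truth shape descriptors (area,
# circularity), quartile-based size/circularity stratification, and
# per-group summaries.
#
# Zero-denominator convention (reported alongside raw counts so alternative
# conventions can be recomputed): an overlap metric is 1 when both masks
# are empty and 0 when exactly one is.

as_binary_mask <- function(m, name) {
  m <- as.matrix(unclass(m))
  if (!all(m %in% c(0, 1))) stop_param(name, " must be binary (0/1)")
  m
}

#' Pixelwise confusion counts
#'
#' @param predicted,truth equally-shaped binary masks.
#' @return Named list `TP`, `FP`, `FN`, `TN`; the four sum to the number of
#'   pixels.
#' @export
confusion_counts <- function(predicted, truth) {
  p <- as_binary_mask(predicted, "predicted")
  g <- as_binary_mask(truth, "truth")
  if (!all(dim(p) == dim(g)))
    stop_param("predicted and truth must have identical shapes")
  tp <- sum(p == 1 & g == 1)
  list(TP = tp, FP = sum(p) - tp, FN = sum(g) - tp,
       TN = sum(p == 0 & g == 0))
}

metric_ratio <- function(num, den, both_empty) {
  if (den == 0) return(if (both_empty) 1 else 0)
  num / den
}

#' Overlap metrics from confusion counts
#'
#' `dice = 2TP / (2TP + FP + FN)`, `precision = TP / (TP + FP)`,
#' `recall = TP / (TP + FN)`, `jaccard = TP / (TP + FP + FN)`; the Jaccard
#' index satisfies the identity `jaccard = dice / (2 - dice)`.
#'
#' @param counts list with `TP`, `FP`, `FN` (as from [confusion_counts()]).
#' @return Value in `[0, 1]`.
#' @export
dice_coefficient <- function(counts) {
  be <- counts$TP + counts$FP + counts$FN == 0
  metric_ratio(2 * counts$TP, 2 * counts$TP + counts$FP + counts$FN, be)
}

#' @rdname dice_coefficient
#' @export
precision_score <- function(counts) {
  be <- counts$TP + counts$FP + counts$FN == 0
  metric_ratio(counts$TP, counts$TP + counts$FP, be)
}

#' @rdname dice_coefficient
#' @export
recall_score <- function(counts) {
  be <- counts$TP + counts$FP + counts$FN == 0
  metric_ratio(counts$TP, counts$TP + counts$FN, be)
}

#' @rdname dice_coefficient
#' @export
jaccard_index <- function(counts) {
  be <- counts$TP + counts$FP + counts$FN == 0
  metric_ratio(counts$TP, counts$TP + counts$FP + counts$FN, be)
}

#' Boundary pixels of a binary mask
#'
#' Foreground pixels 4-adjacent to background (or lying on the image edge).
#'
#' @param mask binary matrix.
#' @return `n x 2` matrix of (row, col) coordinates (possibly 0 rows).
#' @export
mask_boundary <- function(mask) {
  m <- as_binary_mask(mask, "mask")
  h <- nrow(m); w <- ncol(m)
  pad <- matrix(0, h + 2, w + 2)
  pad[2:(h + 1), 2:(w + 1)] <- m
  core <- pad[2:(h + 1), 2:(w + 1)]
  nb_min <- pmin(pad[1:h, 2:(w + 1)], pad[3:(h + 2), 2:(w + 1)],
                 pad[2:(h + 1), 1:w], pad[2:(h + 1), 3:(w + 2)])
  b <- which(core == 1 & nb_min == 0, arr.ind = TRUE)
  colnames(b) <- c("row", "col")
  b
}

#' Hausdorff distance between two mask boundaries
#'
#' The symmetric maximum of the two directed sup-inf Euclidean distances
#' between the boundary pixel sets of the masks: 0 when the contours
#' coincide. When either mask is empty the distance is `Inf` (recorded as a
#' sentinel and excluded from summary means).
#'
#' @param g,s binary masks, or `n x 2` boundary point matrices.
#' @return Distance in pixels (possibly `Inf`).
#' @export
hausdorff_distance <- function(g, s) {
  as_points <- function(x) {
    # a 2-column matrix with values outside {0,1} is a point set, otherwise
    # treat the input as a mask and trace its boundary
    if (is.matrix(x) && ncol(x) == 2 && !all(x %in% c(0, 1))) x
    else mask_boundary(x)
  }
  gb <- as_points(g)
  sb <- as_points(s)
  if (nrow(gb) == 0 || nrow(sb) == 0) return(Inf)
  max(cpp_directed_hausdorff(gb, sb), cpp_directed_hausdorff(sb, gb))
}

# Ordered outer contour of the largest object, via EBImage's oriented
# contour tracer. Returns an n x 2 (row, col) matrix.
traced_contour <- function(mask) {
  oc <- EBImage::ocontour(EBImage::bwlabel(mask))
  if (length(oc) == 0) return(matrix(numeric(0), 0, 2))
  sizes <- vapply(oc, nrow, numeric(1))
  ct <- oc[[which.max(sizes)]]
  # EBImage coordinates are (x, y) 0-based over the matrix's first/second
  # index; orientation does not matter for perimeter length
  ct + 1
}

# Perimeter of a traced contour: length of the closed polygon through
# every `step`-th contour point. Subsampling removes most of the
# staircase-length bias of raw 8-connected chain codes, so large discs
# score near 1 and axis-aligned squares near pi/4 on circularity.
contour_perimeter <- function(contour, step = 4L) {
  n <- nrow(contour)
  if (n <= 1) return(4)
  if (n <= 2 * step) step <- 1L
  idx <- seq(1L, n, by = step)
  pts <- contour[idx, , drop = FALSE]
  nxt <- rbind(pts[-1, , drop = FALSE], pts[1, , drop = FALSE])
  sum(sqrt(rowSums((pts - nxt)^2)))
}

#' Circularity of a binary shape
#'
#' `4 * pi * area / perimeter^2`, clamped to `[0, 1]`: 1 for a perfect
#' circle, smaller for irregular shapes. The perimeter is measured as the
#' length of the traced boundary polygon subsampled at every 4th contour
#' point, which keeps rasterized discs near 1 and an axis-aligned square
#' near `pi / 4`.
#'
#' @param mask non-empty binary matrix.
#' @return Circularity in `[0, 1]`.
#' @export
circularity <- function(mask) {
  m <- as_binary_mask(mask, "mask")
  area <- sum(m)
  if (area == 0) stop_param("mask is empty")
  ct <- traced_contour(m)
  per <- contour_perimeter(ct)
  clamp(4 * pi * area / per^2, 0, 1)
}

#' Per-frame metrics record
#'
#' Confusion counts, the four overlap metrics, the boundary Hausdorff
#' distance, and the ground-truth shape descriptors (area in pixels,
#' circularity) used for stratification.
#'
#' @param predicted,truth equally-shaped binary masks.
#' @param frame_id frame identifier.
#' @param sequence_id optional sequence identifier.
#' @return One-row data.frame.
#' @export
metrics_record <- function(predicted, truth, frame_id = NA_character_,
                           sequence_id = NA_character_) {
  cc <- confusion_counts(predicted, truth)
  gt_area <- cc$TP + cc$FN
  data.frame(
    frame_id = frame_id, sequence_id = sequence_id,
    TP = cc$TP, FP = cc$FP, FN = cc$FN, TN = cc$TN,
    dice = dice_coefficient(cc),
    precision = precision_score(cc),
    recall = recall_score(cc),
    jaccard = jaccard_index(cc),
    hausdorff = hausdorff_distance(truth, predicted),
    gt_area = gt_area,
    gt_circularity = if (gt_area > 0) circularity(truth) else NA_real_,
    stringsAsFactors = FALSE)
}

assign_group <- function(x, q) {
  ifelse(x < q[1], "Small", ifelse(x > q[2], "Large", "Normal"))
}

#' Assign size and circularity strata
#'
#' Frames are labelled `Small` / `Normal` / `Large` by comparing the
#' ground-truth polyp area (and, independently, circularity) against the
#' 25th and 75th percentiles of the training-corpus distributions
#' (linear-interpolation percentiles).
#'
#' @param records data.frame from [metrics_record()] rows.
#' @param train_areas,train_circularities non-empty reference distributions
#'   from the training corpus.
#' @return `records` with `size_group` and `circularity_group` columns.
#' @export
stratify <- function(records, train_areas, train_circularities) {
  if (length(train_areas) == 0 || length(train_circularities) == 0)
    stop_param("reference distributions must be non-empty")
  qa <- quantile(train_areas, c(0.25, 0.75), type = 7, names = FALSE)
  qc <- quantile(train_circularities, c(0.25, 0.75), type = 7, names = FALSE)
  records$size_group <- assign_group(records$gt_area, qa)
  records$circularity_group <- assign_group(records$gt_circularity, qc)
  records
}

summary_stats <- function(x) {
  x_fin <- x[is.finite(x)]
  n_excl <- sum(!is.finite(x))
  if (length(x_fin) == 0)
    return(list(median = NA_real_, mean = NA_real_, sd = NA_real_,
                q25 = NA_real_, q75 = NA_real_, outliers = numeric(0),
                n = 0L, n_excluded = n_excl))
  q <- quantile(x_fin, c(0.25, 0.75), type = 7, names = FALSE)
  iqr <- q[2] - q[1]
  out <- x_fin[x_fin < q[1] - 1.5 * iqr | x_fin > q[2] + 1.5 * iqr]
  list(median = median(x_fin), mean = mean(x_fin),
       sd = if (length(x_fin) > 1) sd(x_fin) else 0,
       q25 = q[1], q75 = q[2], outliers = out,
       n = length(x_fin), n_excluded = n_excl)
}

#' Grouped metric summaries
#'
#' Per-group median/mean/sd/quartiles and 1.5-IQR outliers for each metric,
#' plus the joint per-frame scatter table (Dice vs Hausdorff, recall vs
#' precision).
#'
#' @param records metrics data.frame (e.g. from [cross_validate()]).
#' @param group_key name of the grouping column (`"fold"`, `"size_group"`,
#'   `"circularity_group"`, ...); `NULL` summarizes all records as one
#'   group. Non-finite Hausdorff sentinels are excluded from the summaries
#'   and counted in `n_excluded`.
#' @param metrics metric columns to summarize.
#' @return An object of class `stratified_summary`: list with `summary`
#'   (data.frame), `outliers` (named list) and `scatter` (per-frame table).
#' @export
summarize_metrics <- function(records, group_key = NULL,
                              metrics = c("dice", "precision", "recall",
                                          "jaccard", "hausdorff")) {
  groups <- if (is.null(group_key)) rep("all", nrow(records))
            else as.character(records[[group_key]])
  if (anyNA(groups)) groups[is.na(groups)] <- "NA"
  rows <- list()
  outliers <- list()
  for (g in sort(unique(groups))) {
    sub <- records[groups == g, , drop = FALSE]
    for (m in metrics) {
      st <- summary_stats(sub[[m]])
      rows[[length(rows) + 1L]] <- data.frame(
        group = g, metric = m, n = st$n, n_excluded = st$n_excluded,
        median = st$median, mean = st$mean, sd = st$sd,
        q25 = st$q25, q75 = st$q75, n_outliers = length(st$outliers),
        stringsAsFactors = FALSE)
      outliers[[paste(g, m, sep = ".")]] <- st$outliers
    }
  }
  scatter <- records[, intersect(
    c("frame_id", "sequence_id", "dice", "hausdorff", "recall", "precision",
      group_key), names(records)), drop = FALSE]
  structure(list(summary = do.call(rbind, rows), outliers = outliers,
                 scatter = scatter),
            class = "stratified_summary")
}

#' @export
print.stratified_summary <- function(x, ...) {
  print(x$summary, digits = 3)
  invisible(x)
}

#' Boxplot / scatter figures for metric summaries
#'
#' Mirrors the study's reporting style: per-group boxplots of a metric and
#' the Dice-Hausdorff / recall-precision scatter. Requires ggplot2.
#'
#' @param records metrics data.frame.
#' @param group_key grouping column name.
#' @param metric metric column for the boxplot.
#' @return A ggplot object (boxplot) or, for `plot_metric_scatter`, a list
#'   of two ggplot objects.
#' @export
plot_metric_boxplot <- function(records, group_key = "fold",
                                metric = "dice") {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop_param("ggplot2 is required for plotting")
  df <- records[is.finite(records[[metric]]), , drop = FALSE]
  ggplot2::ggplot(df, ggplot2::aes(
    x = factor(.data[[group_key]]), y = .data[[metric]])) +
    ggplot2::geom_boxplot(outlier.colour = "red") +
    ggplot2::labs(x = group_key, y = metric)
}

#' @rdname plot_metric_boxplot
#' @export
plot_metric_scatter <- function(records) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop_param("ggplot2 is required for plotting")
  df <- records[is.finite(records$hausdorff), , drop = FALSE]
  list(
    dice_hausdorff = ggplot2::ggplot(df, ggplot2::aes(
      x = hausdorff, y = dice)) + ggplot2::geom_point(alpha = 0.6),
    recall_precision = ggplot2::ggplot(records, ggplot2::aes(
      x = recall, y = precision)) + ggplot2::geom_point(alpha = 0.6))
}
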