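test_that("confusion counts match exhaustive enumeration on a toy pair", {
  p <- matrix(c(1, 1, 0, 0,
                1, 0, 0, 0,
                0, 0, 1, 1,
                0, 0, 0, 0), 4, 4, byrow = TRUE)
  g <- matrix(c(1, 0, 0, 0,
                1, 1, 0, 0,
                0, 0, 0, 1,
                0, 0, 0, 0), 4, 4, byrow = TRUE)
  cc <- confusion_counts(p, g)
  # brute force over all 16 cells
  tp <- 0; fp <- 0; fn <- 0; tn <- 0
  for (i in 1:4) for (j in 1:4) {
    if (p[i, j] == 1 && g[i, j] == 1) tp <- tp + 1
    if (p[i, j] == 1 && g[i, j] == 0) fp <- fp + 1
    if (p[i, j] == 0 && g[i, j] == 1) fn <- fn + 1
    if (p[i, j] == 0 && g[i, j] == 0) tn <- tn + 1
  }
  expect_equal(cc, list(TP = tp, FP = fp, FN = fn, TN = tn))
  expect_equal(cc$TP + cc$FP + cc$FN + cc$TN, 16)
  expect_error(confusion_counts(p, g[1:3, ]), "identical shapes")
  expect_error(confusion_counts(p * 2, g), "binary")
})

test_that("overlap metrics evaluate their defining formulas", {
  cc <- list(TP = 8, FP = 2, FN = 2, TN = 88)
  expect_equal(dice_coefficient(cc), 0.8)
  expect_equal(precision_score(cc), 0.8)
  expect_equal(recall_score(cc), 0.8)
  expect_equal(jaccard_index(cc), 2 / 3)
  perfect <- list(TP = 10, FP = 0, FN = 0, TN = 90)
  expect_equal(dice_coefficient(perfect), 1)
  expect_equal(jaccard_index(perfect), 1)
  # conventions: both masks empty -> 1; exactly one empty -> 0
  empty_both <- list(TP = 0, FP = 0, FN = 0, TN = 100)
  expect_equal(dice_coefficient(empty_both), 1)
  one_empty <- list(TP = 0, FP = 0, FN = 5, TN = 95)
  expect_equal(dice_coefficient(one_empty), 0)
  expect_equal(recall_score(one_empty), 0)
})

test_that("the Jaccard-Dice identity holds to machine precision", {
  set.seed(41)
  for (i in 1:1000) {
    cc <- list(TP = sample(0:50, 1), FP = sample(0:50, 1),
               FN = sample(0:50, 1), TN = 10)
    d <- dice_coefficient(cc)
    j <- jaccard_index(cc)
    expect_equal(j, d / (2 - d), tolerance = 1e-12)
    expect_lte(j, d + 1e-15)
  }
})

test_that("dice is symmetric and precision/recall are transposes", {
  set.seed(43)
  for (i in 1:20) {
    a <- random_mask(12, 12)
    b <- random_mask(12, 12)
    expect_equal(dice_coefficient(confusion_counts(a, b)),
                 dice_coefficient(confusion_counts(b, a)))
    expect_equal(precision_score(confusion_counts(a, b)),
                 recall_score(confusion_counts(b, a)))
  }
})

test_that("hausdorff distance matches the all-pairs oracle", {
  # identical contours -> 0
  d1 <- disc_mask(15, 5)
  expect_equal(hausdorff_distance(d1, d1), 0)
  # two single points at distance d
  a <- matrix(0, 10, 10); a[2, 2] <- 1
  b <- matrix(0, 10, 10); b[2, 6] <- 1
  expect_equal(hausdorff_distance(a, b), 4)
  # square contours offset by (3,0)
  s1 <- square_mask(16, 4, top = 4)
  s2 <- square_mask(16, 4, top = 7)
  expect_equal(hausdorff_distance(s1, s2),
               hausdorff_oracle(mask_boundary(s1), mask_boundary(s2)))
  # random masks up to 16x16 against the R oracle
  set.seed(47)
  for (i in 1:40) {
    h <- sample(3:16, 1); w <- sample(3:16, 1)
    m1 <- random_mask(h, w, 0.4)
    m2 <- random_mask(h, w, 0.4)
    expect_equal(hausdorff_distance(m1, m2),
                 hausdorff_oracle(mask_boundary(m1), mask_boundary(m2)))
  }
  # empty-mask sentinel
  expect_equal(hausdorff_distance(matrix(0, 5, 5), d1[1:5, 1:5]), Inf)
})

test_that("circularity matches closed forms for discs and squares", {
  expect_gte(circularity(disc_mask(101, 40)), 0.9)
  expect_gte(circularity(disc_mask(201, 90)),
             circularity(disc_mask(41, 15)))
  # square of side a: 4*pi*a^2 / (4a)^2 = pi/4
  expect_equal(circularity(square_mask(120, 100)), pi / 4,
               tolerance = 0.05 * pi / 4)
  expect_error(circularity(matrix(0, 5, 5)), "empty")
})

regular_ngon_mask <- function(n_sides, r = 80, canvas = 2 * r + 21) {
  cy <- (canvas + 1) / 2
  th <- seq(0, 2 * pi, length.out = n_sides + 1)[-(n_sides + 1)] + pi / 7
  vy <- cy + r * sin(th); vx <- cy + r * cos(th)
  yy <- matrix(seq_len(canvas), canvas, canvas)
  xx <- t(yy)
  inside <- matrix(TRUE, canvas, canvas)
  for (i in seq_len(n_sides)) {
    j <- if (i == n_sides) 1 else i + 1
    inside <- inside &
      ((vx[j] - vx[i]) * (yy - vy[i]) - (vy[j] - vy[i]) * (xx - vx[i]) >= 0)
  }
  inside * 1
}

test_that("circularity of regular polygons increases with side count", {
  circs <- vapply(c(3, 4, 6, 12), function(n)
    circularity(regular_ngon_mask(n)), numeric(1))
  expect_true(all(diff(circs) >= 0))
  expect_gt(circs[4], circs[1])
  expect_gt(circs[4], 0.9)  # 12-gon is nearly circular
})

test_that("metrics are invariant to a common translation of both masks", {
  m1 <- disc_mask(40, 8, center = c(15, 15))
  m2 <- square_mask(40, 12, top = 10)
  shift <- function(m, dy, dx) {
    out <- matrix(0, nrow(m), ncol(m))
    out[(1 + dy):nrow(m), (1 + dx):ncol(m)] <-
      m[1:(nrow(m) - dy), 1:(ncol(m) - dx)]
    out
  }
  r1 <- metrics_record(m1, m2, "a")
  r2 <- metrics_record(shift(m1, 5, 3), shift(m2, 5, 3), "a")
  for (col in c("dice", "precision", "recall", "jaccard", "hausdorff"))
    expect_equal(r1[[col]], r2[[col]], info = col)
})

test_that("stratification reproduces the quartile split", {
  areas <- 1:100
  recs <- data.frame(frame_id = as.character(1:100), gt_area = areas,
                     gt_circularity = rep(0.5, 100))
  out <- stratify(recs, train_areas = areas,
                  train_circularities = rep(0.5, 100))
  # type-7 percentiles of 1..100 are 25.75 and 75.25
  expect_equal(sum(out$size_group == "Small"), 25)
  expect_equal(sum(out$size_group == "Normal"), 50)
  expect_equal(sum(out$size_group == "Large"), 25)
  # degenerate reference: everything Normal
  expect_true(all(out$circularity_group == "Normal"))
  # groups partition the records
  expect_equal(sum(table(out$size_group)), 100)
})

test_that("summaries report quartiles, outliers and grouping correctly", {
  vals <- c(0.1, 0.2, 0.3, 0.4, 0.5)
  recs <- data.frame(frame_id = letters[1:5], dice = vals,
                     precision = vals, recall = vals, jaccard = vals,
                     hausdorff = c(1, 2, 3, 4, 200), grp = "A")
  sm <- summarize_metrics(recs, "grp")
  dice_row <- sm$summary[sm$summary$metric == "dice", ]
  expect_equal(dice_row$median, 0.3)
  expect_equal(dice_row$q25, unname(quantile(vals, 0.25)))
  expect_equal(dice_row$q75, unname(quantile(vals, 0.75)))
  h_row <- sm$summary[sm$summary$metric == "hausdorff", ]
  expect_equal(h_row$n_outliers, 1)  # the 200 is beyond 1.5 IQR
  # single record: median = mean = value, sd 0
  one <- summarize_metrics(recs[1, ], NULL)
  d1 <- one$summary[one$summary$metric == "dice", ]
  expect_equal(d1$median, 0.1)
  expect_equal(d1$mean, 0.1)
  expect_equal(d1$sd, 0)
  # two groups keyed independently
  recs$grp <- c("A", "A", "B", "B", "B")
  sm2 <- summarize_metrics(recs, "grp")
  expect_setequal(unique(sm2$summary$group), c("A", "B"))
  # Inf sentinels excluded with a count
  recs$hausdorff[1] <- Inf
  sm3 <- summarize_metrics(recs, NULL)
  h3 <- sm3$summary[sm3$summary$metric == "hausdorff", ]
  expect_equal(h3$n_excluded, 1)
  expect_true(is.finite(h3$mean))
})

test_that("metrics_record carries counts, shape descriptors and sentinels", {
  g <- disc_mask(30, 8)
  p <- disc_mask(30, 8, center = c(14, 16))
  rec <- metrics_record(p, g, "f7", "s1")
  expect_equal(rec$gt_area, sum(g))
  expect_gt(rec$gt_circularity, 0.85)
  expect_true(rec$TP + rec$FP + rec$FN + rec$TN == 900)
  # empty prediction: Dice 0, Hausdorff Inf
  rec0 <- metrics_record(matrix(0, 30, 30), g, "f8")
  expect_equal(rec0$dice, 0)
  expect_equal(rec0$hausdorff, Inf)
})
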