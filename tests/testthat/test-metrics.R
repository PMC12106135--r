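# Segmentation metrics against set-arithmetic and all-pairs-distance oracles,
# plus the fold aggregation conventions.

test_that("dice and iou match their definitions and conventions", {
  m <- random_mask(8, p_empty = 0)
  expect_equal(dice(mask_pair(m, m)), 1)
  expect_equal(iou(mask_pair(m, m)), 1)

  P <- matrix(0L, 2, 2); P[1, 1] <- 1L; P[1, 2] <- 1L
  G <- matrix(0L, 2, 2); G[1, 1] <- 1L; G[2, 1] <- 1L
  expect_equal(dice(mask_pair(P, G)), 0.5)
  expect_equal(iou(mask_pair(P, G)), 1 / 3)

  A <- matrix(0L, 3, 3); A[1, 1] <- 1L
  B <- matrix(0L, 3, 3); B[3, 3] <- 1L
  expect_equal(dice(mask_pair(A, B)), 0)

  z <- matrix(0L, 4, 4)
  expect_equal(dice(mask_pair(z, z)), 1)
  expect_equal(iou(mask_pair(z, z)), 1)
})

test_that("overlap metrics equal brute-force oracles on random mask pairs", {
  withr::with_seed(20, {
    for (i in 1:25) {
      P <- random_mask(16)
      G <- random_mask(16)
      pr <- mask_pair(P, G)
      expect_equal(dice(pr), oracle_dice(P, G), tolerance = 1e-9)
      expect_equal(iou(pr), oracle_iou(P, G), tolerance = 1e-9)
      expect_equal(volumetric_similarity(pr), oracle_vs(P, G), tolerance = 1e-9)
      d <- dice(pr)
      expect_equal(iou(pr), d / (2 - d), tolerance = 1e-9)
      expect_gte(d, iou(pr))
    }
  })
})

test_that("percentile Hausdorff distance matches the all-pairs oracle", {
  P <- matrix(0L, 8, 8); P[1, 1] <- 1L
  G <- matrix(0L, 8, 8); G[4, 5] <- 1L   # offset (3, 4): distance 5
  expect_equal(hausdorff95(mask_pair(P, G)), 5)
  expect_equal(hausdorff95(mask_pair(P, G), percentile = 100), 5)

  m <- random_mask(16, p_empty = 0)
  expect_equal(hausdorff95(mask_pair(m, m)), 0)

  withr::with_seed(21, {
    for (i in 1:20) {
      A <- random_mask(16, p_empty = 0)
      B <- random_mask(16, p_empty = 0)
      if (sum(A) == 0 || sum(B) == 0) next
      pr <- mask_pair(A, B)
      expect_equal(hausdorff95(pr), oracle_hd(A, B), tolerance = 1e-9)
      expect_equal(hausdorff95(pr, percentile = 100), oracle_hd(A, B, 100),
                   tolerance = 1e-9)
      # monotone non-decreasing in the percentile
      qs <- vapply(c(50, 75, 95, 100),
                   function(q) hausdorff95(pr, percentile = q), numeric(1))
      expect_true(all(diff(qs) >= -1e-12))
    }
  })

  expect_warning(h <- hausdorff95(mask_pair(matrix(0, 4, 4), random_mask(4, 0))),
                 "empty")
  expect_true(is.na(h))
})

test_that("spacing converts Hausdorff distances to millimetres", {
  P <- matrix(0L, 8, 8); P[1, 1] <- 1L
  G <- matrix(0L, 8, 8); G[1, 4] <- 1L
  expect_equal(hausdorff95(mask_pair(P, G, spacing = c(1, 0.5))), 1.5)
})

test_that("confusion metrics follow the printed 2x2 ratios", {
  # TP=3, FP=1, FN=2, TN=10 laid out on a 4x4 grid
  P <- matrix(c(rep(1, 4), rep(0, 12)), 4, 4)
  G <- matrix(c(rep(1, 3), 0, 1, 1, rep(0, 10)), 4, 4)
  cm <- confusion_metrics(mask_pair(P, G))
  expect_equal(cm$sensitivity, 0.6)
  expect_equal(cm$specificity, 10 / 11)
  expect_equal(cm$accuracy, 13 / 16)

  m <- random_mask(8, p_empty = 0)
  cm2 <- confusion_metrics(mask_pair(m, m))
  expect_equal(c(cm2$accuracy, cm2$sensitivity, cm2$specificity), c(1, 1, 1))

  cm3 <- confusion_metrics(mask_pair(1 - m, m))
  expect_equal(cm3$sensitivity, 0)
  expect_equal(cm3$specificity, 0)
})

test_that("volumetric similarity depends only on volumes", {
  P <- matrix(0L, 10, 10); P[1:3, 1:10] <- 1L  # 30 px
  G <- matrix(0L, 10, 10); G[6:10, 1:10] <- 1L # 50 px
  expect_equal(volumetric_similarity(mask_pair(P, G)), 0.75)
  G2 <- matrix(0L, 10, 10); G2[8:10, 1:10] <- 1L # same volume, no overlap
  expect_equal(volumetric_similarity(mask_pair(P, G2)), 1)
  expect_equal(volumetric_similarity(mask_pair(matrix(0, 4, 4), random_mask(4, 0))),
               0)
})

test_that("metrics are invariant to simultaneous flips and match 3-D on one slice", {
  withr::with_seed(22, {
    P <- random_mask(12, p_empty = 0); G <- random_mask(12, p_empty = 0)
    pr <- mask_pair(P, G)
    fl <- mask_pair(P[12:1, ], G[12:1, ])
    expect_equal(dice(fl), dice(pr))
    expect_equal(iou(fl), iou(pr))
    expect_equal(hausdorff95(fl), hausdorff95(pr))

    P3 <- array(P, c(12, 12, 1)); G3 <- array(G, c(12, 12, 1))
    expect_equal(dice(mask_pair(P3, G3)), dice(pr))
    expect_equal(hausdorff95(mask_pair(P3, G3)), hausdorff95(pr))
  })
})

test_that("fold aggregation follows the slice and scan conventions", {
  t1 <- tibble::tibble(fold = 1L, dice = c(0.6, 0.8), iou = c(0.5, 0.6),
                       hd95 = c(1, 3), accuracy = 1, sensitivity = 1,
                       specificity = 1, vs = 1)
  t2 <- dplyr::mutate(t1, fold = 2L, dice = c(0.7, 0.9), hd95 = c(2, 2))
  agg <- aggregate_folds(list(t1, t2), mode = "slice")
  d <- agg[agg$metric == "dice", ]
  expect_equal(d$mean, 0.75)
  expect_equal(d$spread, stats::sd(c(0.7, 0.8)), tolerance = 1e-9)
  expect_equal(d$spread, 0.0707107, tolerance = 1e-6)

  # scan mode: spread is the mean of fold-wise sds
  agg2 <- aggregate_folds(list(t1, t2), mode = "scan")
  d2 <- agg2[agg2$metric == "dice", ]
  expect_equal(d2$spread, mean(c(stats::sd(c(0.6, 0.8)), stats::sd(c(0.7, 0.9)))))

  # single fold: zero spread in slice mode
  agg1 <- aggregate_folds(t1, mode = "slice")
  expect_equal(agg1$spread[agg1$metric == "dice"], 0)

  # permutation invariance
  agg3 <- aggregate_folds(list(t2, t1), mode = "slice")
  expect_equal(agg3, agg)

  expect_error(aggregate_folds(t1[0, ], mode = "slice"), "empty")
})

test_that("metrics_report tabulates per-unit rows and flags excluded HD", {
  withr::with_seed(23, {
    pairs <- list(
      mask_pair(random_mask(8, 0), random_mask(8, 0)),
      mask_pair(matrix(0L, 8, 8), random_mask(8, 0))
    )
    tab <- suppressWarnings(metrics_report(pairs, ids = c("a", "b")))
    expect_equal(nrow(tab), 2)
    expect_true(is.na(tab$hd95[2]))
    expect_equal(attr(tab, "hd95_excluded"), 1L)
    expect_true(all(c("dice", "iou", "hd95", "accuracy", "sensitivity",
                      "specificity", "vs") %in% names(tab)))
  })
})
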