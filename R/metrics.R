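# Slice- and scan-level segmentation metrics: Dice, IoU, 95th-percentile
# Hausdorff distance, confusion metrics, volumetric similarity, and the
# fold-wise aggregation conventions used for reporting.

#' Construct a prediction/ground-truth mask pair
#'
#' @param P Predicted binary mask (2-D slice or 3-D scan).
#' @param GT Ground-truth binary mask of the same shape.
#' @param spacing Optional voxel spacing in mm (length 2 or 3); when supplied,
#'   Hausdorff distances are reported in mm.
#' @return A `mask_pair` object.
#' @export
mask_pair <- function(P, GT, spacing = NULL) {
  P <- (as.array(P) > 0) * 1L
  GT <- (as.array(GT) > 0) * 1L
  if (!identical(dim(P), dim(GT))) stop("P and GT shapes differ", call. = FALSE)
  structure(list(P = P, GT = GT, spacing = spacing), class = "mask_pair")
}

as_mask_pair <- function(pair) {
  if (inherits(pair, "mask_pair")) pair else do.call(mask_pair, pair)
}

#' Dice similarity coefficient
#'
#' `2 |P intersect GT| / (|P| + |GT|)`. When both masks are empty the pair is
#' a correctly predicted negative and the conventional value 1 is returned.
#'
#' @param pair A [mask_pair()].
#' @return Dice in `[0, 1]`.
#' @export
dice <- function(pair) {
  pair <- as_mask_pair(pair)
  s <- sum(pair$P) + sum(pair$GT)
  if (s == 0) return(1)
  2 * sum(pair$P * pair$GT) / s
}

#' Intersection over union (Jaccard index)
#'
#' `|P intersect GT| / |P union GT|`; 1 when both masks are empty.
#'
#' @inheritParams dice
#' @return IoU in `[0, 1]`.
#' @export
iou <- function(pair) {
  pair <- as_mask_pair(pair)
  inter <- sum(pair$P * pair$GT)
  uni <- sum(pair$P) + sum(pair$GT) - inter
  if (uni == 0) return(1)
  inter / uni
}

# Boundary voxel coordinates (rows of a matrix, one column per dimension).
# 2-D: 4-neighbour connectivity; 3-D: 6-neighbour.
boundary_coords <- function(m) {
  m <- (as.array(m) > 0) * 1L
  d <- dim(m)
  # a single-slice stack reduces to the 2-D definition
  if (length(d) == 3L && d[3] == 1L) {
    m <- matrix(m, d[1], d[2])
    d <- dim(m)
  }
  if (length(d) == 2L) {
    return(which(boundary_pixels(m) == 1L, arr.ind = TRUE))
  }
  pad <- array(0L, d + 2L)
  pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- m
  ctr <- function(dr, dc, dk) {
    pad[(2 + dr):(d[1] + 1 + dr), (2 + dc):(d[2] + 1 + dc),
        (2 + dk):(d[3] + 1 + dk), drop = FALSE]
  }
  nb0 <- (ctr(-1, 0, 0) == 0) | (ctr(1, 0, 0) == 0) |
    (ctr(0, -1, 0) == 0) | (ctr(0, 1, 0) == 0) |
    (ctr(0, 0, -1) == 0) | (ctr(0, 0, 1) == 0)
  which(m == 1L & nb0, arr.ind = TRUE)
}

# For each row of `a`, the distance to the nearest row of `b` (coordinates
# already scaled to physical units). Chunked to bound memory.
nn_dists <- function(a, b, chunk = 2048L) {
  nb <- nrow(b)
  bb <- rowSums(b * b)
  out <- numeric(nrow(a))
  i <- 1L
  while (i <= nrow(a)) {
    j <- min(i + chunk - 1L, nrow(a))
    ai <- a[i:j, , drop = FALSE]
    d2 <- outer(rowSums(ai * ai), bb, "+") - 2 * tcrossprod(ai, b)
    out[i:j] <- sqrt(pmax(apply(d2, 1, min), 0))
    i <- j + 1L
  }
  out
}

#' Percentile Hausdorff distance between mask boundaries
#'
#' Pools the directed nearest-neighbour boundary distances `d(P -> GT)` and
#' `d(GT -> P)` and returns their `percentile`-th percentile under the
#' linear-interpolation percentile rule (R quantile type 7);
#' `percentile = 100` is the classical Hausdorff maximum. Boundaries use
#' 4-neighbour (2-D) / 6-neighbour (3-D) connectivity. Distances are in
#' pixels, or mm when the pair carries spacing.
#'
#' @inheritParams dice
#' @param percentile Percentile in `(0, 100]` (default 95).
#' @return Distance; `NA` (with a warning) when either mask is empty.
#' @export
hausdorff95 <- function(pair, percentile = 95) {
  pair <- as_mask_pair(pair)
  if (sum(pair$P) == 0 || sum(pair$GT) == 0) {
    warning("hausdorff95 undefined for an empty mask; returning NA")
    return(NA_real_)
  }
  bp <- boundary_coords(pair$P)
  bg <- boundary_coords(pair$GT)
  if (!is.null(pair$spacing)) {
    sp <- pair$spacing[seq_len(ncol(bp))]
    bp <- sweep(bp, 2, sp, "*")
    bg <- sweep(bg, 2, sp, "*")
  }
  pooled <- c(nn_dists(bp, bg), nn_dists(bg, bp))
  unname(stats::quantile(pooled, percentile / 100, type = 7))
}

#' Pixelwise confusion metrics
#'
#' Accuracy `(TP + TN) / N`, sensitivity `TP / (TP + FN)` and specificity
#' `TN / (TN + FP)`. A zero denominator (e.g. sensitivity on a negative
#' slice) returns the both-empty convention value 1, flagged in the result.
#'
#' @inheritParams dice
#' @return Named list with `accuracy`, `sensitivity`, `specificity` and
#'   `degenerate` (logical flag).
#' @export
confusion_metrics <- function(pair) {
  pair <- as_mask_pair(pair)
  tp <- sum(pair$P * pair$GT)
  fp <- sum(pair$P * (1 - pair$GT))
  fn <- sum((1 - pair$P) * pair$GT)
  tn <- sum((1 - pair$P) * (1 - pair$GT))
  degenerate <- (tp + fn) == 0 || (tn + fp) == 0
  list(
    accuracy = (tp + tn) / (tp + tn + fp + fn),
    sensitivity = if ((tp + fn) == 0) 1 else tp / (tp + fn),
    specificity = if ((tn + fp) == 0) 1 else tn / (tn + fp),
    degenerate = degenerate
  )
}

#' Volumetric similarity
#'
#' `1 - ||P| - |GT|| / (|P| + |GT|)`: agreement of total segmented volume,
#' ignoring overlap. Both-empty pairs return 1 by convention.
#'
#' @inheritParams dice
#' @return VS in `[0, 1]`.
#' @export
volumetric_similarity <- function(pair) {
  pair <- as_mask_pair(pair)
  vp <- sum(pair$P); vg <- sum(pair$GT)
  if (vp + vg == 0) return(1)
  1 - abs(vp - vg) / (vp + vg)
}

#' All metrics for one mask pair
#'
#' @inheritParams dice
#' @return One-row tibble with columns `dice`, `iou`, `hd95`, `accuracy`,
#'   `sensitivity`, `specificity`, `vs`.
#' @export
evaluate_pair <- function(pair) {
  pair <- as_mask_pair(pair)
  cm <- confusion_metrics(pair)
  hd <- if (sum(pair$P) == 0 || sum(pair$GT) == 0) NA_real_ else hausdorff95(pair)
  tibble::tibble(
    dice = dice(pair), iou = iou(pair), hd95 = hd,
    accuracy = cm$accuracy, sensitivity = cm$sensitivity,
    specificity = cm$specificity, vs = volumetric_similarity(pair)
  )
}

#' Per-unit metric table for a set of mask pairs
#'
#' @param pairs List of [mask_pair()]s (or lists with `P`, `GT`).
#' @param ids Optional unit identifiers (slice or scan ids).
#' @param level Aggregation level tag stored in the table.
#' @param fold Optional fold identifier.
#' @return Tibble with one row per unit. Pairs with an empty side have
#'   `hd95 = NA`; their count is reported via the `hd95_excluded` attribute.
#' @export
metrics_report <- function(pairs, ids = NULL, level = c("slice", "scan"),
                           fold = NA_integer_) {
  level <- match.arg(level)
  if (is.null(ids)) ids <- as.character(seq_along(pairs))
  tab <- purrr::map_dfr(seq_along(pairs), function(i) {
    dplyr::mutate(evaluate_pair(pairs[[i]]), id = ids[[i]], .before = 1)
  })
  tab <- dplyr::mutate(tab, level = level, fold = fold)
  attr(tab, "hd95_excluded") <- sum(is.na(tab$hd95))
  tab
}

#' Aggregate per-unit metric tables across folds
#'
#' Slice mode reports the mean of fold-wise means plus/minus the standard
#' deviation of the fold-wise means; scan mode reports the mean of fold-wise
#' means plus/minus the mean of the fold-wise standard deviations. Sample
#' (n - 1) standard deviations throughout; `NA` metric values (undefined
#' Hausdorff distances) are dropped per fold.
#'
#' @param per_unit Tibble as produced by [metrics_report()] (rows from all
#'   folds, `fold` column set), or a list of such tibbles.
#' @param mode `"slice"` or `"scan"`.
#' @param metrics Metric columns to aggregate.
#' @return Tibble with columns `metric`, `mean`, `spread`, `mode`, `n_folds`.
#' @export
aggregate_folds <- function(per_unit, mode = c("slice", "scan"),
                            metrics = c("dice", "iou", "hd95", "accuracy",
                                        "sensitivity", "specificity", "vs")) {
  mode <- match.arg(mode)
  if (is.list(per_unit) && !is.data.frame(per_unit)) {
    per_unit <- dplyr::bind_rows(per_unit)
  }
  if (nrow(per_unit) == 0) stop("empty fold table", call. = FALSE)
  metrics <- intersect(metrics, names(per_unit))
  long <- tidyr::pivot_longer(
    dplyr::select(per_unit, dplyr::all_of(c("fold", metrics))),
    dplyr::all_of(metrics), names_to = "metric", values_to = "value"
  )
  per_fold <- dplyr::summarise(
    dplyr::group_by(long, .data$metric, .data$fold),
    m = mean(.data$value, na.rm = TRUE),
    s = stats::sd(.data$value, na.rm = TRUE),
    .groups = "drop"
  )
  out <- dplyr::summarise(
    dplyr::group_by(per_fold, .data$metric),
    mean = mean(.data$m),
    spread = if (mode == "slice") {
      if (dplyr::n() > 1) stats::sd(.data$m) else 0
    } else {
      mean(.data$s, na.rm = TRUE)
    },
    n_folds = dplyr::n(),
    .groups = "drop"
  )
  out$spread[is.na(out$spread)] <- 0
  dplyr::mutate(out, mode = mode)[match(metrics, out$metric), ]
}
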