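# Inter-observer agreement: reviewer-vs-reviewer (or reviewer-vs-model)
# metric tables with one annotator fixed as the reference, and the same
# agreement binned by lesion size.

as_slice_list <- function(x) {
  if (is.list(x) && !is.matrix(x)) return(lapply(x, as.matrix))
  x <- as.array(x)
  if (length(dim(x)) == 2L) return(list(x))
  lapply(seq_len(dim(x)[3]), function(k) x[, , k])
}

#' Agreement report between two annotation sets
#'
#' Computes per-slice segmentation metrics with `reference` fixed as the
#' ground-truth role (so sensitivity reads "fraction of the reference mask
#' recovered by the comparison annotator") and reports their means.
#'
#' @param reference Reference masks: list of binary matrices or an
#'   `H x W x C` array (Reviewer A role).
#' @param comparison Comparison masks, aligned with `reference` (Reviewer B
#'   or model role).
#' @param ids Optional slice identifiers.
#' @return List with `per_slice` (tibble, one row per slice, plus the
#'   reference lesion pixel count `ref_px`) and `summary` (one-row tibble of
#'   metric means; Hausdorff averaged over the slices where it is defined).
#' @export
agreement_report <- function(reference, comparison, ids = NULL) {
  ref <- as_slice_list(reference)
  cmp <- as_slice_list(comparison)
  stopifnot(length(ref) == length(cmp), length(ref) >= 1)
  pairs <- lapply(seq_along(ref), function(i) mask_pair(cmp[[i]], ref[[i]]))
  tab <- suppressWarnings(metrics_report(pairs, ids = ids, level = "slice"))
  tab$ref_px <- vapply(ref, sum, numeric(1))
  metric_cols <- c("dice", "iou", "hd95", "accuracy", "sensitivity",
                   "specificity", "vs")
  summary <- dplyr::summarise(tab, dplyr::across(dplyr::all_of(metric_cols),
                                                 ~ mean(.x, na.rm = TRUE)))
  list(per_slice = tab, summary = summary)
}

#' Size-binned agreement table
#'
#' Assigns slices to bins by the reference mask's positive-pixel count
#' (half-open on the left; the last bin is unbounded) and reports per-bin
#' mean and sample standard deviation of each metric. Empty bins are absent
#' from the table, not reported as zero.
#'
#' @inheritParams agreement_report
#' @param bins Ascending bin edges; defaults to the lesion-size groups
#'   0-2000, 2000-4000, 4000-6000, 6000-8000 and >= 8000 pixels.
#' @return Tibble with columns `bin`, `n`, `metric`, `mean`, `sd`.
#' @export
size_binned_agreement <- function(reference, comparison,
                                  bins = c(0, 2000, 4000, 6000, 8000, Inf),
                                  ids = NULL) {
  stopifnot(!is.unsorted(bins, strictly = TRUE))
  ar <- agreement_report(reference, comparison, ids = ids)
  tab <- ar$per_slice
  labels <- paste0("[", bins[-length(bins)], ",",
                   ifelse(is.finite(bins[-1]), bins[-1], "Inf"), ")")
  tab$bin <- cut(tab$ref_px, breaks = bins, labels = labels, right = FALSE,
                 include.lowest = FALSE)
  tab <- dplyr::filter(tab, !is.na(.data$bin))
  metric_cols <- c("dice", "iou", "hd95", "accuracy", "sensitivity",
                   "specificity", "vs")
  long <- tidyr::pivot_longer(
    dplyr::select(tab, dplyr::all_of(c("bin", metric_cols))),
    dplyr::all_of(metric_cols), names_to = "metric", values_to = "value")
  dplyr::summarise(
    dplyr::group_by(long, .data$bin, .data$metric),
    n = sum(!is.na(.data$value)),
    mean = mean(.data$value, na.rm = TRUE),
    sd = stats::sd(.data$value, na.rm = TRUE),
    .groups = "drop"
  )
}

#' Simulate a perturbed annotator from reference masks
#'
#' Applies the phantom generator's annotator model (per-lesion morphological
#' boundary jitter of scale `perturb_px`, dropping small lesions with
#' probability `miss_rate`) to arbitrary reference masks. Useful for
#' studying how agreement metrics respond to a known disagreement scale.
#'
#' @param reference List of binary matrices or an `H x W x C` array.
#' @param perturb_px Boundary perturbation scale in pixels.
#' @param miss_rate Miss probability for small lesions.
#' @param miss_area_px Small-lesion footprint threshold (pixels).
#' @param seed Integer seed.
#' @return List of perturbed masks (same layout as a list input).
#' @export
simulate_annotator <- function(reference, perturb_px = 2, miss_rate = 0,
                               miss_area_px = 60, seed = 1L) {
  ref <- as_slice_list(reference)
  with_seed(seed, {
    lapply(ref, perturb_annotator, perturb_px = perturb_px,
           miss_rate = miss_rate, miss_area = miss_area_px)
  })
}

#' Agreement analysis from two mask directories
#'
#' Reads aligned mask sets from two directories (NIfTI volumes or per-slice
#' PNG subdirectories) paired by filename stem and runs
#' [agreement_report()] and [size_binned_agreement()] over all slices.
#'
#' @param dir_a Reference annotator directory (Reviewer A role).
#' @param dir_b Comparison annotator directory.
#' @param bins Size-bin edges (see [size_binned_agreement()]).
#' @return List with `report` (from [agreement_report()]) and `bins`
#'   (from [size_binned_agreement()]).
#' @export
agreement_from_dirs <- function(dir_a, dir_b,
                                bins = c(0, 2000, 4000, 6000, 8000, Inf)) {
  stem <- function(x) sub("\\.nii(\\.gz)?$", "", basename(x))
  list_masks <- function(d) {
    f <- list.files(d, pattern = "\\.nii(\\.gz)?$", full.names = TRUE)
    if (!length(f)) {
      f <- list.dirs(d, recursive = FALSE)
      if (!length(f)) stop("no masks found in ", d, call. = FALSE)
    }
    stats::setNames(f, stem(f))
  }
  fa <- list_masks(dir_a)
  fb <- list_masks(dir_b)
  common <- intersect(names(fa), names(fb))
  if (!length(common)) stop("no matching filename stems", call. = FALSE)
  ref <- list(); cmp <- list(); ids <- character(0)
  for (nm in common) {
    a <- read_masks(fa[[nm]])
    b <- read_masks(fb[[nm]])
    if (!identical(dim(a), dim(b))) {
      stop("shape mismatch for ", nm, call. = FALSE)
    }
    if (length(dim(a)) == 2L) { a <- array(a, c(dim(a), 1)); b <- array(b, c(dim(b), 1)) }
    for (k in seq_len(dim(a)[3])) {
      ref[[length(ref) + 1L]] <- a[, , k]
      cmp[[length(cmp) + 1L]] <- b[, , k]
      ids <- c(ids, sprintf("%s_s%03d", nm, k))
    }
  }
  list(report = agreement_report(ref, cmp, ids = ids),
       bins = size_binned_agreement(ref, cmp, bins = bins, ids = ids))
}
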