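# Synthetic head-CT phantom generator: elliptical skull ring, brain interior,
# hyperdense lesion blobs in the acute-blood HU band, Gaussian noise,
# per-scan DICOM rescale metadata, ground-truth masks and a correlated
# second annotator. Gives every other module a realistic, fully seeded input
# with no data download.

#' Phantom dataset specification
#'
#' Defaults emulate the acute-hematoma data regime: roughly 80% positive
#' scans, lesions in the 50-90 HU band over 30 HU brain tissue inside a
#' approximately 900 HU skull ring, lesion footprints spanning the size range
#' whose quartiles (rescaled to the phantom resolution) match clinical
#' hematoma pixel counts, and a second annotator who redraws boundaries with
#' a few pixels of jitter and sometimes misses small lesions.
#'
#' @param n_scans Number of scans.
#' @param slices_per_scan Integer range (min, max) of slices per scan.
#' @param image_size Slice side length in pixels.
#' @param fraction_positive Fraction of scans containing lesions.
#' @param lesions_per_positive_scan Integer range of lesions per positive
#'   scan.
#' @param lesion_area_px Range of peak lesion footprint (pixels per slice).
#' @param lesion_hu Lesion attenuation range (HU).
#' @param brain_hu,skull_hu Brain / skull attenuation (HU).
#' @param noise_sd Gaussian noise standard deviation (HU).
#' @param annotator_perturb_px Boundary perturbation scale of the second
#'   annotator (pixels; 0 reproduces the reference masks).
#' @param miss_rate_small Probability the second annotator misses a lesion
#'   slice smaller than `miss_area_px`.
#' @param miss_area_px Footprint (pixels) below which a lesion slice counts
#'   as small for `miss_rate_small`.
#' @param seed Integer seed.
#' @return A `phantom_spec` list.
#' @export
phantom_spec <- function(n_scans = 10, slices_per_scan = c(6, 10),
                         image_size = 64, fraction_positive = 0.8,
                         lesions_per_positive_scan = c(1, 2),
                         lesion_area_px = c(40, 300),
                         lesion_hu = c(50, 90), brain_hu = 30, skull_hu = 900,
                         noise_sd = 4, annotator_perturb_px = 2,
                         miss_rate_small = 0.2, miss_area_px = 60,
                         seed = 1L) {
  stopifnot(fraction_positive >= 0, fraction_positive <= 1,
            lesion_hu[1] > brain_hu, lesion_area_px[1] <= lesion_area_px[2],
            slices_per_scan[1] <= slices_per_scan[2])
  structure(as.list(environment()), class = "phantom_spec")
}

# smooth irregular blob: thresholded sum of 2-4 Gaussians, clipped to the
# brain interior, targeting `area` pixels
make_blob <- function(size, interior, area, max_tries = 20) {
  rr <- matrix(seq_len(size), size, size)
  cc <- matrix(seq_len(size), size, size, byrow = TRUE)
  inside <- which(interior > 0)
  if (length(inside) < 2 * area) {
    stop("lesion larger than brain interior", call. = FALSE)
  }
  for (try in seq_len(max_tries)) {
    ctr <- inside[sample.int(length(inside), 1)]
    c0 <- c((ctr - 1) %% size + 1, (ctr - 1) %/% size + 1)  # (row, col)
    ng <- sample(2:4, 1)
    sigma <- sqrt(area / pi) * stats::runif(ng, 0.5, 1.0)
    field <- matrix(0, size, size)
    for (gidx in seq_len(ng)) {
      dc <- c0 + stats::rnorm(2, 0, sqrt(area / pi) * 0.5)
      field <- field + exp(-((rr - dc[1])^2 + (cc - dc[2])^2) / (2 * sigma[gidx]^2))
    }
    field[interior == 0] <- 0
    ord <- sort(field[field > 0], decreasing = TRUE)
    if (length(ord) < area) next
    thr <- ord[area]
    m <- (field >= thr & interior > 0) * 1L
    if (sum(m) >= 0.5 * area && sum(m) <= 2 * area) return(m)
  }
  stop("could not place lesion after ", max_tries, " tries", call. = FALSE)
}

head_geometry <- function(size) {
  rr <- matrix(seq_len(size), size, size)
  cc <- matrix(seq_len(size), size, size, byrow = TRUE)
  cy <- (size + 1) / 2; cx <- (size + 1) / 2
  b <- 0.44 * size * stats::runif(1, 0.95, 1.05)  # vertical semi-axis
  a <- 0.35 * size * stats::runif(1, 0.95, 1.05)  # horizontal semi-axis
  rho <- sqrt(((rr - cy) / b)^2 + ((cc - cx) / a)^2)
  list(skull = (rho <= 1 & rho > 0.88) * 1L, interior = (rho <= 0.82) * 1L)
}

# second-annotator mask: per-lesion-slice morphological boundary jitter plus
# dropped small lesions
perturb_annotator <- function(mask, perturb_px, miss_rate, miss_area) {
  if (sum(mask) == 0) return(mask)
  lbl <- EBImage::bwlabel(mask)
  out <- matrix(0L, nrow(mask), ncol(mask))
  for (l in seq_len(max(lbl))) {
    comp <- (lbl == l) * 1L
    a <- sum(comp)
    if (a < miss_area && stats::runif(1) < miss_rate) next
    r <- round(abs(stats::rnorm(1, 0, perturb_px)))
    if (r > 0) {
      brush <- EBImage::makeBrush(2 * r + 1, shape = "disc")
      comp <- if (stats::runif(1) < 0.5) {
        EBImage::dilate(comp, brush)
      } else {
        EBImage::erode(comp, brush)
      }
      comp <- matrix(as.integer(comp > 0), nrow(mask), ncol(mask))
    }
    out <- pmax(out, comp)
  }
  out
}

#' Generate a synthetic phantom dataset
#'
#' Each scan is an elliptical skull ring (at `skull_hu`) around brain tissue
#' (at `brain_hu`), with optional smooth lesion blobs (uniform HU in
#' `lesion_hu`) spanning contiguous slice ranges, plus Gaussian HU noise.
#' Stored values encode HU through a per-scan random rescale intercept
#' (slope 1), so the Hounsfield conversion is exercised nontrivially.
#' Ground-truth masks are the exact painted lesion regions before noise; the
#' second annotator's masks perturb them morphologically. Byte-identical
#' given the same spec (including its seed).
#'
#' @param spec A [phantom_spec()].
#' @return A `phantom_dataset`: list with `scans` (each with `volume`
#'   ([ct_volume()]), `gt` and `annotator_b` mask arrays), and `manifest`
#'   (per-slice tibble with `scan_id`, `slice`, `scan_positive`,
#'   `slice_positive`, `lesion_px`, `slope`, `intercept`).
#' @export
generate_phantom_dataset <- function(spec = phantom_spec()) {
  stopifnot(inherits(spec, "phantom_spec"))
  with_seed(spec$seed, {
    n_pos <- round(spec$n_scans * spec$fraction_positive)
    positive <- c(rep(TRUE, n_pos), rep(FALSE, spec$n_scans - n_pos))
    scans <- vector("list", spec$n_scans)
    manifest <- list()
    for (sc in seq_len(spec$n_scans)) {
      scan_id <- sprintf("scan%03d", sc)
      C <- sample(spec$slices_per_scan[1]:spec$slices_per_scan[2], 1)
      sz <- spec$image_size
      geom <- head_geometry(sz)
      hu <- array(-1000, c(sz, sz, C))
      gt <- array(0L, c(sz, sz, C))
      for (k in seq_len(C)) {
        hu[, , k] <- -1000 + geom$interior * (spec$brain_hu + 1000) +
          geom$skull * (spec$skull_hu + 1000)
      }
      if (positive[sc]) {
        n_les <- sample(spec$lesions_per_positive_scan[1]:spec$lesions_per_positive_scan[2], 1)
        for (l in seq_len(n_les)) {
          area <- round(stats::runif(1, spec$lesion_area_px[1], spec$lesion_area_px[2]))
          span <- sample(1:min(3, C), 1)
          k0 <- sample(seq_len(C - span + 1), 1)
          lhu <- stats::runif(1, spec$lesion_hu[1], spec$lesion_hu[2])
          profile <- if (span == 1) 1 else 0.55 + 0.45 * sin(pi * (seq_len(span) - 0.5) / span)
          blob <- make_blob(sz, geom$interior, area)
          for (j in seq_len(span)) {
            ak <- max(6, round(area * profile[j]))
            if (ak < sum(blob)) {
              # shrink the blob deterministically to the per-slice footprint
              d <- EBImage::distmap(blob, metric = "euclidean")
              thr <- sort(d[d > 0], decreasing = TRUE)[ak]
              bk <- (d >= thr) * 1L
            } else bk <- blob
            k <- k0 + j - 1
            hu[, , k][bk == 1] <- lhu
            gt[, , k] <- pmax(gt[, , k], bk)
          }
        }
      }
      noisy <- hu + array(stats::rnorm(length(hu), 0, spec$noise_sd), dim(hu))
      intercept <- round(stats::runif(1, -1100, -950))
      slope <- 1
      raw <- round((noisy - intercept) / slope)
      raw[raw < 0] <- 0L
      storage.mode(raw) <- "integer"
      ab <- gt
      for (k in seq_len(C)) {
        ab[, , k] <- perturb_annotator(gt[, , k], spec$annotator_perturb_px,
                                       spec$miss_rate_small, spec$miss_area_px)
      }
      scans[[sc]] <- list(
        volume = ct_volume(raw, slope, intercept, spacing = c(1, 1, 5),
                           scan_id = scan_id),
        gt = gt, annotator_b = ab, positive = positive[sc]
      )
      manifest[[sc]] <- tibble::tibble(
        scan_id = scan_id, slice = seq_len(C),
        scan_positive = positive[sc],
        slice_positive = apply(gt, 3, sum) > 0,
        lesion_px = apply(gt, 3, sum),
        slope = slope, intercept = intercept
      )
    }
    structure(list(scans = scans, manifest = dplyr::bind_rows(manifest),
                   spec = spec),
              class = "phantom_dataset")
  })
}

#' @export
print.phantom_dataset <- function(x, ...) {
  m <- x$manifest
  cat(sprintf("<phantom_dataset: %d scans (%d positive), %d slices (%d positive), %dpx>\n",
              length(x$scans), sum(vapply(x$scans, `[[`, logical(1), "positive")),
              nrow(m), sum(m$slice_positive), x$spec$image_size))
  invisible(x)
}

#' Dataset statistics table
#'
#' Counts of positive/negative scans and slices plus the quartiles of
#' positive-pixel counts over positive slices, recomputed from the masks.
#'
#' @param dataset A `phantom_dataset`.
#' @return One-row tibble with `scans_pos`, `scans_neg`, `slices_pos`,
#'   `slices_neg`, `q25`, `q50`, `q75` (quartiles `NA` when no positive
#'   slice exists).
#' @export
dataset_statistics <- function(dataset) {
  counts <- unlist(lapply(dataset$scans, function(s) apply(s$gt, 3, sum)))
  pos <- counts[counts > 0]
  qs <- if (length(pos)) unname(stats::quantile(pos, c(0.25, 0.5, 0.75), type = 7))
        else rep(NA_real_, 3)
  tibble::tibble(
    scans_pos = sum(vapply(dataset$scans, function(s) any(s$gt > 0), logical(1))),
    scans_neg = sum(vapply(dataset$scans, function(s) !any(s$gt > 0), logical(1))),
    slices_pos = sum(counts > 0),
    slices_neg = sum(counts == 0),
    q25 = qs[1], q50 = qs[2], q75 = qs[3]
  )
}

#' Write a phantom dataset to disk
#'
#' One DICOM series per scan (directory of `.dcm` slices), NIfTI mask
#' volumes for the reference and second annotator, and a CSV manifest.
#'
#' @param dataset A `phantom_dataset`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_phantom_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "masks_a"), showWarnings = FALSE)
  dir.create(file.path(dir, "masks_b"), showWarnings = FALSE)
  for (s in dataset$scans) {
    vid <- s$volume$scan_id
    sdir <- file.path(dir, "dicom", vid)
    dir.create(sdir, recursive = TRUE, showWarnings = FALSE)
    series_uid <- paste0(UID_ROOT, ".", utf8ToInt(substr(vid, 5, 5)) %% 10,
                         ".", sub("scan", "", vid))
    for (k in seq_len(dim(s$volume$raw)[3])) {
      write_dicom_slice(
        file.path(sdir, sprintf("slice%03d.dcm", k)),
        s$volume$raw[, , k],
        slope = s$volume$slope, intercept = s$volume$intercept,
        instance_number = k, series_uid = series_uid,
        z = k * s$volume$spacing[3], spacing = s$volume$spacing[1:2]
      )
    }
    write_masks(file.path(dir, "masks_a", paste0(vid, ".nii.gz")), s$gt)
    write_masks(file.path(dir, "masks_b", paste0(vid, ".nii.gz")), s$annotator_b)
  }
  utils::write.csv(dataset$manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(dir)
}
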