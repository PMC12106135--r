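# CT preprocessing: Hounsfield conversion, window/level contrast, orientation
# standardization, size standardization, normalization, and seeded
# training-time augmentation.
#
# Coordinate convention (pinned for all geometric code): matrices are indexed
# (row, col) with the origin at the top-left; angles are in degrees and
# counter-clockwise positive as the image is displayed.

#' Construct a CT volume
#'
#' Bundles a stored-value voxel grid with the DICOM rescale metadata needed to
#' convert it to Hounsfield units (HU).
#'
#' @param raw Integer-valued array `H x W x C` (or `H x W` for a single slice)
#'   of stored pixel values.
#' @param slope Rescale slope (dimensionless, > 0).
#' @param intercept Rescale intercept (HU).
#' @param spacing Optional numeric triple of voxel spacing in mm
#'   (row, col, slice).
#' @param scan_id Scan identifier string.
#' @return An object of class `ct_volume`.
#' @export
ct_volume <- function(raw, slope, intercept, spacing = NULL, scan_id = "scan") {
  if (length(dim(raw)) == 2L) raw <- array(raw, c(dim(raw), 1L))
  stopifnot(length(dim(raw)) == 3L, all(dim(raw) >= 1L))
  if (!is.null(slope) && !is.na(slope) && slope <= 0) {
    stop("rescale slope must be positive", call. = FALSE)
  }
  structure(
    list(raw = raw, slope = slope, intercept = intercept,
         spacing = spacing, scan_id = scan_id),
    class = "ct_volume"
  )
}

#' @export
print.ct_volume <- function(x, ...) {
  d <- dim(x$raw)
  cat(sprintf("<ct_volume %s: %d x %d x %d, slope=%s, intercept=%s>\n",
              x$scan_id, d[1], d[2], d[3],
              format(x$slope), format(x$intercept)))
  invisible(x)
}

#' Convert stored CT values to Hounsfield units
#'
#' Applies the DICOM linear rescale `x * slope + intercept` elementwise.
#'
#' @param volume A [ct_volume()].
#' @return Numeric array of HU values with the shape of `volume$raw`.
#' @export
to_hounsfield <- function(volume) {
  stopifnot(inherits(volume, "ct_volume"))
  if (is.null(volume$slope) || is.na(volume$slope)) {
    stop("missing rescale metadata: slope", call. = FALSE)
  }
  if (is.null(volume$intercept) || is.na(volume$intercept)) {
    stop("missing rescale metadata: intercept", call. = FALSE)
  }
  volume$raw * volume$slope + volume$intercept
}

#' Construct a HU display window
#'
#' @param lower,upper Window bounds in HU; `lower < upper`. The default
#'   `[0, 140]` targets acute blood, which is hyperdense relative to brain.
#' @return A `window_spec` list.
#' @export
window_spec <- function(lower = 0, upper = 140) {
  if (!(is.finite(lower) && is.finite(upper)) || lower >= upper) {
    stop("degenerate window: require lower < upper", call. = FALSE)
  }
  structure(list(lower = lower, upper = upper), class = "window_spec")
}

#' Window/level contrast adjustment
#'
#' Maps HU values into display range: values at or below `lower` to 0, at or
#' above `upper` to 255, and the interior linearly. The result is kept in
#' floating point; quantization to `uint8` happens only on image export.
#'
#' @param hu Numeric array of HU values.
#' @param w A [window_spec()].
#' @return Numeric array in `[0, 255]`, same shape as `hu`.
#' @export
window_contrast <- function(hu, w = window_spec()) {
  stopifnot(inherits(w, "window_spec"))
  out <- 255 * (hu - w$lower) / (w$upper - w$lower)
  out[hu <= w$lower] <- 0
  out[hu >= w$upper] <- 255
  out
}

# ---- geometric warps --------------------------------------------------------

# Inverse-mapping affine warp of a 2-D image. `map_fun(xo, yo)` receives
# centered output coordinates (x right, y up) and returns list(x=, y=) input
# coordinates in the same frame.
warp2d <- function(img, map_fun, interp = c("bilinear", "nearest"), fill = 0) {
  interp <- match.arg(interp)
  H <- nrow(img); W <- ncol(img)
  cy <- (H + 1) / 2; cx <- (W + 1) / 2
  ro <- matrix(seq_len(H), H, W)
  co <- matrix(seq_len(W), H, W, byrow = TRUE)
  xo <- co - cx
  yo <- -(ro - cy)
  mp <- map_fun(xo, yo)
  ci <- mp$x + cx
  ri <- cy - mp$y
  if (interp == "nearest") {
    rn <- round(ri); cn <- round(ci)
    ok <- rn >= 1 & rn <= H & cn >= 1 & cn <= W
    out <- matrix(fill, H, W)
    out[ok] <- img[cbind(rn[ok], cn[ok])]
    return(out)
  }
  r0 <- floor(ri); c0 <- floor(ci)
  fr <- ri - r0; fc <- ci - c0
  pix <- function(r, c) {
    ok <- r >= 1 & r <= H & c >= 1 & c <= W
    v <- matrix(fill, H, W)
    v[ok] <- img[cbind(r[ok], c[ok])]
    v
  }
  (1 - fr) * (1 - fc) * pix(r0, c0) +
    (1 - fr) * fc * pix(r0, c0 + 1) +
    fr * (1 - fc) * pix(r0 + 1, c0) +
    fr * fc * pix(r0 + 1, c0 + 1)
}

# Rotate a 2-D image counter-clockwise (as displayed) by `angle` degrees.
rotate2d <- function(img, angle, interp = "bilinear", fill = 0) {
  th <- angle * pi / 180
  warp2d(img, function(xo, yo) {
    list(x = cos(th) * xo + sin(th) * yo,
         y = -sin(th) * xo + cos(th) * yo)
  }, interp = interp, fill = fill)
}

#' Estimate head orientation from a binary head mask
#'
#' Computes second-order image moments of the mask per slice and returns the
#' angle of the principal (long) axis relative to the vertical image axis,
#' counter-clockwise positive, in `(-90, 90]`. For a volume the per-slice
#' angles of nonempty slices are combined by their median.
#'
#' @param mask Binary matrix or `H x W x C` array (head mask, e.g. thresholded
#'   HU volume).
#' @return Angle in degrees.
#' @export
estimate_orientation <- function(mask) {
  slice_angle <- function(m) {
    idx <- which(m > 0, arr.ind = TRUE)
    if (nrow(idx) < 3L) return(NA_real_)
    x <- idx[, 2] - mean(idx[, 2])
    y <- -(idx[, 1] - mean(idx[, 1]))
    mu20 <- mean(x * x); mu02 <- mean(y * y); mu11 <- mean(x * y)
    phi <- 0.5 * atan2(2 * mu11, mu20 - mu02) * 180 / pi
    a <- phi - 90
    while (a <= -90) a <- a + 180
    while (a > 90) a <- a - 180
    a
  }
  if (length(dim(mask)) == 3L) {
    angs <- apply(mask, 3, slice_angle)
    angs <- angs[!is.na(angs)]
    if (!length(angs)) stop("empty mask: cannot estimate orientation", call. = FALSE)
    # circular-safe median over (-90, 90] via doubling
    a2 <- angs * 2 * pi / 180
    med <- atan2(stats::median(sin(a2)), stats::median(cos(a2))) * 90 / pi
    return(med)
  }
  a <- slice_angle(as.matrix(mask))
  if (is.na(a)) stop("empty mask: cannot estimate orientation", call. = FALSE)
  a
}

#' Rotate image and mask to a standard orientation
#'
#' Rotates both inputs by `-angle` about the image center (so that content at
#' the estimated angle becomes upright). The image is resampled bilinearly,
#' the mask with nearest-neighbour interpolation so it stays binary.
#'
#' @param image Numeric matrix or `H x W x C` array.
#' @param mask Binary matrix/array of the same shape, or `NULL`.
#' @param angle Angle in degrees (see [estimate_orientation()]).
#' @return List with elements `image` and `mask`.
#' @export
apply_affine <- function(image, mask = NULL, angle = 0) {
  stopifnot(is.finite(angle))
  rot_stack <- function(x, interp) {
    if (length(dim(x)) == 3L) {
      out <- x
      for (k in seq_len(dim(x)[3])) out[, , k] <- rotate2d(x[, , k], -angle, interp)
      out
    } else rotate2d(x, -angle, interp)
  }
  list(
    image = rot_stack(image, "bilinear"),
    mask = if (!is.null(mask)) rot_stack(mask, "nearest")
  )
}

#' Standardize a slice to a square target size
#'
#' Dimensions smaller than `target` are zero-padded symmetrically (the extra
#' pixel of an odd difference goes to the bottom/right); larger dimensions are
#' center-cropped (the extra pixel of an odd difference is removed from the
#' bottom/right).
#'
#' @param slice 2-D numeric matrix.
#' @param target Output side length in pixels.
#' @return `target x target` matrix.
#' @export
standardize_size <- function(slice, target = 512) {
  stopifnot(length(dim(slice)) == 2L)
  fit_dim <- function(m, n, along) {
    d <- if (along == 1) nrow(m) else ncol(m)
    if (d == n) return(m)
    if (d < n) {
      lo <- floor((n - d) / 2)
      if (along == 1) {
        rbind(matrix(0, lo, ncol(m)), m, matrix(0, n - d - lo, ncol(m)))
      } else {
        cbind(matrix(0, nrow(m), lo), m, matrix(0, nrow(m), n - d - lo))
      }
    } else {
      lo <- floor((d - n) / 2)
      if (along == 1) m[(lo + 1):(lo + n), , drop = FALSE]
      else m[, (lo + 1):(lo + n), drop = FALSE]
    }
  }
  fit_dim(fit_dim(slice, target, 1), target, 2)
}

#' Min-max intensity normalization
#'
#' Rescales to `[0, 1]` via `(x - min) / (max - min)`. A constant image maps
#' to all zeros (no information to rescale).
#'
#' @param image Numeric array.
#' @return Array of the same shape in `[0, 1]`.
#' @export
minmax_normalize <- function(image) {
  stopifnot(all(is.finite(image)))
  rng <- range(image)
  if (rng[1] == rng[2]) return(image * 0)
  (image - rng[1]) / (rng[2] - rng[1])
}

#' Augmentation specification
#'
#' Each transform is applied independently with probability `probability`;
#' parameter ranges are symmetric about the identity.
#'
#' @param probability Per-transform application probability in `[0, 1]`.
#' @param rotation_deg Maximum |rotation| in degrees.
#' @param zoom Two-element multiplicative zoom range.
#' @param shift_frac Maximum |shift| as a fraction of width/height.
#' @param brightness,contrast Maximum photometric jitter (additive offset /
#'   multiplicative contrast change) as fractions.
#' @param seed Default seed used when [augment()] is called without one.
#' @return An `augment_spec` list.
#' @export
augment_spec <- function(probability = 0.5, rotation_deg = 15,
                         zoom = c(0.9, 1.1), shift_frac = 0.1,
                         brightness = 0.2, contrast = 0.2, seed = 1L) {
  stopifnot(probability >= 0, probability <= 1, length(zoom) == 2L,
            zoom[1] <= zoom[2])
  structure(
    list(probability = probability, rotation_deg = rotation_deg, zoom = zoom,
         shift_frac = shift_frac, brightness = brightness, contrast = contrast,
         seed = as.integer(seed)),
    class = "augment_spec"
  )
}

#' Seeded training-time augmentation
#'
#' Applies horizontal flip, rotation, zoom and shift (identically to image and
#' mask; nearest-neighbour resampling keeps the mask binary) and photometric
#' brightness/contrast jitter (image only), each with probability
#' `spec$probability`. Fully reproducible given `seed`.
#'
#' @param image Numeric matrix in `[0, 1]`.
#' @param mask Binary matrix of the same shape.
#' @param spec An [augment_spec()].
#' @param seed Integer seed; defaults to `spec$seed`.
#' @return List with elements `image` and `mask`.
#' @export
augment <- function(image, mask, spec = augment_spec(), seed = spec$seed) {
  stopifnot(all(dim(image) == dim(mask)))
  with_seed(seed, {
    doit <- stats::runif(6) < spec$probability
    ang <- stats::runif(1, -spec$rotation_deg, spec$rotation_deg)
    zm <- stats::runif(1, spec$zoom[1], spec$zoom[2])
    sx <- stats::runif(1, -spec$shift_frac, spec$shift_frac) * ncol(image)
    sy <- stats::runif(1, -spec$shift_frac, spec$shift_frac) * nrow(image)
    br <- stats::runif(1, -spec$brightness, spec$brightness)
    ct <- 1 + stats::runif(1, -spec$contrast, spec$contrast)

    geo <- function(x, interp) {
      if (doit[1]) x <- x[, rev(seq_len(ncol(x))), drop = FALSE]
      if (doit[2]) x <- rotate2d(x, ang, interp)
      if (doit[3]) x <- warp2d(x, function(xo, yo) list(x = xo / zm, y = yo / zm), interp)
      if (doit[4]) x <- warp2d(x, function(xo, yo) list(x = xo - sx, y = yo - sy), interp)
      x
    }
    img <- geo(image, "bilinear")
    msk <- geo(mask, "nearest")
    if (doit[5]) img <- img + br
    if (doit[6]) img <- (img - mean(img)) * ct + mean(img)
    img <- pmin(pmax(img, 0), 1)
    list(image = img, mask = msk)
  })
}

#' Full CT preprocessing chain
#'
#' HU conversion, window/level contrast, orientation standardization
#' (estimated from the HU volume thresholded at `hu_threshold`), size
#' standardization and min-max normalization, in that order. A ground-truth
#' mask, when supplied, receives the identical geometric transforms with
#' nearest-neighbour resampling.
#'
#' @param volume A [ct_volume()].
#' @param mask Optional binary array matching `volume$raw`.
#' @param window A [window_spec()].
#' @param target Output slice side length.
#' @param orient Apply orientation standardization?
#' @param hu_threshold HU threshold defining the head mask used for
#'   orientation estimation (default 100 HU captures bone).
#' @return List with `image` (`target x target x C`, in `[0, 1]`), `mask`
#'   (same shape or `NULL`) and `angle` (degrees).
#' @export
preprocess_scan <- function(volume, mask = NULL, window = window_spec(),
                            target = 512, orient = TRUE, hu_threshold = 100) {
  hu <- to_hounsfield(volume)
  img <- window_contrast(hu, window)
  ang <- 0
  if (orient) {
    head <- hu >= hu_threshold
    ang <- tryCatch(estimate_orientation(head), error = function(e) 0)
    rt <- apply_affine(img, mask, ang)
    img <- rt$image
    mask <- rt$mask
  }
  C <- dim(img)[3]
  out <- array(0, c(target, target, C))
  mout <- if (!is.null(mask)) array(0L, c(target, target, C))
  for (k in seq_len(C)) {
    out[, , k] <- minmax_normalize(standardize_size(img[, , k], target))
    if (!is.null(mask)) mout[, , k] <- standardize_size(mask[, , k], target)
  }
  list(image = out, mask = mout, angle = ang)
}
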