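# Phantom generator: determinism, manifest bookkeeping, HU structure,
# annotator model, and the DICOM round trip.

test_that("phantom datasets are deterministic and degenerate specs behave", {
  ds1 <- generate_phantom_dataset(tiny_phantom_spec(seed = 50))
  ds2 <- generate_phantom_dataset(tiny_phantom_spec(seed = 50))
  expect_identical(ds1$scans, ds2$scans)
  expect_identical(ds1$manifest, ds2$manifest)

  neg <- phantom_spec(n_scans = 3, slices_per_scan = c(2, 3), image_size = 48,
                      fraction_positive = 0, seed = 51)
  dsn <- generate_phantom_dataset(neg)
  expect_true(all(vapply(dsn$scans, function(s) sum(s$gt) == 0, logical(1))))
  expect_true(all(!dsn$manifest$slice_positive))
  st <- dataset_statistics(dsn)
  expect_equal(st$slices_pos, 0)
  expect_true(is.na(st$q50))
})

test_that("windowing renders lesions brighter than brain tissue", {
  ds <- generate_phantom_dataset(tiny_phantom_spec(seed = 52, n_scans = 6))
  les <- c(); brn <- c()
  for (s in ds$scans) {
    hu <- to_hounsfield(s$volume)
    wimg <- window_contrast(hu, window_spec(0, 140))
    gt <- s$gt
    if (sum(gt) == 0) next
    les <- c(les, mean(wimg[gt == 1]))
    # brain: inside the head, not lesion, HU near brain level
    brain <- hu > 0 & hu < 45 & gt == 0
    brn <- c(brn, mean(wimg[brain]))
  }
  expect_gt(mean(les), mean(brn))
})

test_that("manifest bookkeeping matches an independent recount from the masks", {
  ds <- generate_phantom_dataset(tiny_phantom_spec(seed = 53, n_scans = 5))
  m <- ds$manifest
  for (sc in ds$scans) {
    sub <- m[m$scan_id == sc$volume$scan_id, ]
    expect_equal(nrow(sub), dim(sc$gt)[3])
    expect_equal(sub$lesion_px, unname(apply(sc$gt, 3, sum)))
    expect_equal(sub$slice_positive, unname(apply(sc$gt, 3, sum) > 0))
  }
  st <- dataset_statistics(ds)
  expect_equal(st$slices_pos + st$slices_neg, nrow(m))
  pos_counts <- m$lesion_px[m$lesion_px > 0]
  expect_equal(st$q50, unname(stats::quantile(pos_counts, 0.5, type = 7)))
})

test_that("hand-built slice counts give the expected quartiles", {
  ds <- generate_phantom_dataset(tiny_phantom_spec(seed = 54, n_scans = 3))
  # override masks with known counts
  fake <- ds
  sizes <- c(100, 200, 300)
  for (i in 1:3) {
    g <- array(0L, dim(fake$scans[[i]]$gt))
    g[seq_len(sizes[i])] <- 1L
    fake$scans[[i]]$gt <- g
  }
  st <- dataset_statistics(fake)
  expect_equal(st$q50, 200)
})

test_that("annotator-B agreement decreases monotonically with perturbation", {
  dices <- vapply(c(0, 2, 5), function(perturb) {
    spec <- phantom_spec(n_scans = 4, slices_per_scan = c(3, 4), image_size = 48,
                         fraction_positive = 1, lesion_area_px = c(60, 160),
                         annotator_perturb_px = perturb, miss_rate_small = 0,
                         seed = 55)
    ds <- generate_phantom_dataset(spec)
    ref <- list(); cmp <- list()
    for (s in ds$scans) for (k in seq_len(dim(s$gt)[3])) {
      if (sum(s$gt[, , k]) == 0) next
      ref[[length(ref) + 1]] <- s$gt[, , k]
      cmp[[length(cmp) + 1]] <- s$annotator_b[, , k]
    }
    mean(vapply(seq_along(ref), function(i) {
      dice(mask_pair(cmp[[i]], ref[[i]]))
    }, numeric(1)))
  }, numeric(1))
  expect_equal(dices[1], 1)
  expect_true(all(diff(dices) < 0))
})

test_that("noise never alters the ground-truth masks", {
  spec1 <- tiny_phantom_spec(seed = 56)
  spec2 <- tiny_phantom_spec(seed = 56)
  spec2$noise_sd <- 15
  g1 <- generate_phantom_dataset(spec1)
  g2 <- generate_phantom_dataset(spec2)
  for (i in seq_along(g1$scans)) {
    expect_identical(g1$scans[[i]]$gt, g2$scans[[i]]$gt)
  }
})

test_that("written DICOM series round-trip bit-exactly through the reader", {
  ds <- generate_phantom_dataset(tiny_phantom_spec(seed = 57, n_scans = 2))
  dir <- tempfile("phantom")
  write_phantom_dataset(ds, dir)
  for (s in ds$scans) {
    vol <- read_ct_series(file.path(dir, "dicom", s$volume$scan_id))
    expect_identical(vol$raw, s$volume$raw)
    expect_equal(vol$slope, s$volume$slope)
    expect_equal(vol$intercept, s$volume$intercept)
    # masks round-trip through NIfTI
    gt <- read_masks(file.path(dir, "masks_a", paste0(s$volume$scan_id, ".nii.gz")))
    expect_equal(array(as.integer(gt), dim(gt)), s$volume$raw * 0L + s$gt)
  }
  man <- utils::read.csv(file.path(dir, "manifest.csv"))
  expect_equal(nrow(man), nrow(ds$manifest))
})

test_that("slice order on disk does not affect the assembled volume", {
  ds <- generate_phantom_dataset(tiny_phantom_spec(seed = 58, n_scans = 1))
  s <- ds$scans[[1]]
  dir <- tempfile("scrambled")
  dir.create(dir, recursive = TRUE)
  C <- dim(s$volume$raw)[3]
  # write slices under names whose alphabetical order scrambles acquisition order
  for (k in seq_len(C)) {
    write_dicom_slice(file.path(dir, sprintf("z%03d.dcm", C - k + 1)),
                      s$volume$raw[, , k], slope = 1, intercept = -1000,
                      instance_number = k, series_uid = "1.2.3.4")
  }
  vol <- read_ct_series(dir)
  expect_identical(vol$raw, s$volume$raw)

  # single-slice series
  dir2 <- tempfile("single")
  dir.create(dir2)
  write_dicom_slice(file.path(dir2, "a.dcm"), s$volume$raw[, , 1],
                    slope = 2, intercept = -1024, instance_number = 1,
                    series_uid = "9.8.7")
  v1 <- read_ct_series(dir2)
  expect_equal(dim(v1$raw)[3], 1L)
  expect_equal(v1$slope, 2)

  # mixed series UIDs rejected
  write_dicom_slice(file.path(dir2, "b.dcm"), s$volume$raw[, , 1],
                    slope = 2, intercept = -1024, instance_number = 2,
                    series_uid = "9.8.6")
  expect_error(read_ct_series(dir2), "mixed series UIDs")
})

test_that("our DICOM files parse identically under pydicom", {
  skip_if_not(nzchar(Sys.which("python")), "python not available")
  ds <- generate_phantom_dataset(tiny_phantom_spec(seed = 59, n_scans = 1))
  s <- ds$scans[[1]]
  f <- tempfile(fileext = ".dcm")
  write_dicom_slice(f, s$volume$raw[, , 1], slope = 1,
                    intercept = s$volume$intercept, instance_number = 3,
                    series_uid = "1.2.840.99.1")
  script <- sprintf(
    "import pydicom, json; d = pydicom.dcmread(r'%s');
print(json.dumps({'rows': int(d.Rows), 'cols': int(d.Columns),
 'slope': float(d.RescaleSlope), 'intercept': float(d.RescaleIntercept),
 'inst': int(d.InstanceNumber), 'series': str(d.SeriesInstanceUID),
 'sum': int(d.pixel_array.sum()), 'p00': int(d.pixel_array[0, 0])}))", f)
  out <- tryCatch(system2("python", c("-c", shQuote(script)), stdout = TRUE),
                  warning = function(w) NULL, error = function(e) NULL)
  skip_if(is.null(out) || !length(out), "pydicom unavailable")
  j <- jsonlite::fromJSON(paste(out, collapse = ""))
  expect_equal(j$rows, nrow(s$volume$raw))
  expect_equal(j$slope, 1)
  expect_equal(j$intercept, s$volume$intercept)
  expect_equal(j$inst, 3)
  expect_equal(j$series, "1.2.840.99.1")
  expect_equal(j$sum, sum(s$volume$raw[, , 1]))
  expect_equal(j$p00, s$volume$raw[1, 1, 1])
})
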