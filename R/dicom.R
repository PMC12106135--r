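# Minimal DICOM reader/writer: Explicit VR Little Endian, one file per slice,
# 16-bit unsigned pixel data. Covers the subset of tags the pipeline needs
# (rescale slope/intercept, geometry, ordering); written files carry a
# standard Part-10 preamble and file-meta group so third-party readers accept
# them.

UID_TRANSFER_LE <- "1.2.840.10008.1.2.1"
UID_CT_STORAGE <- "1.2.840.10008.5.1.4.1.1.2"
UID_ROOT <- "1.2.826.0.1.3680043.9.7435"

pad_even <- function(x, pad = " ") {
  if (nchar(x, type = "bytes") %% 2 == 1) paste0(x, pad) else x
}

uint16_bytes <- function(v) writeBin(as.integer(v), raw(), size = 2, endian = "little")
uint32_bytes <- function(v) writeBin(as.integer(v), raw(), size = 4, endian = "little")

dicom_element <- function(group, element, vr, value) {
  hdr <- c(uint16_bytes(group), uint16_bytes(element), charToRaw(vr))
  if (vr %in% c("OB", "OW", "OF", "SQ", "UT", "UN")) {
    body <- value
    c(hdr, as.raw(c(0, 0)), uint32_bytes(length(body)), body)
  } else {
    body <- switch(vr,
      US = uint16_bytes(value),
      UL = uint32_bytes(value),
      {
        b <- charToRaw(as.character(value))
        # UI values are padded to even length with a NUL byte, text with space
        if (length(b) %% 2 == 1) {
          b <- c(b, if (vr == "UI") as.raw(0) else charToRaw(" "))
        }
        b
      }
    )
    c(hdr, uint16_bytes(length(body)), body)
  }
}

#' Write one CT slice as a DICOM file
#'
#' Explicit VR Little Endian with a Part-10 preamble; stored values are
#' 16-bit unsigned integers.
#'
#' @param path Output file path.
#' @param pixels Integer matrix of stored values (rows x cols), values in
#'   `[0, 65535]`.
#' @param slope,intercept Rescale slope/intercept written to the header.
#' @param instance_number 1-based slice index within the series.
#' @param series_uid,sop_uid DICOM UIDs (digits and dots).
#' @param z Slice z-position in mm (ImagePositionPatient).
#' @param spacing Pixel spacing in mm (length 2).
#' @return `path`, invisibly.
#' @export
write_dicom_slice <- function(path, pixels, slope, intercept,
                              instance_number, series_uid,
                              sop_uid = paste0(series_uid, ".", instance_number),
                              z = instance_number, spacing = c(1, 1)) {
  pixels <- as.matrix(pixels)
  if (any(pixels < 0 | pixels > 65535)) {
    stop("stored values must fit unsigned 16-bit", call. = FALSE)
  }
  # pixel data in row-major order, as acquired
  pix <- writeBin(as.integer(t(pixels)), raw(), size = 2, endian = "little")

  meta <- c(
    dicom_element(0x0002, 0x0001, "OB", as.raw(c(0, 1))),
    dicom_element(0x0002, 0x0002, "UI", UID_CT_STORAGE),
    dicom_element(0x0002, 0x0003, "UI", sop_uid),
    dicom_element(0x0002, 0x0010, "UI", UID_TRANSFER_LE),
    dicom_element(0x0002, 0x0012, "UI", paste0(UID_ROOT, ".1"))
  )
  body <- c(
    dicom_element(0x0008, 0x0016, "UI", UID_CT_STORAGE),
    dicom_element(0x0008, 0x0018, "UI", sop_uid),
    dicom_element(0x0008, 0x0060, "CS", "CT"),
    dicom_element(0x0020, 0x000D, "UI", paste0(series_uid, ".0")),
    dicom_element(0x0020, 0x000E, "UI", series_uid),
    dicom_element(0x0020, 0x0013, "IS", as.character(instance_number)),
    dicom_element(0x0020, 0x0032, "DS",
                  paste(c(0, 0, format(z, trim = TRUE)), collapse = "\\")),
    dicom_element(0x0028, 0x0002, "US", 1L),
    dicom_element(0x0028, 0x0004, "CS", "MONOCHROME2"),
    dicom_element(0x0028, 0x0010, "US", nrow(pixels)),
    dicom_element(0x0028, 0x0011, "US", ncol(pixels)),
    dicom_element(0x0028, 0x0030, "DS",
                  paste(format(spacing, trim = TRUE), collapse = "\\")),
    dicom_element(0x0028, 0x0100, "US", 16L),
    dicom_element(0x0028, 0x0101, "US", 16L),
    dicom_element(0x0028, 0x0102, "US", 15L),
    dicom_element(0x0028, 0x0103, "US", 0L),
    dicom_element(0x0028, 0x1052, "DS", format(intercept, trim = TRUE)),
    dicom_element(0x0028, 0x1053, "DS", format(slope, trim = TRUE)),
    dicom_element(0x7FE0, 0x0010, "OW", pix)
  )
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(raw(128), con)
  writeBin(charToRaw("DICM"), con)
  writeBin(c(dicom_element(0x0002, 0x0000, "UL", length(meta)), meta, body), con)
  invisible(path)
}

read_uint <- function(r, i, n) {
  v <- 0
  for (k in seq_len(n)) v <- v + as.integer(r[i + k - 1L]) * 256^(k - 1)
  v
}

#' Read one DICOM slice
#'
#' Parses Explicit VR Little Endian files (the format this package writes).
#'
#' @param path DICOM file path.
#' @return List with `pixels` (integer matrix), `slope`, `intercept`,
#'   `instance_number`, `series_uid`, `z`, `spacing`.
#' @export
read_dicom_slice <- function(path) {
  r <- readBin(path, raw(), file.size(path))
  if (length(r) < 132 || rawToChar(r[129:132]) != "DICM") {
    stop("not a DICOM part-10 file: ", path, call. = FALSE)
  }
  i <- 133L
  tags <- list()
  long_vrs <- c("OB", "OW", "OF", "SQ", "UT", "UN")
  while (i + 7L <= length(r)) {
    group <- read_uint(r, i, 2); element <- read_uint(r, i + 2L, 2)
    vr <- rawToChar(r[(i + 4L):(i + 5L)])
    if (vr %in% long_vrs) {
      len <- read_uint(r, i + 8L, 4)
      val_at <- i + 12L
    } else {
      len <- read_uint(r, i + 6L, 2)
      val_at <- i + 8L
    }
    key <- sprintf("%04x%04x", group, element)
    tags[[key]] <- list(vr = vr, raw = r[seq.int(val_at, length.out = len)])
    i <- val_at + len
  }
  str_tag <- function(key) {
    t <- tags[[key]]
    if (is.null(t)) return(NULL)
    trimws(rawToChar(t$raw[t$raw != as.raw(0)]))
  }
  num_tag <- function(key) {
    s <- str_tag(key)
    if (is.null(s)) NULL else as.numeric(strsplit(s, "\\\\")[[1]])
  }
  us_tag <- function(key) {
    t <- tags[[key]]
    if (is.null(t)) NULL else read_uint(t$raw, 1L, 2)
  }
  rows <- us_tag("00280010"); cols <- us_tag("00280011")
  if (is.null(rows) || is.null(cols)) stop("missing Rows/Columns in ", path, call. = FALSE)
  slope <- num_tag("00281053"); intercept <- num_tag("00281052")
  pix_raw <- tags[["7fe00010"]]
  if (is.null(pix_raw)) stop("missing PixelData in ", path, call. = FALSE)
  vals <- readBin(pix_raw$raw, integer(), n = rows * cols, size = 2,
                  signed = FALSE, endian = "little")
  ipp <- num_tag("00200032")
  list(
    pixels = matrix(vals, rows, cols, byrow = TRUE),
    slope = if (is.null(slope)) NA_real_ else slope,
    intercept = if (is.null(intercept)) NA_real_ else intercept,
    instance_number = {
      s <- str_tag("00200013"); if (is.null(s)) NA_integer_ else as.integer(s)
    },
    series_uid = str_tag("0020000e"),
    z = if (is.null(ipp)) NA_real_ else ipp[3],
    spacing = num_tag("00280030")
  )
}

#' Read a DICOM series into a CT volume
#'
#' One file per slice; slices are sorted by InstanceNumber, falling back to
#' the ImagePositionPatient z-component. In-series shape or SeriesInstanceUID
#' inconsistencies are rejected.
#'
#' @param directory Directory containing `.dcm` files of one series.
#' @return A [ct_volume()].
#' @export
read_ct_series <- function(directory) {
  files <- sort(list.files(directory, pattern = "\\.dcm$", full.names = TRUE))
  if (!length(files)) stop("no DICOM files in ", directory, call. = FALSE)
  slices <- lapply(files, read_dicom_slice)
  uids <- unique(vapply(slices, function(s) s$series_uid %||% "", character(1)))
  if (length(uids) > 1) {
    stop("mixed series UIDs in ", directory, ": ",
         paste(uids, collapse = ", "), call. = FALSE)
  }
  dims <- vapply(slices, function(s) dim(s$pixels), integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    stop("inconsistent slice shapes in ", directory, call. = FALSE)
  }
  inst <- vapply(slices, function(s) as.numeric(s$instance_number), numeric(1))
  ord <- if (!anyNA(inst)) order(inst) else {
    order(vapply(slices, function(s) s$z, numeric(1)))
  }
  slices <- slices[ord]
  raw <- array(0L, c(dims[1, 1], dims[2, 1], length(slices)))
  for (k in seq_along(slices)) raw[, , k] <- slices[[k]]$pixels
  s1 <- slices[[1]]
  if (is.na(s1$slope) || is.na(s1$intercept)) {
    stop("missing rescale metadata (slope/intercept) in ", directory,
         call. = FALSE)
  }
  sp <- s1$spacing
  ct_volume(raw, slope = s1$slope, intercept = s1$intercept,
            spacing = if (!is.null(sp)) c(sp, 1),
            scan_id = basename(directory))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
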