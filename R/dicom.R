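# Minimal DICOM series reader: single-frame grayscale slices, little-endian
# transfer syntaxes (implicit 1.2.840.10008.1.2 and explicit 1.2.840.10008.1.2.1),
# uncompressed 8/16-bit pixel data. Covers clinical axial T1 exports; anything
# else errors with the offending file name.

DICOM_EXPLICIT_LE <- "1.2.840.10008.1.2.1"
DICOM_IMPLICIT_LE <- "1.2.840.10008.1.2"

read_u16 <- function(raw, pos) {
  as.integer(raw[pos]) + 256L * as.integer(raw[pos + 1L])
}
read_u32 <- function(raw, pos) {
  as.numeric(raw[pos]) + 256 * as.numeric(raw[pos + 1L]) +
    65536 * as.numeric(raw[pos + 2L]) + 16777216 * as.numeric(raw[pos + 3L])
}

# VRs with a 2-byte reserved field and 4-byte length in explicit encoding
LONG_VRS <- c("OB", "OW", "OF", "OD", "OL", "SQ", "UC", "UR", "UT", "UN")

# Parse one element at `pos`; returns list(group, elem, bytes, next_pos).
dicom_element <- function(raw, pos, explicit) {
  group <- read_u16(raw, pos)
  elem <- read_u16(raw, pos + 2L)
  if (explicit && group != 0xFFFE) {
    vr <- rawToChar(raw[(pos + 4L):(pos + 5L)])
    if (vr %in% LONG_VRS) {
      len <- read_u32(raw, pos + 8L)
      hdr <- 12L
    } else {
      len <- read_u16(raw, pos + 6L)
      hdr <- 8L
    }
  } else {
    vr <- NA_character_
    len <- read_u32(raw, pos + 4L)
    hdr <- 8L
  }
  if (len == 4294967295) stop("undefined-length DICOM elements are not supported")
  val <- if (len > 0) raw[(pos + hdr):(pos + hdr + len - 1L)] else raw(0)
  list(group = group, elem = elem, vr = vr, bytes = val,
       next_pos = pos + hdr + len)
}

dicom_str <- function(bytes) {
  bytes <- bytes[bytes != as.raw(0)]  # strip NUL padding
  sub(" +$", "", rawToChar(bytes))
}
dicom_nums <- function(bytes) as.numeric(strsplit(dicom_str(bytes), "\\\\")[[1]])

# Read the tags this package needs from one DICOM file.
read_dicom_file <- function(path) {
  raw <- readBin(path, "raw", n = file.info(path)$size)
  if (length(raw) < 160 || rawToChar(raw[129:132]) != "DICM")
    stop(sprintf("'%s' is not a DICOM part-10 file", path))
  pos <- 133L
  # file meta group (0002,xxxx) is always explicit little endian
  ts <- NULL
  meta_end <- NA
  while (pos < length(raw)) {
    el <- dicom_element(raw, pos, explicit = TRUE)
    if (el$group != 2L) break
    if (el$elem == 0L) meta_end <- el$next_pos + read_u32(el$bytes, 1L)
    if (el$elem == 16L) ts <- dicom_str(el$bytes)
    pos <- el$next_pos
    if (!is.na(meta_end) && pos >= meta_end) break
  }
  if (is.null(ts)) stop(sprintf("'%s': missing transfer syntax UID", path))
  explicit <- ts == DICOM_EXPLICIT_LE
  if (!explicit && ts != DICOM_IMPLICIT_LE)
    stop(sprintf("'%s': unsupported transfer syntax %s", path, ts))

  out <- list(path = path, rescale_slope = 1, rescale_intercept = 0,
              pixel_representation = 0L)
  while (pos < length(raw)) {
    el <- dicom_element(raw, pos, explicit)
    key <- sprintf("%04X%04X", el$group, el$elem)
    switch(key,
      "00200013" = out$instance <- as.integer(dicom_str(el$bytes)),
      "00200032" = out$position <- dicom_nums(el$bytes),
      "00180050" = out$slice_thickness <- dicom_nums(el$bytes)[1],
      "00180088" = out$slice_spacing <- dicom_nums(el$bytes)[1],
      "00280010" = out$rows <- read_u16(el$bytes, 1L),
      "00280011" = out$cols <- read_u16(el$bytes, 1L),
      "00280030" = out$pixel_spacing <- dicom_nums(el$bytes),
      "00280100" = out$bits_allocated <- read_u16(el$bytes, 1L),
      "00280103" = out$pixel_representation <- read_u16(el$bytes, 1L),
      "00281052" = out$rescale_intercept <- dicom_nums(el$bytes)[1],
      "00281053" = out$rescale_slope <- dicom_nums(el$bytes)[1],
      "7FE00010" = out$pixel_bytes <- el$bytes
    )
    pos <- el$next_pos
  }
  for (f in c("rows", "cols", "pixel_spacing", "bits_allocated", "pixel_bytes"))
    if (is.null(out[[f]]))
      stop(sprintf("'%s': required DICOM field %s missing", path, f))
  n <- out$rows * out$cols
  if (out$bits_allocated == 16L) {
    px <- readBin(out$pixel_bytes, "integer", n = n, size = 2,
                  signed = out$pixel_representation == 1L, endian = "little")
  } else if (out$bits_allocated == 8L) {
    px <- as.integer(out$pixel_bytes[seq_len(n)])
  } else {
    stop(sprintf("'%s': unsupported bits allocated %d", path, out$bits_allocated))
  }
  if (length(px) < n) stop(sprintf("'%s': truncated pixel data", path))
  # DICOM pixel order is row-major (row = y anterior->posterior, col = x)
  out$pixels <- t(matrix(out$rescale_slope * px + out$rescale_intercept,
                         nrow = out$cols, ncol = out$rows))
  out
}

# Assemble a directory of single-frame DICOM files into an image_volume.
read_dicom_series <- function(path) {
  files <- list.files(path, full.names = TRUE)
  files <- files[!dir.exists(files)]
  if (length(files) == 0)
    stop(sprintf("cannot read DICOM series: no files in '%s'", path))
  slices <- lapply(files, read_dicom_file)
  rows <- unique(vapply(slices, `[[`, 1L, "rows"))
  cols <- unique(vapply(slices, `[[`, 1L, "cols"))
  if (length(rows) != 1L || length(cols) != 1L)
    stop(sprintf("DICOM series '%s': slices disagree on matrix size", path))
  zpos <- vapply(slices, function(s)
    if (!is.null(s$position)) s$position[3] else NA_real_, 0)
  if (all(is.finite(zpos))) {
    ord <- order(zpos)
  } else {
    inst <- vapply(slices, function(s)
      if (!is.null(s$instance)) s$instance else NA_integer_, 0L)
    if (any(is.na(inst)))
      stop(sprintf("DICOM series '%s': no slice positions or instance numbers", path))
    ord <- order(inst)
  }
  slices <- slices[ord]
  nz <- length(slices)
  if (nz > 1 && all(is.finite(zpos))) {
    gaps <- diff(sort(zpos))
    if (max(gaps) - min(gaps) > 1e-3 * max(gaps))
      stop(sprintf("DICOM series '%s': inconsistent slice spacing", path))
    dz <- mean(gaps)
  } else {
    s1 <- slices[[1]]
    dz <- if (!is.null(s1$slice_spacing)) s1$slice_spacing
          else if (!is.null(s1$slice_thickness)) s1$slice_thickness else 1
  }
  ps <- slices[[1]]$pixel_spacing  # (row spacing = dy, column spacing = dx)
  data <- array(0, dim = c(nz, rows, cols))
  for (i in seq_len(nz)) data[i, , ] <- slices[[i]]$pixels
  image_volume(data, spacing = c(dz, ps[1], ps[2]))
}
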