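#' Read a CT volume from disk
#'
#' Supported formats:
#'
#' * `"packed_array"` — the package's container (see [write_packed_array]):
#'   a 4-byte little-endian header length, a JSON header, then raw
#'   little-endian voxel data. Round-trips are bit-exact and carry spacing,
#'   domain and level count.
#' * `"nifti"` — NIfTI-1 via the RNifti package. NIfTI axes `(x, y, z)` map
#'   to package axes `(col, row, slice)`; a file with dims 64 x 64 x 9 loads
#'   as a volume of shape `(9, 64, 64)`. Spacing is taken from `pixdim`.
#' * `"dicom_series"` — a directory of single-frame DICOM files written by
#'   this package's minimal codec (uncompressed, explicit VR little endian).
#'   Slices are ordered by the ImagePositionPatient z coordinate, never by
#'   filename. A series whose slice positions are not uniformly spaced
#'   (e.g. a missing slice) is rejected with a validation error.
#'
#' NIfTI and DICOM carry no intensity-domain tag, so `domain` (and `levels`
#' for `"quantized"`) retag the result; the default is `"hounsfield"` for
#' DICOM and `"gray8"` for NIfTI when voxels are integers in \[0, 255\],
#' otherwise `"hounsfield"`.
#'
#' @param path file (packed_array, nifti) or directory (dicom_series).
#' @param format one of `"packed_array"`, `"nifti"`, `"dicom_series"`.
#' @param domain optional intensity-domain retag (see [ct_volume]).
#' @param levels level count when `domain = "quantized"`.
#' @return a [ct_volume].
#' @seealso [write_volume]
#' @export
read_volume <- function(path, format = c("packed_array", "nifti", "dicom_series"),
                        domain = NULL, levels = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("cannot read volume: no such path: ", path, call. = FALSE)
  vol <- switch(format,
    packed_array = read_packed_volume(path),
    nifti        = read_nifti_volume(path),
    dicom_series = read_dicom_series(path)
  )
  if (!is.null(domain)) {
    vol <- ct_volume(vol$voxels, vol$spacing, domain = domain, levels = levels)
  }
  vol
}

#' Write a CT volume to disk
#'
#' Inverse of [read_volume]. For integer intensity domains the round-trip is
#' voxel-exact in every format. `"dicom_series"` writes one file per slice
#' into the directory `path` (created if needed) as signed 16-bit pixels, so
#' it requires integer voxels in the signed 16-bit range.
#'
#' @param vol a [ct_volume].
#' @param path output file, or directory for `"dicom_series"`.
#' @param format as in [read_volume].
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path, format = c("packed_array", "nifti", "dicom_series")) {
  format <- match.arg(format)
  stopifnot(inherits(vol, "ct_volume"))
  switch(format,
    packed_array = write_packed_array(vol$voxels, path, spacing = vol$spacing,
                                      domain = vol$domain, levels = vol$levels),
    nifti        = write_nifti_volume(vol, path),
    dicom_series = write_dicom_series(vol, path)
  )
  invisible(path)
}

# ---- packed-array container -------------------------------------------------

#' Write an array in the packed-array container
#'
#' The container is a single binary file: a 4-byte little-endian integer
#' giving the byte length of a JSON header, the header itself, then the array
#' data in R's column-major order, little endian. `dtype` is `int32` for
#' integer data and `float64` otherwise. The header records `dim` and any
#' metadata passed through `...` (e.g. `spacing`, `domain`, `levels`, or a
#' feature-sequence sidecar block).
#'
#' @param x numeric/integer array or matrix.
#' @param path output file.
#' @param ... additional scalar/vector metadata stored in the JSON header.
#' @return `path`, invisibly.
#' @export
write_packed_array <- function(x, path, ...) {
  meta <- list(...)
  dtype <- if (is.integer(x) || all(x == floor(x))) "int32" else "float64"
  header <- c(list(magic = "pka1", dim = dim(x) %||% length(x), dtype = dtype),
              meta[!vapply(meta, is.null, logical(1))])
  hjson <- charToRaw(jsonlite::toJSON(header, auto_unbox = TRUE, digits = NA))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(length(hjson), con, size = 4L, endian = "little")
  writeBin(hjson, con)
  if (dtype == "int32") {
    writeBin(as.integer(x), con, size = 4L, endian = "little")
  } else {
    writeBin(as.double(x), con, size = 8L, endian = "little")
  }
  invisible(path)
}

#' Read a packed-array container
#'
#' @param path file written by [write_packed_array].
#' @return a list with `data` (array with the stored dims) and `meta`
#'   (the JSON header as a list).
#' @export
read_packed_array <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  n <- readBin(con, "integer", n = 1L, size = 4L, endian = "little")
  if (length(n) != 1L || is.na(n) || n <= 0L || n > 1e6) {
    stop("cannot read packed array: corrupt header in ", path, call. = FALSE)
  }
  header <- jsonlite::fromJSON(rawToChar(readBin(con, "raw", n = n)))
  if (!identical(header$magic, "pka1")) {
    stop("cannot read packed array: bad magic in ", path, call. = FALSE)
  }
  d <- as.integer(header$dim)
  len <- prod(d)
  data <- if (identical(header$dtype, "int32")) {
    readBin(con, "integer", n = len, size = 4L, endian = "little")
  } else {
    readBin(con, "double", n = len, size = 8L, endian = "little")
  }
  if (length(data) != len) {
    stop("cannot read packed array: truncated data in ", path, call. = FALSE)
  }
  if (length(d) > 1L) dim(data) <- d
  list(data = data, meta = header)
}

read_packed_volume <- function(path) {
  pk <- read_packed_array(path)
  domain <- pk$meta$domain %||% "hounsfield"
  ct_volume(pk$data, spacing = as.numeric(pk$meta$spacing %||% c(1, 1, 1)),
            domain = domain,
            levels = if (identical(domain, "quantized")) pk$meta$levels else NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- NIfTI ------------------------------------------------------------------

read_nifti_volume <- function(path) {
  img <- RNifti::readNifti(path)
  a <- as.array(img)
  if (length(dim(a)) == 2L) dim(a) <- c(dim(a), 1L)
  if (length(dim(a)) != 3L) stop("expected a 3D NIfTI volume: ", path, call. = FALSE)
  vox <- aperm(a, c(3, 2, 1))  # (x,y,z) -> (slice,row,col)
  pd <- RNifti::pixdim(img)
  sp <- rev(pd[seq_len(min(3, length(pd)))])
  if (length(sp) < 3) sp <- c(rep(1, 3 - length(sp)), sp)
  integral <- all(vox == floor(vox))
  if (integral) storage.mode(vox) <- "integer"
  domain <- if (integral && min(vox) >= 0 && max(vox) <= 255) "gray8" else "hounsfield"
  ct_volume(vox, spacing = sp, domain = domain)
}

write_nifti_volume <- function(vol, path) {
  a <- aperm(vol$voxels, c(3, 2, 1))
  if (vol$domain %in% c("gray8", "quantized") || all(a == floor(a))) {
    storage.mode(a) <- "integer"
  }
  img <- RNifti::asNifti(a)
  RNifti::pixdim(img) <- rev(vol$spacing)
  RNifti::writeNifti(img, path)
  invisible(path)
}

# ---- minimal DICOM codec ----------------------------------------------------
# A deliberately small DICOM implementation: uncompressed, explicit VR little
# endian, one frame per file, signed 16-bit pixels, and only the tags needed
# for geometry and intensity. It round-trips with itself and reads nothing
# fancier; it is not a general DICOM parser.

dcm_tag <- function(group, element) c(group %% 256L, group %/% 256L,
                                      element %% 256L, element %/% 256L)

dcm_uint16 <- function(x) as.raw(c(x %% 256L, x %/% 256L))
dcm_uint32 <- function(x) {
  as.raw(c(x %% 256, (x %/% 256) %% 256, (x %/% 65536) %% 256, (x %/% 16777216) %% 256))
}

# encode one element, explicit VR little endian
dcm_element <- function(group, element, vr, value_raw) {
  n <- length(value_raw)
  if (n %% 2L == 1L) {
    pad <- if (vr %in% c("UI", "OB")) as.raw(0L) else charToRaw(" ")
    value_raw <- c(value_raw, pad)
    n <- n + 1L
  }
  head <- c(as.raw(dcm_tag(group, element)), charToRaw(vr))
  if (vr %in% c("OB", "OW", "OF", "SQ", "UT", "UN")) {
    c(head, as.raw(c(0L, 0L)), dcm_uint32(n), value_raw)
  } else {
    c(head, dcm_uint16(n), value_raw)
  }
}

dcm_str_element <- function(group, element, vr, s) {
  dcm_element(group, element, vr, charToRaw(s))
}
dcm_us_element <- function(group, element, x) {
  dcm_element(group, element, "US", dcm_uint16(as.integer(x)))
}

write_dicom_slice <- function(path, pixels, rows, cols, instance, z, row_sp, col_sp) {
  # file meta group
  meta <- c(
    dcm_str_element(2L, 0x0010L, "UI", "1.2.840.10008.1.2.1")
  )
  meta <- c(dcm_element(2L, 0L, "UL", dcm_uint32(length(meta))), meta)
  body <- c(
    dcm_str_element(0x0008L, 0x0060L, "CS", "CT"),
    dcm_str_element(0x0020L, 0x0013L, "IS", as.character(instance)),
    dcm_str_element(0x0020L, 0x0032L, "DS",
                    sprintf("0\\0\\%.6f", z)),
    dcm_us_element(0x0028L, 0x0002L, 1L),
    dcm_us_element(0x0028L, 0x0010L, rows),
    dcm_us_element(0x0028L, 0x0011L, cols),
    dcm_str_element(0x0028L, 0x0030L, "DS", sprintf("%.6f\\%.6f", row_sp, col_sp)),
    dcm_us_element(0x0028L, 0x0100L, 16L),
    dcm_us_element(0x0028L, 0x0101L, 16L),
    dcm_us_element(0x0028L, 0x0102L, 15L),
    dcm_us_element(0x0028L, 0x0103L, 1L),
    dcm_str_element(0x0028L, 0x1052L, "DS", "0"),
    dcm_str_element(0x0028L, 0x1053L, "DS", "1")
  )
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(raw(128L), con)
  writeBin(charToRaw("DICM"), con)
  writeBin(c(meta, body), con)
  # pixel data: row-major int16, as in standard DICOM raster order
  px <- as.integer(t(pixels))  # row-major
  writeBin(c(as.raw(dcm_tag(0x7FE0L, 0x0010L)), charToRaw("OW"),
             as.raw(c(0L, 0L)), dcm_uint32(2L * length(px))), con)
  writeBin(px, con, size = 2L, endian = "little")
  invisible(path)
}

write_dicom_series <- function(vol, dir) {
  v <- vol$voxels
  if (any(v != floor(v)) || min(v) < -32768 || max(v) > 32767) {
    stop_param("dicom_series requires integer voxels in the signed 16-bit range")
  }
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create directory: ", dir, call. = FALSE)
  }
  d <- dim(v)
  for (s in seq_len(d[1])) {
    write_dicom_slice(file.path(dir, sprintf("%06d.dcm", s)),
                      v[s, , , drop = TRUE], rows = d[2], cols = d[3],
                      instance = s, z = (s - 1) * vol$spacing[1],
                      row_sp = vol$spacing[2], col_sp = vol$spacing[3])
  }
  invisible(dir)
}

# parse one slice file into a list of the tags we care about
read_dicom_slice <- function(path) {
  bytes <- readBin(path, "raw", n = file.size(path))
  if (length(bytes) < 140 || rawToChar(bytes[129:132]) != "DICM") {
    stop("unreadable DICOM file (no DICM marker): ", path, call. = FALSE)
  }
  pos <- 133L
  out <- list()
  long_vrs <- c("OB", "OW", "OF", "SQ", "UT", "UN")
  u16 <- function(i) as.integer(bytes[i]) + 256L * as.integer(bytes[i + 1L])
  u32 <- function(i) {
    as.numeric(bytes[i]) + 256 * as.numeric(bytes[i + 1L]) +
      65536 * as.numeric(bytes[i + 2L]) + 16777216 * as.numeric(bytes[i + 3L])
  }
  while (pos + 7L <= length(bytes)) {
    group <- u16(pos); element <- u16(pos + 2L)
    vr <- rawToChar(bytes[(pos + 4L):(pos + 5L)])
    if (vr %in% long_vrs) {
      len <- u32(pos + 8L); vstart <- pos + 12L
    } else {
      len <- u16(pos + 6L); vstart <- pos + 8L
    }
    vend <- vstart + len - 1L
    if (vend > length(bytes)) stop("truncated DICOM element in ", path, call. = FALSE)
    key <- sprintf("%04x%04x", group, element)
    out[[key]] <- list(vr = vr, value = bytes[vstart:vend])
    pos <- vstart + len
    if (group == 0x7FE0L && element == 0x0010L) break
  }
  get_str <- function(key) {
    el <- out[[key]]
    if (is.null(el)) return(NULL)
    trimws(rawToChar(el$value[el$value != as.raw(0L)]))
  }
  get_us <- function(key) {
    el <- out[[key]]
    if (is.null(el)) return(NULL)
    as.integer(el$value[1]) + 256L * as.integer(el$value[2])
  }
  rows <- get_us("00280010"); cols <- get_us("00280011")
  signed <- identical(get_us("00280103"), 1L)
  pix_el <- out[["7fe00010"]]
  if (is.null(rows) || is.null(cols) || is.null(pix_el)) {
    stop("DICOM file missing required tags: ", path, call. = FALSE)
  }
  px <- readBin(pix_el$value, "integer", n = rows * cols, size = 2L,
                signed = signed, endian = "little")
  ipp <- get_str("00200032")
  z <- if (!is.null(ipp)) as.numeric(strsplit(ipp, "\\\\")[[1]])[3] else NA_real_
  psp <- get_str("00280030")
  sp <- if (!is.null(psp)) as.numeric(strsplit(psp, "\\\\")[[1]]) else c(1, 1)
  slope <- as.numeric(get_str("00281053") %||% "1")
  intercept <- as.numeric(get_str("00281052") %||% "0")
  inst <- as.integer(get_str("00200013") %||% "0")
  list(pixels = matrix(px, nrow = rows, ncol = cols, byrow = TRUE),
       z = z, row_sp = sp[1], col_sp = sp[2],
       slope = slope, intercept = intercept, instance = inst)
}

read_dicom_series <- function(dir) {
  if (!dir.exists(dir)) stop("no such DICOM directory: ", dir, call. = FALSE)
  files <- list.files(dir, pattern = "\\.dcm$", full.names = TRUE)
  if (length(files) == 0L) stop("no .dcm files in ", dir, call. = FALSE)
  slices <- lapply(files, read_dicom_slice)
  zs <- vapply(slices, function(s) s$z, numeric(1))
  if (anyNA(zs)) stop("DICOM series missing slice positions in ", dir, call. = FALSE)
  ord <- order(zs)
  slices <- slices[ord]; zs <- zs[ord]
  dims <- vapply(slices, function(s) dim(s$pixels), integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    stop("inconsistent slice dimensions in DICOM series: ", dir, call. = FALSE)
  }
  slice_sp <- 1
  if (length(zs) > 1L) {
    dz <- diff(zs)
    if (any(dz <= 0) || (max(dz) - min(dz)) > 1e-3) {
      stop("validation error: inconsistent slice spacing in DICOM series: ",
           dir, " (spacings ", paste(format(dz), collapse = ", "), ")",
           call. = FALSE)
    }
    slice_sp <- mean(dz)
  }
  vox <- array(0, dim = c(length(slices), dims[1, 1], dims[2, 1]))
  for (i in seq_along(slices)) {
    s <- slices[[i]]
    vox[i, , ] <- s$pixels * s$slope + s$intercept
  }
  if (all(vox == floor(vox))) storage.mode(vox) <- "integer"
  ct_volume(vox, spacing = c(slice_sp, slices[[1]]$row_sp, slices[[1]]$col_sp),
            domain = "hounsfield")
}
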