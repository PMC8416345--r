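#' Derive voxel spacing from physical extent and grid shape
#'
#' The reference macular protocol covers 6 x 6 x 2 mm (slow axis x lateral x
#' axial) on a 128 x 512 x 885 grid, giving (46.875, 2.2599, 11.71875) um
#' in (inter-slice, axial, lateral) order.
#'
#' @param extentMm numeric(3) physical extent in mm, (slow, axial, lateral).
#' @param shape numeric(3) grid size, (n_bscans, n_axial, n_lateral).
#' @return numeric(3) spacing in micrometres, (inter-slice, axial, lateral).
#' @examples
#' spacingFromExtent(c(6, 2, 6), c(128, 885, 512))
#' @export
spacingFromExtent <- function(extentMm, shape) {
  stopifnot(length(extentMm) == 3L, length(shape) == 3L)
  if (any(extentMm <= 0)) stop("extentMm entries must be strictly positive")
  if (any(shape <= 0)) stop("shape entries must be strictly positive")
  as.numeric(extentMm) * 1000 / as.numeric(shape)
}

#' Default Topcon macular-cube spacing (um)
#'
#' @return numeric(3): (46.875, 2.2599..., 11.71875) um.
#' @export
topconSpacing <- function() {
  spacingFromExtent(c(6, 2, 6), c(128, 885, 512))
}

## ---- MetaImage plumbing -------------------------------------------------
## Header is `Key = Value` text; data is a raw block, either appended after
## `ElementDataFile = LOCAL` (.mha) or in a sibling .raw file (.mhd).
## On disk: DimSize / ElementSpacing / Offset are in file axis order
## (lateral x, axial z, b-scan), fastest-varying first, spacing in mm.
## In memory everything is (b, z, x) with spacing in um.

.metaHeader <- function(dimSize, spacingMm, offsetMm, elementType, dataFile,
                        compressed = FALSE) {
  c("ObjectType = Image",
    "NDims = 3",
    "BinaryData = True",
    "BinaryDataByteOrderMSB = False",
    sprintf("CompressedData = %s", if (compressed) "True" else "False"),
    "TransformMatrix = 1 0 0 0 1 0 0 0 1",
    sprintf("Offset = %s", paste(format(offsetMm, digits = 9), collapse = " ")),
    "CenterOfRotation = 0 0 0",
    sprintf("ElementSpacing = %s",
            paste(format(spacingMm, digits = 9), collapse = " ")),
    sprintf("DimSize = %s", paste(dimSize, collapse = " ")),
    sprintf("ElementType = %s", elementType),
    sprintf("ElementDataFile = %s", dataFile))
}

.parseMetaHeader <- function(rawBytes) {
  # header ends at the newline terminating the ElementDataFile line; find it
  # at byte level (the payload that follows is binary)
  pat <- charToRaw("ElementDataFile")
  n <- min(length(rawBytes), 8192L)
  hit <- NA_integer_
  limit <- n - length(pat) + 1L
  for (i in seq_len(max(limit, 0L))) {
    if (rawBytes[i] == pat[1] &&
        identical(rawBytes[i:(i + length(pat) - 1L)], pat)) { hit <- i; break }
  }
  if (is.na(hit))
    stop("not a MetaImage header: no ElementDataFile field found")
  nl <- hit + which(rawBytes[hit:n] == as.raw(10L))[1] - 1L
  if (is.na(nl)) stop("malformed MetaImage header: unterminated ElementDataFile")
  txt <- rawToChar(rawBytes[seq_len(nl - 1L)])
  Encoding(txt) <- "latin1"
  hdrLines <- strsplit(txt, "\n", fixed = TRUE)[[1]]
  kv <- list()
  for (ln in hdrLines) {
    parts <- regmatches(ln, regexec("^\\s*([A-Za-z]+)\\s*=\\s*(.*?)\\s*$", ln))[[1]]
    if (length(parts) == 3L) kv[[parts[2]]] <- parts[3]
  }
  headerBytes <- sum(nchar(hdrLines, type = "bytes")) + length(hdrLines)
  list(fields = kv, headerBytes = headerBytes)
}

.elementTypeInfo <- function(type) {
  switch(type,
    MET_UCHAR  = list(size = 1L, signed = TRUE,  max = 255),
    MET_USHORT = list(size = 2L, signed = FALSE, max = 65535),
    stop(sprintf("unsupported ElementType '%s' (supported: MET_UCHAR, MET_USHORT)",
                 type)))
}

.readMetaRaw <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  rawBytes <- readBin(path, "raw", n = file.size(path))
  hdr <- .parseMetaHeader(rawBytes)
  f <- hdr$fields
  ndims <- as.integer(f[["NDims"]])
  if (is.na(ndims) || ndims != 3L)
    stop(sprintf("NDims = %s: only 3-D MetaImage volumes are supported",
                 f[["NDims"]]))
  dimSize <- as.integer(strsplit(trimws(f[["DimSize"]]), "\\s+")[[1]])
  if (length(dimSize) != 3L || any(is.na(dimSize)) || any(dimSize < 1L))
    stop(sprintf("DimSize = '%s' is not three positive integers", f[["DimSize"]]))
  spacingMm <- as.numeric(strsplit(trimws(f[["ElementSpacing"]] %||% "1 1 1"),
                                   "\\s+")[[1]])
  offsetMm <- as.numeric(strsplit(trimws(f[["Offset"]] %||% "0 0 0"), "\\s+")[[1]])
  ti <- .elementTypeInfo(f[["ElementType"]] %||% "MET_USHORT")
  msb <- identical(toupper(f[["BinaryDataByteOrderMSB"]] %||% "FALSE"), "TRUE")
  compressed <- identical(toupper(f[["CompressedData"]] %||% "FALSE"), "TRUE")

  dataFile <- f[["ElementDataFile"]]
  if (identical(toupper(dataFile), "LOCAL")) {
    data <- rawBytes[(hdr$headerBytes + 1L):length(rawBytes)]
  } else {
    rawPath <- file.path(dirname(path), dataFile)
    if (!file.exists(rawPath))
      stop(sprintf("ElementDataFile '%s' not found next to %s", dataFile, path))
    data <- readBin(rawPath, "raw", n = file.size(rawPath))
  }
  if (compressed) {
    data <- tryCatch(memDecompress(data, type = "gzip"),
                     error = function(e) memDecompress(data, type = "unknown"))
  }
  nVox <- prod(dimSize)
  need <- nVox * ti$size
  if (length(data) < need)
    stop(sprintf("data block too short: %d bytes for DimSize %s x %d-byte elements",
                 length(data), paste(dimSize, collapse = "x"), ti$size))
  vals <- readBin(data, "integer", n = nVox, size = ti$size, signed = ti$signed,
                  endian = if (msb) "big" else "little")
  if (ti$size == 1L) vals <- ifelse(vals < 0L, vals + 256L, vals)
  # file order is (x, z, b) fastest-first; permute to (b, z, x)
  arr <- array(vals, dim = dimSize)
  arr <- aperm(arr, c(3, 2, 1))
  list(arr = arr, spacingUm = rev(spacingMm) * 1000, originMm = rev(offsetMm),
       typeMax = ti$max)
}

#' Read an OCT volume from an ITK MetaImage file
#'
#' Accepts `.mha` (header + embedded data) or `.mhd` (header + sibling raw
#' file); `CompressedData = True` is supported on read. Intensities are
#' normalized to [0, 1] by dividing by the element-type maximum (255 for
#' MET_UCHAR, 65535 for MET_USHORT), so network input scaling is
#' deterministic regardless of on-disk bit depth.
#'
#' @param path path to a readable `.mhd` or `.mha` file.
#' @return An \linkS4class{OCTVolume} with spacing (um) taken from the
#'   header and index order (b, z, x).
#' @seealso [writeMetaImage()], [readLabelMask()]
#' @export
readMetaImage <- function(path) {
  r <- .readMetaRaw(path)
  OCTVolume(r$arr / r$typeMax, spacingUm = r$spacingUm, originMm = r$originMm)
}

#' Read a label mask from an ITK MetaImage file
#'
#' Like [readMetaImage()] but keeps the integer labels {0, 1, 2} unscaled.
#'
#' @param path path to a `.mhd` or `.mha` file.
#' @return A \linkS4class{LabelMask}.
#' @export
readLabelMask <- function(path) {
  r <- .readMetaRaw(path)
  LabelMask(r$arr, spacingUm = r$spacingUm)
}

#' Write an OCT volume or label mask as ITK MetaImage
#'
#' Volumes are quantized to MET_USHORT (16-bit; intensity v is stored as
#' round(v * 65535)), masks as MET_UCHAR. A `.mhd` path produces a header +
#' sibling `.raw` pair; a `.mha` path a single file. [readMetaImage()] /
#' [readLabelMask()] invert the write bit-exactly for data already on the
#' 16-bit grid (all phantom output is).
#'
#' @param x an \linkS4class{OCTVolume} or \linkS4class{LabelMask}.
#' @param path output path ending in `.mhd` or `.mha`.
#' @return `path`, invisibly.
#' @export
setGeneric("writeMetaImage", function(x, path) standardGeneric("writeMetaImage"))

.writeMetaRaw <- function(arr, spacingUm, originMm, elementType, path) {
  ti <- .elementTypeInfo(elementType)
  d <- dim(arr)
  fileArr <- aperm(arr, c(3, 2, 1))                     # back to (x, z, b)
  vals <- as.integer(round(fileArr))
  if (any(vals < 0L) || any(vals > ti$max))
    stop("values out of range for ", elementType)
  single <- grepl("\\.mha$", path, ignore.case = TRUE)
  dataFile <- if (single) "LOCAL" else paste0(sub("\\.mhd$", "", basename(path),
                                                  ignore.case = TRUE), ".raw")
  hdr <- .metaHeader(dimSize = rev(d), spacingMm = rev(spacingUm) / 1000,
                     offsetMm = rev(originMm), elementType = elementType,
                     dataFile = dataFile)
  # build the byte stream by hand: writeBin() truncates signed when asked to
  # write unsigned 16-bit values above 32767
  payload <- if (ti$size == 1L) {
    as.raw(vals)
  } else {
    as.raw(as.vector(rbind(vals %% 256L, vals %/% 256L)))  # little-endian
  }
  con <- file(path, "wb")
  on.exit(close(con), add = TRUE)
  writeLines(hdr, con, sep = "\n")
  if (single) {
    writeBin(payload, con)
  } else {
    writeBin(payload, file.path(dirname(path), dataFile))
  }
  invisible(path)
}

#' @rdname writeMetaImage
#' @export
setMethod("writeMetaImage", "OCTVolume", function(x, path) {
  .writeMetaRaw(x@voxels * 65535, x@spacingUm, x@originMm, "MET_USHORT", path)
})

#' @rdname writeMetaImage
#' @export
setMethod("writeMetaImage", "LabelMask", function(x, path) {
  .writeMetaRaw(x@labels, x@spacingUm, c(0, 0, 0), "MET_UCHAR", path)
})

`%||%` <- function(a, b) if (is.null(a)) b else a
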