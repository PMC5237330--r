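#' Read a 3D medical volume
#'
#' Reads NIfTI-1 (`.nii`, `.nii.gz`), MetaImage (`.mha`, `.mhd` + raw) and
#' NRRD (`.nrrd`, raw encoding) volumes into the package's containers. Grid
#' metadata (dims, spacing in mm, origin) is taken from the header. Only 3D
#' scalar volumes are accepted; orientation is assumed axis-aligned (the
#' package never resamples between frames, so direction cosines other than
#' identity are rejected).
#'
#' In `binary` mode any strictly positive voxel maps to 1 (segmentation masks
#' in the wild use arbitrary positive label values); negative values are a
#' content error. `probability` mode requires values in `[0,1]` up to float
#' rounding; `distance` mode accepts any finite values.
#'
#' @param path file path.
#' @param mode one of `"binary"`, `"probability"`, `"distance"`.
#' @return A [binary_volume()], [probability_volume()] or [distance_volume()].
#' @seealso [write_volume()]
#' @export
read_volume <- function(path, mode = c("binary", "probability", "distance")) {
  mode <- match.arg(mode)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  ext <- volume_format(path)
  raw <- switch(ext,
    nii  = read_nifti(path),
    mha  = read_metaimage(path),
    mhd  = read_metaimage(path),
    nrrd = read_nrrd(path),
    stop("unrecognized volume format: ", path, call. = FALSE))
  grid <- volume_grid(raw$dims, raw$spacing, raw$origin)
  vals <- array(raw$values, dim = raw$dims)
  switch(mode,
    binary = {
      if (any(vals < 0))
        stop("binary mode: negative voxel values are not a valid mask",
             call. = FALSE)
      binary_volume(array(as.integer(vals > 0), dim = raw$dims), grid)
    },
    probability = {
      if (any(vals < -1e-5) || any(vals > 1 + 1e-5))
        stop("probability mode: values outside [0,1]", call. = FALSE)
      probability_volume(pmin(pmax(vals, 0), 1), grid)
    },
    distance = distance_volume(vals, grid))
}

#' Write a volume to a standard format
#'
#' Binary volumes are stored as unsigned 8-bit, real-valued volumes as 32-bit
#' little-endian floats (so real values round-trip within single-precision
#' rounding). The format is chosen from the file extension: `.nii`/`.nii.gz`
#' (NIfTI-1), `.mha`/`.mhd` (MetaImage; `.mhd` writes a sibling `.raw`),
#' `.nrrd` (NRRD, raw encoding).
#'
#' @param vol any volume object.
#' @param path destination path; the parent directory must exist.
#' @return Invisibly `path`.
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "shape_volume"))
  if (!dir.exists(dirname(path)))
    stop("cannot write volume: directory does not exist: ", dirname(path),
         call. = FALSE)
  binary <- inherits(vol, "binary_volume")
  ext <- volume_format(path)
  switch(ext,
    nii  = write_nifti(vol, path, binary),
    mha  = write_metaimage(vol, path, binary, local = TRUE),
    mhd  = write_metaimage(vol, path, binary, local = FALSE),
    nrrd = write_nrrd(vol, path, binary),
    stop("unrecognized volume format: ", path, call. = FALSE))
  invisible(path)
}

volume_format <- function(path) {
  lower <- tolower(path)
  if (grepl("\\.nii(\\.gz)?$", lower)) return("nii")
  if (grepl("\\.mha$", lower)) return("mha")
  if (grepl("\\.mhd$", lower)) return("mhd")
  if (grepl("\\.nrrd$", lower)) return("nrrd")
  "unknown"
}

# ---- NIfTI-1 ---------------------------------------------------------------

nifti_dtypes <- list(
  `2`   = list(what = "integer", size = 1L, signed = FALSE),  # uint8
  `4`   = list(what = "integer", size = 2L, signed = TRUE),   # int16
  `8`   = list(what = "integer", size = 4L, signed = TRUE),   # int32
  `16`  = list(what = "double",  size = 4L, signed = TRUE),   # float32
  `64`  = list(what = "double",  size = 8L, signed = TRUE),   # float64
  `256` = list(what = "integer", size = 1L, signed = TRUE),   # int8
  `512` = list(what = "integer", size = 2L, signed = FALSE))  # uint16

read_nifti <- function(path) {
  con <- if (grepl("\\.gz$", tolower(path))) gzfile(path, "rb")
         else file(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", n = 348L)
  if (length(hdr) < 348L) stop("truncated NIfTI header", call. = FALSE)
  endian <- "little"
  if (readBin(hdr[1:4], "integer", size = 4, endian = endian) != 348L) {
    endian <- "big"
    if (readBin(hdr[1:4], "integer", size = 4, endian = endian) != 348L)
      stop("not a NIfTI-1 file (bad sizeof_hdr)", call. = FALSE)
  }
  rd <- function(off, what, n, size, signed = TRUE)
    readBin(hdr[(off + 1):(off + n * size)], what, n = n, size = size,
            signed = signed, endian = endian)
  magic <- rawToChar(hdr[345:347])
  if (!magic %in% c("n+1", "ni1"))
    stop("not a NIfTI-1 file (bad magic)", call. = FALSE)
  dim0 <- rd(40, "integer", 8, 2)
  ndim <- dim0[1]
  if (ndim > 3L && any(dim0[(4 + 1):(ndim + 1)] > 1L))
    stop("only 3D volumes are supported (file is ", ndim, "D)", call. = FALSE)
  if (ndim < 3L) stop("only 3D volumes are supported", call. = FALSE)
  dims <- dim0[2:4]
  datatype <- rd(70, "integer", 1, 2)
  pixdim <- rd(76, "double", 8, 4)
  vox_offset <- rd(108, "double", 1, 4)
  scl_slope <- rd(112, "double", 1, 4)
  scl_inter <- rd(116, "double", 1, 4)
  qform_code <- rd(252, "integer", 1, 2)
  sform_code <- rd(254, "integer", 1, 2)
  origin <- c(0, 0, 0)
  if (sform_code > 0L) {
    srow <- rbind(rd(280, "double", 4, 4), rd(296, "double", 4, 4),
                  rd(312, "double", 4, 4))
    origin <- srow[, 4]
  } else if (qform_code > 0L) {
    origin <- rd(268, "double", 3, 4)
  }
  dt <- nifti_dtypes[[as.character(datatype)]]
  if (is.null(dt))
    stop("unsupported NIfTI datatype code ", datatype, call. = FALSE)
  # skip to the data (gz connections cannot seek)
  skip <- as.integer(round(vox_offset)) - 348L
  if (skip > 0L) readBin(con, "raw", n = skip)
  n <- prod(dims)
  vals <- readBin(con, dt$what, n = n, size = dt$size, signed = dt$signed,
                  endian = endian)
  if (length(vals) != n) stop("truncated NIfTI data", call. = FALSE)
  vals <- as.double(vals)
  if (is.finite(scl_slope) && scl_slope != 0 && !(scl_slope == 1 && scl_inter == 0))
    vals <- vals * scl_slope + scl_inter
  list(dims = dims, spacing = abs(pixdim[2:4]), origin = origin, values = vals)
}

write_nifti <- function(vol, path, binary) {
  dims <- vol$grid$dims; sp <- vol$grid$spacing; org <- vol$grid$origin
  con <- if (grepl("\\.gz$", tolower(path))) gzfile(path, "wb")
         else file(path, "wb")
  on.exit(close(con))
  w <- function(x, size) writeBin(x, con, size = size, endian = "little")
  pad <- function(s, n) {
    r <- as.raw(rep(0L, n)); b <- charToRaw(s); r[seq_along(b)] <- b
    writeBin(r, con)
  }
  w(348L, 4)                               # sizeof_hdr
  writeBin(as.raw(rep(0L, 36)), con)       # data_type..dim_info
  w(as.integer(c(3L, dims, 1L, 1L, 1L, 1L)), 2)  # dim[8]
  w(numeric(3), 4); w(0L, 2)               # intent_p, intent_code
  w(if (binary) 2L else 16L, 2)            # datatype
  w(if (binary) 8L else 32L, 2)            # bitpix
  w(0L, 2)                                 # slice_start
  w(c(1, sp, 1, 1, 1, 1), 4)               # pixdim (qfac = 1)
  w(352, 4)                                # vox_offset
  w(c(1, 0), 4)                            # scl_slope, scl_inter
  w(0L, 2); writeBin(as.raw(c(0L, 2L)), con)  # slice_end/code, xyzt=mm
  w(numeric(4), 4)                         # cal_max/min, slice_dur, toffset
  w(c(0L, 0L), 4)                          # glmax, glmin
  pad("shapeatlas", 80); pad("", 24)       # descrip, aux_file
  w(c(1L, 1L), 2)                          # qform_code, sform_code
  w(numeric(3), 4)                         # quaternion b,c,d (identity)
  w(org, 4)                                # qoffset
  w(c(sp[1], 0, 0, org[1]), 4)             # srow_x
  w(c(0, sp[2], 0, org[2]), 4)             # srow_y
  w(c(0, 0, sp[3], org[3]), 4)             # srow_z
  pad("", 16)                              # intent_name
  pad("n+1", 4)                            # magic
  writeBin(as.raw(c(0L, 0L, 0L, 0L)), con) # extension flag
  if (binary) {
    writeBin(as.raw(as.integer(vol$data)), con)
  } else {
    w(as.double(vol$data), 4)
  }
}

# ---- MetaImage -------------------------------------------------------------

met_types <- list(
  MET_UCHAR  = list(what = "integer", size = 1L, signed = FALSE),
  MET_CHAR   = list(what = "integer", size = 1L, signed = TRUE),
  MET_SHORT  = list(what = "integer", size = 2L, signed = TRUE),
  MET_USHORT = list(what = "integer", size = 2L, signed = FALSE),
  MET_INT    = list(what = "integer", size = 4L, signed = TRUE),
  MET_FLOAT  = list(what = "double",  size = 4L, signed = TRUE),
  MET_DOUBLE = list(what = "double",  size = 8L, signed = TRUE))

read_metaimage <- function(path) {
  blob <- readBin(path, "raw", n = file.info(path)$size)
  # header is the text up to the end of the ElementDataFile line
  key <- charToRaw("ElementDataFile")
  pos <- locate_bytes(blob, key)
  if (is.na(pos)) stop("MetaImage header lacks ElementDataFile", call. = FALSE)
  nl <- pos
  while (nl <= length(blob) && blob[nl] != as.raw(10L)) nl <- nl + 1L
  header <- strsplit(rawToChar(blob[1:(nl - 1L)]), "\r?\n")[[1]]
  fields <- list()
  for (line in header) {
    kv <- regmatches(line, regexec("^\\s*([A-Za-z]+)\\s*=\\s*(.*?)\\s*$", line))[[1]]
    if (length(kv) == 3) fields[[kv[2]]] <- kv[3]
  }
  if (!identical(fields$NDims, "3"))
    stop("only 3D MetaImage volumes are supported", call. = FALSE)
  if (identical(tolower(fields$CompressedData %||% "false"), "true"))
    stop("compressed MetaImage data is not supported", call. = FALSE)
  msb <- tolower(fields$BinaryDataByteOrderMSB %||%
                 fields$ElementByteOrderMSB %||% "false")
  endian <- if (identical(msb, "true")) "big" else "little"
  dims <- as.integer(strsplit(trimws(fields$DimSize), "\\s+")[[1]])
  spacing <- as.numeric(strsplit(trimws(fields$ElementSpacing %||% "1 1 1"),
                                 "\\s+")[[1]])
  origin <- as.numeric(strsplit(trimws(fields$Offset %||% fields$Position %||%
                                       "0 0 0"), "\\s+")[[1]])
  tm <- fields$TransformMatrix
  if (!is.null(tm)) {
    m <- as.numeric(strsplit(trimws(tm), "\\s+")[[1]])
    if (max(abs(m - c(1, 0, 0, 0, 1, 0, 0, 0, 1))) > 1e-6)
      stop("non-identity MetaImage TransformMatrix is not supported",
           call. = FALSE)
  }
  dt <- met_types[[fields$ElementType %||% "MET_FLOAT"]]
  if (is.null(dt))
    stop("unsupported MetaImage ElementType ", fields$ElementType,
         call. = FALSE)
  datafile <- fields$ElementDataFile
  data_raw <- if (identical(datafile, "LOCAL")) {
    blob[(nl + 1L):length(blob)]
  } else {
    dp <- file.path(dirname(path), datafile)
    readBin(dp, "raw", n = file.info(dp)$size)
  }
  n <- prod(dims)
  vals <- readBin(data_raw, dt$what, n = n, size = dt$size,
                  signed = dt$signed, endian = endian)
  if (length(vals) != n) stop("truncated MetaImage data", call. = FALSE)
  list(dims = dims, spacing = spacing, origin = origin,
       values = as.double(vals))
}

write_metaimage <- function(vol, path, binary, local) {
  dims <- vol$grid$dims
  hdr <- c(
    "ObjectType = Image",
    "NDims = 3",
    "BinaryData = True",
    "BinaryDataByteOrderMSB = False",
    "CompressedData = False",
    "TransformMatrix = 1 0 0 0 1 0 0 0 1",
    paste("Offset =", paste(format(vol$grid$origin, digits = 12),
                            collapse = " ")),
    paste("ElementSpacing =", paste(format(vol$grid$spacing, digits = 12),
                                    collapse = " ")),
    paste("DimSize =", paste(dims, collapse = " ")),
    paste("ElementType =", if (binary) "MET_UCHAR" else "MET_FLOAT"))
  rawname <- paste0(sub("\\.mhd$", "", basename(path), ignore.case = TRUE),
                    ".raw")
  hdr <- c(hdr, paste("ElementDataFile =", if (local) "LOCAL" else rawname))
  con <- file(path, "wb")
  writeBin(charToRaw(paste0(paste(hdr, collapse = "\n"), "\n")), con)
  if (local) {
    write_payload(vol, con, binary)
    close(con)
  } else {
    close(con)
    con2 <- file(file.path(dirname(path), rawname), "wb")
    write_payload(vol, con2, binary)
    close(con2)
  }
}

write_payload <- function(vol, con, binary) {
  if (binary) writeBin(as.raw(as.integer(vol$data)), con)
  else writeBin(as.double(vol$data), con, size = 4, endian = "little")
}

# ---- NRRD ------------------------------------------------------------------

nrrd_types <- list(
  uint8 = list(what = "integer", size = 1L, signed = FALSE),
  int8 = list(what = "integer", size = 1L, signed = TRUE),
  int16 = list(what = "integer", size = 2L, signed = TRUE),
  uint16 = list(what = "integer", size = 2L, signed = FALSE),
  int32 = list(what = "integer", size = 4L, signed = TRUE),
  float = list(what = "double", size = 4L, signed = TRUE),
  double = list(what = "double", size = 8L, signed = TRUE))

nrrd_type_alias <- c(
  "uchar" = "uint8", "unsigned char" = "uint8", "uint8_t" = "uint8",
  "char" = "int8", "signed char" = "int8", "int8_t" = "int8",
  "short" = "int16", "short int" = "int16", "int16_t" = "int16",
  "ushort" = "uint16", "unsigned short" = "uint16", "uint16_t" = "uint16",
  "int" = "int32", "int32_t" = "int32")

read_nrrd <- function(path) {
  blob <- readBin(path, "raw", n = file.info(path)$size)
  # header ends at the first blank line
  hdr_end <- locate_bytes(blob, as.raw(c(10L, 10L)))
  crlf <- locate_bytes(blob, as.raw(c(13L, 10L, 13L, 10L)))
  if (!is.na(crlf) && (is.na(hdr_end) || crlf < hdr_end)) {
    header_raw <- blob[1:(crlf - 1L)]; data_start <- crlf + 4L
  } else if (!is.na(hdr_end)) {
    header_raw <- blob[1:(hdr_end - 1L)]; data_start <- hdr_end + 2L
  } else stop("NRRD header has no terminating blank line", call. = FALSE)
  lines <- strsplit(rawToChar(header_raw), "\r?\n")[[1]]
  if (!grepl("^NRRD000", lines[1]))
    stop("not a NRRD file (bad magic)", call. = FALSE)
  fields <- list()
  for (line in lines[-1]) {
    if (grepl("^#", line) || !nzchar(line)) next
    kv <- regmatches(line, regexec("^([^:]+):\\s*(.*)$", line))[[1]]
    if (length(kv) == 3) fields[[trimws(tolower(kv[2]))]] <- trimws(kv[3])
  }
  if (!identical(fields$dimension, "3"))
    stop("only 3D NRRD volumes are supported", call. = FALSE)
  if (!identical(tolower(fields$encoding %||% ""), "raw"))
    stop("only raw NRRD encoding is supported", call. = FALSE)
  endian <- if (identical(tolower(fields$endian %||% "little"), "big"))
    "big" else "little"
  dims <- as.integer(strsplit(fields$sizes, "\\s+")[[1]])
  spacing <- c(1, 1, 1)
  if (!is.null(fields$spacings)) {
    spacing <- as.numeric(strsplit(fields$spacings, "\\s+")[[1]])
  } else if (!is.null(fields[["space directions"]])) {
    vecs <- regmatches(fields[["space directions"]],
                       gregexpr("\\(([^)]*)\\)", fields[["space directions"]]))[[1]]
    m <- sapply(vecs, function(v)
      as.numeric(strsplit(gsub("[()]", "", v), ",")[[1]]))
    if (max(abs(m - diag(diag(m)))) > 1e-9)
      stop("non-axis-aligned NRRD space directions are not supported",
           call. = FALSE)
    spacing <- diag(m)
  }
  origin <- c(0, 0, 0)
  if (!is.null(fields[["space origin"]]))
    origin <- as.numeric(strsplit(gsub("[()]", "",
                                       fields[["space origin"]]), ",")[[1]])
  tname <- tolower(fields$type)
  if (tname %in% names(nrrd_type_alias)) tname <- nrrd_type_alias[[tname]]
  dt <- nrrd_types[[tname]]
  if (is.null(dt)) stop("unsupported NRRD type ", fields$type, call. = FALSE)
  n <- prod(dims)
  vals <- readBin(blob[data_start:length(blob)], dt$what, n = n,
                  size = dt$size, signed = dt$signed, endian = endian)
  if (length(vals) != n) stop("truncated NRRD data", call. = FALSE)
  list(dims = dims, spacing = abs(spacing), origin = origin,
       values = as.double(vals))
}

write_nrrd <- function(vol, path, binary) {
  sp <- vol$grid$spacing; org <- vol$grid$origin
  hdr <- c(
    "NRRD0004",
    "# written by shapeatlas",
    paste("type:", if (binary) "uint8" else "float"),
    "dimension: 3",
    "space dimension: 3",
    paste("sizes:", paste(vol$grid$dims, collapse = " ")),
    paste0("space directions: (", sp[1], ",0,0) (0,", sp[2], ",0) (0,0,",
           sp[3], ")"),
    paste0("space origin: (", org[1], ",", org[2], ",", org[3], ")"),
    "kinds: domain domain domain",
    "encoding: raw",
    "endian: little")
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw(paste0(paste(hdr, collapse = "\n"), "\n\n")), con)
  write_payload(vol, con, binary)
}

# first byte index at which `pattern` occurs in `blob`, NA if absent
locate_bytes <- function(blob, pattern) {
  hits <- which(blob == pattern[1])
  for (h in hits) {
    if (h + length(pattern) - 1L <= length(blob) &&
        all(blob[h:(h + length(pattern) - 1L)] == pattern))
      return(h)
  }
  NA_integer_
}

`%||%` <- function(a, b) if (is.null(a)) b else a
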