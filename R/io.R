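#' Read an image or label volume
#'
#' Reads NIfTI-1 (`.nii`, `.nii.gz`), MetaImage (`.mhd`, `.mha`) or PNG
#' (2D only) into the package's internal grid convention: arrays indexed
#' `(z, y, x)` (3D) or `(y, x)` (2D), spacing in mm aligned with those axes.
#' On-disk `(x, y, z)` orderings are transposed at this boundary.
#'
#' PNG carries no physical metadata: spacing defaults to 1 mm per axis with a
#' warning. Direction matrices beyond axis order are ignored; a non-identity
#' direction triggers a warning, not an error, because the border analysis is
#' intrinsic to the voxel grid.
#'
#' @param path path to the file.
#' @param kind `"image"` for scalar intensities, `"label"` for integer class
#'   maps. A label file whose stored values are not exactly integer is a
#'   format error naming the offending value.
#' @return A [image_volume()] or [label_volume()].
#' @export
read_volume <- function(path, kind = c("image", "label")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) {
    stop("read_volume: file not found: ", path, call. = FALSE)
  }
  ext <- volume_format(path)
  raw <- switch(ext,
    nifti = read_nifti_raw(path),
    meta  = read_meta_raw(path),
    png   = read_png_raw(path)
  )
  if (kind == "label") {
    d <- raw$data
    if (!is.null(raw$png_scale)) d <- d * raw$png_scale  # stored 8/16-bit ints
    label_volume(d, spacing = raw$spacing, origin = raw$origin)
  } else {
    image_volume(raw$data, spacing = raw$spacing, origin = raw$origin)
  }
}

#' Write a volume to NIfTI, MetaImage or PNG
#'
#' Round-trip stable: integer labels survive bitwise, images within float32
#' precision (NIfTI/MetaImage). Label volumes are stored with unsigned/signed
#' integer voxel types, images as float32. PNG (2D only) stores 8-bit or
#' 16-bit gray: labels must fit the integer range, images are expected in
#' `[0, 1]`.
#'
#' @param vol a [image_volume()] or [label_volume()].
#' @param path output path; format chosen by extension.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "us_volume"))
  if (!dir.exists(dirname(path))) {
    stop("write_volume: parent directory does not exist: ", dirname(path),
         call. = FALSE)
  }
  ext <- volume_format(path)
  is_label <- inherits(vol, "us_label")
  switch(ext,
    nifti = write_nifti_raw(vol, path, is_label),
    meta  = write_meta_raw(vol, path, is_label),
    png   = write_png_raw(vol, path, is_label)
  )
  invisible(path)
}

#' Wrap a boolean mask as a writable label volume
#'
#' Convenience for persisting border / edge / CAM-target masks as uint8
#' {0,1} label maps on the grid of an existing volume.
#'
#' @param mask logical array.
#' @param like a `us_volume` providing spacing and origin.
#' @return A [label_volume()] with values in {0, 1}.
#' @export
mask_volume <- function(mask, like) {
  stopifnot(is.logical(mask), inherits(like, "us_volume"))
  check_same_shape(mask, like, "mask and reference volume")
  label_volume(array(as.integer(mask), dim = dim(mask)),
               spacing = like$spacing, origin = like$origin)
}

volume_format <- function(path) {
  low <- tolower(path)
  if (grepl("\\.nii(\\.gz)?$", low)) return("nifti")
  if (grepl("\\.(mhd|mha)$", low)) return("meta")
  if (grepl("\\.png$", low)) return("png")
  stop("unsupported volume format: ", path,
       " (expected .nii/.nii.gz, .mhd/.mha or .png)", call. = FALSE)
}

# ---- NIfTI ------------------------------------------------------------------

read_nifti_raw <- function(path) {
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  nd <- length(dim(arr))
  if (!nd %in% c(2L, 3L)) {
    stop("read_volume: only 2D/3D NIfTI supported, got ", nd, " dims",
         call. = FALSE)
  }
  sp <- RNifti::pixdim(img)[seq_len(nd)]
  xf <- try(RNifti::xform(img), silent = TRUE)
  org <- rep(0, nd)
  if (!inherits(xf, "try-error") && is.matrix(xf)) {
    org3 <- xf[seq_len(3), 4]
    org <- abs(org3[seq_len(nd)])
    rot <- xf[seq_len(3), seq_len(3)]
    offdiag <- rot - diag(diag(rot))
    if (max(abs(offdiag)) > 1e-4 * max(abs(diag(rot)), 1)) {
      warning("read_volume: non-axis-aligned direction matrix ignored; ",
              "grid treated as axis-aligned", call. = FALSE)
    }
  }
  # on-disk (x,y[,z]) -> internal ([z,]y,x)
  list(data = aperm(arr, rev(seq_len(nd))),
       spacing = rev(sp), origin = rev(org))
}

write_nifti_raw <- function(vol, path, is_label) {
  nd <- n_dims(vol)
  arr <- aperm(vol$data, rev(seq_len(nd)))        # internal -> (x,y[,z])
  if (is_label) {
    mx <- max(arr)
    dtype <- if (mx < 256) "uint8" else if (mx < 32768) "int16" else "int32"
    storage.mode(arr) <- "integer"
  } else {
    dtype <- "float"
    storage.mode(arr) <- "double"
  }
  img <- RNifti::asNifti(structure(arr, pixdim = rev(vol$spacing)),
                         datatype = dtype)
  RNifti::writeNifti(img, path, datatype = dtype)
  invisible(path)
}

# ---- MetaImage --------------------------------------------------------------
# Minimal MHD/MHA support: text header, uncompressed little-endian raw
# payload, axis-aligned grids. That is all this toolkit needs; anything
# fancier should be converted to NIfTI upstream.

meta_types <- c(
  MET_UCHAR = "uint8", MET_CHAR = "int8", MET_USHORT = "uint16",
  MET_SHORT = "int16", MET_UINT = "uint32", MET_INT = "int32",
  MET_FLOAT = "float32", MET_DOUBLE = "float64"
)

read_meta_raw <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con), add = TRUE)
  hdr <- list()
  repeat {
    line <- readLines(con, n = 1L, warn = FALSE)
    if (length(line) == 0) stop("read_volume: truncated MetaImage header",
                                call. = FALSE)
    kv <- strsplit(line, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2) next
    key <- trimws(kv[1]); val <- trimws(kv[2])
    hdr[[key]] <- val
    if (key == "ElementDataFile") break
  }
  ndims <- as.integer(hdr$NDims)
  dims <- as.integer(strsplit(hdr$DimSize, "\\s+")[[1]])     # (x,y[,z])
  sp <- if (!is.null(hdr$ElementSpacing)) {
    as.numeric(strsplit(hdr$ElementSpacing, "\\s+")[[1]])
  } else rep(1, ndims)
  org <- if (!is.null(hdr$Offset)) {
    as.numeric(strsplit(hdr$Offset, "\\s+")[[1]])
  } else rep(0, ndims)
  if (!is.null(hdr$CompressedData) && toupper(hdr$CompressedData) == "TRUE") {
    stop("read_volume: compressed MetaImage not supported", call. = FALSE)
  }
  if (!is.null(hdr$TransformMatrix)) {
    tm <- as.numeric(strsplit(hdr$TransformMatrix, "\\s+")[[1]])
    if (max(abs(tm - as.numeric(diag(ndims)))) > 1e-6) {
      warning("read_volume: non-identity TransformMatrix ignored",
              call. = FALSE)
    }
  }
  type <- meta_types[[hdr$ElementType]]
  if (is.null(type)) {
    stop("read_volume: unsupported MetaImage ElementType ", hdr$ElementType,
         call. = FALSE)
  }
  msb <- isTRUE(toupper(hdr$BinaryDataByteOrderMSB %||% hdr$ElementByteOrderMSB %||% "FALSE") == "TRUE")
  endian <- if (msb) "big" else "little"
  n <- prod(dims)
  datafile <- hdr$ElementDataFile
  if (identical(toupper(datafile), "LOCAL")) {
    vals <- read_meta_payload(con, type, n, endian)
  } else {
    rawpath <- file.path(dirname(path), datafile)
    rcon <- file(rawpath, "rb")
    on.exit(close(rcon), add = TRUE)
    vals <- read_meta_payload(rcon, type, n, endian)
  }
  arr <- array(vals, dim = dims)
  list(data = aperm(arr, rev(seq_len(ndims))),
       spacing = rev(sp), origin = rev(org))
}

read_meta_payload <- function(con, type, n, endian) {
  switch(type,
    uint8   = as.integer(readBin(con, "integer", n, size = 1, signed = FALSE,
                                 endian = endian)),
    int8    = readBin(con, "integer", n, size = 1, signed = TRUE,
                      endian = endian),
    uint16  = readBin(con, "integer", n, size = 2, signed = FALSE,
                      endian = endian),
    int16   = readBin(con, "integer", n, size = 2, signed = TRUE,
                      endian = endian),
    uint32  = ,
    int32   = readBin(con, "integer", n, size = 4, endian = endian),
    float32 = readBin(con, "numeric", n, size = 4, endian = endian),
    float64 = readBin(con, "numeric", n, size = 8, endian = endian)
  )
}

write_meta_raw <- function(vol, path, is_label) {
  nd <- n_dims(vol)
  arr <- aperm(vol$data, rev(seq_len(nd)))
  if (is_label) {
    mx <- max(arr)
    et <- if (mx < 256) "MET_UCHAR" else if (mx < 32768) "MET_SHORT" else "MET_INT"
    size <- c(MET_UCHAR = 1, MET_SHORT = 2, MET_INT = 4)[[et]]
    what <- as.integer(arr)
  } else {
    et <- "MET_FLOAT"; size <- 4
    what <- as.double(arr)
  }
  local_data <- grepl("\\.mha$", tolower(path))
  datafile <- if (local_data) "LOCAL" else paste0(
    sub("\\.mhd$", "", basename(path), ignore.case = TRUE), ".raw")
  hdr <- c(
    "ObjectType = Image",
    paste0("NDims = ", nd),
    "BinaryData = True",
    "BinaryDataByteOrderMSB = False",
    "CompressedData = False",
    paste0("TransformMatrix = ",
           paste(as.integer(diag(nd)), collapse = " ")),
    paste0("Offset = ", paste(rev(vol$origin), collapse = " ")),
    paste0("ElementSpacing = ", paste(rev(vol$spacing), collapse = " ")),
    paste0("DimSize = ", paste(dim(arr), collapse = " ")),
    paste0("ElementType = ", et),
    paste0("ElementDataFile = ", datafile)
  )
  con <- file(path, "wb")
  on.exit(close(con), add = TRUE)
  writeLines(hdr, con)
  if (local_data) {
    writeBin(what, con, size = size, endian = "little")
  } else {
    rcon <- file(file.path(dirname(path), datafile), "wb")
    on.exit(close(rcon), add = TRUE)
    writeBin(what, rcon, size = size, endian = "little")
  }
  invisible(path)
}

# ---- PNG --------------------------------------------------------------------

read_png_raw <- function(path) {
  arr <- png::readPNG(path, info = TRUE)
  info <- attr(arr, "info")
  bit_depth <- if (!is.null(info$bit.depth)) info$bit.depth else 8L
  if (length(dim(arr)) == 3L) arr <- arr[, , 1L]   # gray taken from channel 1
  warning("read_volume: PNG carries no spacing metadata; using 1 mm per axis",
          call. = FALSE)
  scale <- 2^bit_depth - 1
  list(data = arr,                                 # (y, x), values in [0,1]
       spacing = c(1, 1), origin = c(0, 0),
       png_scale = scale)
}

write_png_raw <- function(vol, path, is_label) {
  if (n_dims(vol) != 2L) {
    stop("write_volume: PNG supports 2D volumes only", call. = FALSE)
  }
  if (is_label) {
    mx <- max(vol$data)
    if (mx > 65535) stop("write_volume: label values exceed 16-bit PNG range",
                         call. = FALSE)
    scale <- if (mx > 255) 65535 else 255
    png::writePNG(vol$data / scale, path)
  } else {
    d <- vol$data
    if (min(d) < 0 || max(d) > 1) {
      warning("write_volume: image rescaled to [0,1] for PNG", call. = FALSE)
      rng <- range(d)
      d <- if (diff(rng) > 0) (d - rng[1]) / diff(rng) else d * 0
    }
    png::writePNG(d, path)
  }
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
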