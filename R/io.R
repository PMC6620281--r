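#' @title Image and config I/O
#' @name io
#' @description Readers and writers for the formats the pipeline touches:
#'   16-bit PNG, plain-text PGM (P2), CSV matrices, a minimal NIfTI-1
#'   reader/writer (pixel spacing in the header) and a minimal single-frame
#'   explicit-VR little-endian DICOM reader (PixelSpacing, rescale slope /
#'   intercept applied). YAML/JSON configuration files.
NULL

read_config_file <- function(path) {
  if (!file.exists(path)) stop_io("config file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml")) yaml::read_yaml(path)
  else if (ext == "json") jsonlite::read_json(path, simplifyVector = TRUE)
  else stop_io("unsupported config format '", ext, "' (use .yaml/.yml/.json)")
}

# CRC32 (PNG chunk checksum), table-driven.
png_crc_table <- local({
  tab <- NULL
  function() {
    if (is.null(tab)) {
      t <- integer(256)
      for (n in 0:255) {
        c <- n
        for (k in 1:8) {
          c <- if (bitwAnd(c, 1L) != 0L) {
            bitwXor(bitwShiftR(c, 1), -306674912L) # 0xEDB88320 as signed
          } else bitwShiftR(c, 1)
        }
        t[n + 1] <- c
      }
      tab <<- t
    }
    tab
  }
})

crc32_raw <- function(bytes) {
  tab <- png_crc_table()
  crc <- -1L # 0xFFFFFFFF
  for (b in as.integer(bytes)) {
    crc <- bitwXor(bitwShiftR(bitwAnd(crc, -256L), 8),
                   tab[bitwAnd(bitwXor(crc, b), 255L) + 1L])
    # bitwShiftR on negative ints is arithmetic; mask the top byte back in
    crc <- bitwAnd(crc, -1L)
  }
  bitwXor(crc, -1L)
}

u32be <- function(x) {
  as.raw(c(x %/% 16777216, (x %/% 65536) %% 256, (x %/% 256) %% 256, x %% 256))
}

png_chunk <- function(type, payload) {
  body <- c(charToRaw(type), payload)
  c(u32be(length(payload)), body,
    u32be(as.numeric(crc32_raw(body)) %% 2^32))
}

#' Write a matrix as 16-bit grayscale PNG
#'
#' Intensities are linearly rescaled to the full 16-bit range; the scale and
#' offset are returned so the mapping is invertible. (Hand-rolled writer: the
#' available PNG bindings only write 8-bit, which would quantize away the
#' sub-pixel contrast the pipeline depends on.)
#'
#' @param img numeric matrix.
#' @param path output path.
#' @return invisibly, `c(offset, scale)` with `img = png/65535 * scale + offset`.
#' @export
write_png16 <- function(img, path) {
  rng <- range(img)
  den <- if (diff(rng) > 0) diff(rng) else 1
  v <- round((img - rng[1]) / den * 65535)
  h <- nrow(img); w <- ncol(img)
  # scanlines: filter byte 0 + big-endian uint16 pixels, row-major
  vm <- t(v)
  hi <- as.raw(vm %/% 256); lo <- as.raw(vm %% 256)
  px <- as.raw(rbind(hi, lo)) # interleave hi/lo per pixel, row-major order
  dim(px) <- NULL
  rows <- split(px, rep(seq_len(h), each = 2 * w))
  scan <- unlist(lapply(rows, function(r) c(as.raw(0), r)), use.names = FALSE)
  zlib <- memCompress(scan, "gzip") # despite the name, this is a zlib stream
  ihdr <- c(u32be(w), u32be(h), as.raw(c(16, 0, 0, 0, 0)))
  out <- c(as.raw(c(137, 80, 78, 71, 13, 10, 26, 10)),
           png_chunk("IHDR", ihdr), png_chunk("IDAT", zlib),
           png_chunk("IEND", raw(0)))
  writeBin(out, path)
  invisible(c(offset = rng[1], scale = den))
}

read_png_gray <- function(path) {
  a <- png::readPNG(path)
  if (length(dim(a)) == 3) a <- a[, , 1]
  a * 65535
}

#' Write a matrix as plain-text PGM (P2)
#'
#' @param img numeric matrix; values are rounded and clamped to `maxval`.
#' @param path output path.
#' @param maxval maximum gray value (default 65535).
#' @export
write_pgm <- function(img, path, maxval = 65535L) {
  v <- pmin(pmax(round(img), 0), maxval)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P2", paste(ncol(img), nrow(img)), as.character(maxval)), con)
  apply(v, 1, function(r) writeLines(paste(r, collapse = " "), con))
  invisible(path)
}

read_pgm <- function(path) {
  toks <- scan(path, what = character(), comment.char = "#", quiet = TRUE)
  if (toks[1] != "P2") stop_io("only plain-text (P2) PGM is supported: ", path)
  w <- as.integer(toks[2]); h <- as.integer(toks[3])
  vals <- as.numeric(toks[-(1:4)])
  if (length(vals) != w * h) stop_io("corrupt PGM: expected ", w * h, " pixels")
  matrix(vals, nrow = h, ncol = w, byrow = TRUE)
}

# ---- minimal NIfTI-1 -------------------------------------------------------

#' Write a 2-D matrix as a NIfTI-1 file (float64)
#'
#' Double precision is kept so write/read round-trips are bit-exact.
#'
#' @param img numeric matrix.
#' @param path output path (`.nii`).
#' @param spacing pixel spacing in mm (scalar or length-2).
#' @export
write_nifti <- function(img, path, spacing = 1) {
  spacing <- rep(spacing, length.out = 2)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(348L, con, size = 4)                    # sizeof_hdr
  writeBin(raw(36), con)                           # unused
  dims <- c(2L, nrow(img), ncol(img), 1L, 1L, 1L, 1L, 1L)
  writeBin(as.integer(dims), con, size = 2)        # dim
  writeBin(raw(14), con)                           # intent params etc.
  writeBin(64L, con, size = 2)                     # datatype = float64
  writeBin(64L, con, size = 2)                     # bitpix
  writeBin(0L, con, size = 2)                      # slice_start
  writeBin(c(1, spacing[1], spacing[2], 1, 1, 1, 1, 1), con, size = 4) # pixdim
  writeBin(352, con, size = 4)                     # vox_offset
  writeBin(c(1, 0), con, size = 4)                 # scl_slope, scl_inter
  writeBin(raw(348 - 124), con)                    # remainder of header
  seek(con, 344)
  writeBin(charToRaw("n+1"), con)                  # magic
  writeBin(as.raw(0), con)
  seek(con, 348)
  writeBin(raw(4), con)                            # extension flag
  writeBin(as.numeric(img), con, size = 8)         # column-major voxels
  invisible(path)
}

#' Read a NIfTI-1 file (2-D or single-slice 3-D)
#'
#' Supports uint8/int16/int32/float32/float64 data, plain or gzipped, with
#' scl_slope/scl_inter applied.
#'
#' @param path `.nii` or `.nii.gz` path.
#' @param slice slice index if the volume has more than one.
#' @return list `intensities` (matrix), `spacing` (length-2, mm).
#' @export
read_nifti <- function(path, slice = 1L) {
  if (!file.exists(path)) stop_io("file not found: ", path)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rb") else file(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", 348)
  sz <- readBin(hdr[1:4], "integer", 1, size = 4)
  endian <- "little"
  if (sz != 348L) {
    sz <- readBin(hdr[1:4], "integer", 1, size = 4, endian = "big")
    if (sz != 348L) stop_io("not a NIfTI-1 file: ", path)
    endian <- "big"
  }
  rd <- function(off, what, n, size) {
    readBin(hdr[(off + 1):(off + n * size)], what, n, size = size, endian = endian)
  }
  dim0 <- rd(40, "integer", 8, 2)
  datatype <- rd(70, "integer", 1, 2)
  pixdim <- rd(76, "numeric", 8, 4)
  vox_offset <- rd(108, "numeric", 1, 4)
  scl_slope <- rd(112, "numeric", 1, 4)
  scl_inter <- rd(116, "numeric", 1, 4)
  nd <- dim0[1]
  nx <- dim0[2]; ny <- max(dim0[3], 1L); nz <- if (nd >= 3) max(dim0[4], 1L) else 1L
  spec <- switch(as.character(datatype),
    "2" = list(what = "integer", size = 1, signed = FALSE),
    "4" = list(what = "integer", size = 2, signed = TRUE),
    "8" = list(what = "integer", size = 4, signed = TRUE),
    "16" = list(what = "numeric", size = 4, signed = TRUE),
    "64" = list(what = "numeric", size = 8, signed = TRUE),
    stop_io("unsupported NIfTI datatype code ", datatype))
  skip <- vox_offset - 348
  if (skip > 0) readBin(con, "raw", skip)
  n <- nx * ny * nz
  v <- readBin(con, spec$what, n, size = spec$size, signed = spec$signed,
               endian = endian)
  if (nz > 1L) {
    if (slice < 1 || slice > nz) {
      stop_io("slice ", slice, " out of range; volume has ", nz,
              " slices (select 1..", nz, ")")
    }
    v <- v[((slice - 1) * nx * ny + 1):(slice * nx * ny)]
  }
  if (is.finite(scl_slope) && scl_slope != 0 && !(scl_slope == 1 && scl_inter == 0)) {
    v <- v * scl_slope + scl_inter
  }
  list(intensities = matrix(v, nrow = nx, ncol = ny),
       spacing = c(pixdim[2], pixdim[3]))
}

# ---- minimal DICOM reader --------------------------------------------------

# Single-frame, explicit-VR little-endian, uncompressed DICOM only.
read_dicom_minimal <- function(path) {
  if (!file.exists(path)) stop_io("file not found: ", path)
  raw <- readBin(path, "raw", file.size(path))
  if (length(raw) < 132 || rawToChar(raw[129:132]) != "DICM") {
    stop_io("not a DICOM part-10 file (missing DICM magic): ", path)
  }
  pos <- 133L
  u16 <- function(p) readBin(raw[p:(p + 1)], "integer", 1, 2, signed = FALSE,
                             endian = "little")
  u32 <- function(p) readBin(raw[p:(p + 3)], "integer", 1, 4, endian = "little")
  elems <- list()
  long_vrs <- c("OB", "OW", "OF", "SQ", "UT", "UN")
  while (pos + 8 <= length(raw) + 1) {
    grp <- u16(pos); el <- u16(pos + 2L)
    vr <- rawToChar(raw[(pos + 4L):(pos + 5L)])
    if (vr %in% long_vrs) {
      len <- u32(pos + 8L)
      hdr <- 12L
    } else {
      len <- u16(pos + 6L)
      hdr <- 8L
    }
    if (len < 0) stop_io("undefined-length DICOM elements are not supported")
    tag <- sprintf("%04x%04x", grp, el)
    val_raw <- if (len > 0) raw[(pos + hdr):(pos + hdr + len - 1L)] else raw(0)
    elems[[tag]] <- list(vr = vr, raw = val_raw)
    pos <- pos + hdr + len
    if (tag == "7fe00010") break
  }
  getstr <- function(tag) {
    e <- elems[[tag]]
    if (is.null(e)) return(NULL)
    trimws(rawToChar(e$raw))
  }
  getu16 <- function(tag) {
    e <- elems[[tag]]
    if (is.null(e)) return(NULL)
    readBin(e$raw, "integer", 1, 2, signed = FALSE, endian = "little")
  }
  rows <- getu16("00280010"); cols <- getu16("00280011")
  if (is.null(rows) || is.null(cols)) stop_io("DICOM lacks Rows/Columns")
  spacing_str <- getstr("00280030")
  spacing <- if (!is.null(spacing_str)) {
    as.numeric(strsplit(spacing_str, "\\\\")[[1]])
  } else NULL
  bits <- getu16("00280100"); if (is.null(bits)) bits <- 16L
  pixrep <- getu16("00280103"); if (is.null(pixrep)) pixrep <- 0L
  slope <- getstr("00281053"); slope <- if (is.null(slope)) 1 else as.numeric(slope)
  inter <- getstr("00281052"); inter <- if (is.null(inter)) 0 else as.numeric(inter)
  px <- elems[["7fe00010"]]
  if (is.null(px)) stop_io("DICOM lacks PixelData")
  size <- bits / 8
  n <- rows * cols
  if (length(px$raw) < n * size) stop_io("truncated PixelData")
  v <- readBin(px$raw, "integer", n, size = size, signed = pixrep == 1L,
               endian = "little")
  img <- matrix(v * slope + inter, nrow = rows, ncol = cols, byrow = TRUE)
  list(intensities = img, spacing = spacing)
}

#' Read a 2-D slice from disk
#'
#' Supported formats: `dicom` (single-frame explicit-VR little-endian),
#' `nifti` (`.nii`/`.nii.gz`), `png`, `pgm` (plain text), `csv` (numeric
#' matrix, no header). Pixel spacing comes from the DICOM PixelSpacing tag or
#' the NIfTI pixdim; PNG/PGM/CSV require the `spacing` argument.
#'
#' @param path file path.
#' @param format one of `"auto"`, `"dicom"`, `"nifti"`, `"png"`, `"pgm"`,
#'   `"csv"`. `"auto"` infers from the extension (`.dcm`, `.nii`, `.nii.gz`,
#'   `.png`, `.pgm`, `.csv`).
#' @param spacing mm/pixel, required for formats without embedded spacing.
#' @param slice slice index for multi-slice NIfTI volumes.
#' @return an [lsn_slice()].
#' @export
read_slice <- function(path, format = "auto", spacing = NULL, slice = 1L) {
  if (!file.exists(path)) stop_io("file not found: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(sub("\\.gz$", "", path)))
    format <- switch(ext, dcm = "dicom", nii = "nifti", png = "png",
                     pgm = "pgm", csv = "csv",
                     stop_io("cannot infer format from extension '", ext, "'"))
  }
  res <- switch(format,
    dicom = read_dicom_minimal(path),
    nifti = read_nifti(path, slice = slice),
    png = list(intensities = read_png_gray(path), spacing = NULL),
    pgm = list(intensities = read_pgm(path), spacing = NULL),
    csv = list(intensities = as.matrix(utils::read.csv(path, header = FALSE)),
               spacing = NULL),
    stop_io("unknown format: ", format))
  sp <- res$spacing
  if (is.null(sp) || !all(is.finite(sp))) {
    if (is.null(spacing)) {
      stop_io(format, " input carries no pixel spacing; pass spacing= (mm/pixel)")
    }
    sp <- spacing
  }
  lsn_slice(res$intensities, pixel_spacing = sp[1],
            metadata = list(path = path, format = format))
}

#' Write a contour as CSV
#'
#' Columns: `index, row, col, cumulative_arclength_mm`.
#'
#' @param contour an `lsn_contour`.
#' @param path output path.
#' @export
write_contour_csv <- function(contour, path) {
  stopifnot(inherits(contour, "lsn_contour"))
  cl <- contour_cumlen(contour) * contour$pixel_spacing
  n <- nrow(contour$points)
  utils::write.csv(data.frame(index = seq_len(n),
                              row = contour$points[, "row"],
                              col = contour$points[, "col"],
                              cumulative_arclength_mm = cl[seq_len(n)]),
                   path, row.names = FALSE)
  invisible(path)
}

#' Write a subject result as JSON
#'
#' Deterministic content: identical measurements produce byte-identical
#' files (timestamps live in the run log, not here).
#'
#' @param result a `subject_lsn` from [measure_subject()].
#' @param path output path.
#' @export
write_subject_json <- function(result, path) {
  stopifnot(inherits(result, "subject_lsn"))
  rois <- lapply(result$measurements, function(m) {
    list(roi_id = m$roi_id, n_points = m$n_points, mean_sq = m$mean_sq,
         variance = m$variance, sd = m$sd, lsn_roi = m$lsn_roi)
  })
  prov <- result$provenance
  prov$elapsed_seconds <- NULL # non-deterministic; kept in the log only
  obj <- list(subject_id = result$subject_id, lsn_score = result$lsn_score,
              units = result$units, cv_percent = result$cv_percent,
              rois = rois, provenance = prov)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
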