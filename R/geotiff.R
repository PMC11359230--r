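# Minimal GeoTIFF reader/writer.
#
# Scope: uncompressed, strip-organized baseline TIFF with the GeoTIFF
# georeferencing tags (ModelPixelScale, ModelTiepoint, GeoKeyDirectory,
# GeoAsciiParams) and the GDAL_NODATA convention. Sample types: unsigned
# 8/16/32-bit and signed 16/32-bit integers, 32/64-bit IEEE floats; chunky
# (pixel-interleaved) or planar band organization; either byte order on read,
# little-endian on write. Compressed or tiled TIFFs are rejected with a clear
# error; decompression is out of scope.

TIFF_TAGS <- c(ImageWidth = 256L, ImageLength = 257L, BitsPerSample = 258L,
               Compression = 259L, Photometric = 262L, StripOffsets = 273L,
               SamplesPerPixel = 277L, RowsPerStrip = 278L,
               StripByteCounts = 279L, PlanarConfig = 284L, TileWidth = 322L,
               SampleFormat = 339L, ModelPixelScale = 33550L,
               ModelTiepoint = 33922L, GeoKeyDirectory = 34735L,
               GeoDoubleParams = 34736L, GeoAsciiParams = 34737L,
               GDAL_NODATA = 42113L)

# ---- low-level byte helpers (little-endian on write) ----

le_u16 <- function(x) writeBin(as.integer(x), raw(), size = 2L, endian = "little")
le_u32 <- function(x) writeBin(as.integer(x), raw(), size = 4L, endian = "little")
le_f32 <- function(x) writeBin(as.numeric(x), raw(), size = 4L, endian = "little")
le_f64 <- function(x) writeBin(as.numeric(x), raw(), size = 8L, endian = "little")

# writeBin() refuses integers >= 2^31; route wide unsigned values through
# explicit byte arithmetic.
le_u32_wide <- function(x) {
  x <- as.numeric(x)
  b <- vapply(x, function(v) as.raw(c(v %% 256, (v %/% 256) %% 256,
                                      (v %/% 65536) %% 256,
                                      (v %/% 16777216) %% 256)), raw(4))
  as.raw(b)
}

# ---- writer ----

tiff_type_size <- c(`1` = 1L, `2` = 1L, `3` = 2L, `4` = 4L, `5` = 8L,
                    `11` = 4L, `12` = 8L)

encode_tag_value <- function(type, values) {
  switch(as.character(type),
         `2` = c(charToRaw(paste(values, collapse = "")), as.raw(0L)),
         `3` = le_u16(values),
         `4` = le_u32_wide(values),
         `12` = le_f64(values),
         stop("unsupported TIFF tag type on write: ", type))
}

#' Write a GeoTIFF raster
#'
#' Low-level writer used by [write_raster()]. Bands are written uncompressed
#' in a single strip, pixel-interleaved, little-endian.
#'
#' @param planes A numeric matrix or a list of matrices (bands) sharing one
#'   shape, in row/column orientation (rows = image rows, north at row 1).
#' @param path Output file path.
#' @param grid A [grid_geometry()] providing the geotransform and CRS.
#' @param type Storage type, one of `"Float32"`, `"Float64"`, `"UInt8"`,
#'   `"UInt16"`, `"UInt32"`, `"Int16"`, `"Int32"`.
#' @param nodata Optional nodata value recorded with the GDAL_NODATA
#'   convention; for float types `NA`/`NaN` cells are stored as NaN.
#' @return `path`, invisibly.
#' @keywords internal
#' @export
write_geotiff <- function(planes, path, grid, type = "Float32", nodata = NULL) {
  if (is.matrix(planes)) planes <- list(planes)
  if (!length(planes) || !all(vapply(planes, is.matrix, TRUE)))
    stop("planes must be a matrix or a list of matrices")
  nr <- nrow(planes[[1]]); nc <- ncol(planes[[1]])
  if (!all(vapply(planes, function(p) nrow(p) == nr && ncol(p) == nc, TRUE)))
    stop("all band planes must share one shape")
  stopifnot(inherits(grid, "grid_geometry"))
  if (grid$n_rows != nr || grid$n_cols != nc)
    stop("plane shape does not match the grid geometry")
  nb <- length(planes)

  spec <- switch(type,
                 Float32 = list(bits = 32L, fmt = 3L),
                 Float64 = list(bits = 64L, fmt = 3L),
                 UInt8   = list(bits = 8L,  fmt = 1L),
                 UInt16  = list(bits = 16L, fmt = 1L),
                 UInt32  = list(bits = 32L, fmt = 1L),
                 Int16   = list(bits = 16L, fmt = 2L),
                 Int32   = list(bits = 32L, fmt = 2L),
                 stop("unsupported storage type: ", type))

  # pixel-interleaved vector: band fastest, then column, then row
  arr <- array(unlist(planes, use.names = FALSE), dim = c(nr, nc, nb))
  v <- as.vector(aperm(arr, c(3L, 2L, 1L)))
  if (spec$fmt == 3L) {
    v[is.na(v)] <- NaN
    data <- writeBin(as.numeric(v), raw(), size = spec$bits %/% 8L,
                     endian = "little")
  } else {
    if (!is.null(nodata)) v[is.na(v)] <- nodata
    if (anyNA(v)) stop("NA cells in an integer raster need a nodata value")
    v <- round(v)
    data <- if (spec$bits == 8L) as.raw(v)
            else if (spec$bits == 16L) le_u16(v)
            else le_u32_wide(v)
  }

  # GeoTIFF keys
  epsg <- NA_integer_
  if (grepl("^EPSG:[0-9]+$", grid$crs, ignore.case = TRUE))
    epsg <- as.integer(sub("^EPSG:", "", grid$crs, ignore.case = TRUE))
  geographic <- !is.na(epsg) && epsg >= 4000L && epsg < 5000L
  citation <- if (nzchar(grid$crs)) paste0(grid$crs, "|") else NULL
  keys <- list(c(1024L, 0L, 1L, if (geographic) 2L else 1L),  # model type
               c(1025L, 0L, 1L, 1L))                          # raster: PixelIsArea
  if (!is.null(citation))
    keys <- c(keys, list(c(1026L, TIFF_TAGS[["GeoAsciiParams"]], nchar(citation), 0L)))
  if (!is.na(epsg))
    keys <- c(keys, list(c(if (geographic) 2048L else 3072L, 0L, 1L, epsg)))
  keydir <- c(1L, 1L, 0L, length(keys), unlist(keys))

  tags <- list(
    list(TIFF_TAGS[["ImageWidth"]], 4L, nc),
    list(TIFF_TAGS[["ImageLength"]], 4L, nr),
    list(TIFF_TAGS[["BitsPerSample"]], 3L, rep(spec$bits, nb)),
    list(TIFF_TAGS[["Compression"]], 3L, 1L),
    list(TIFF_TAGS[["Photometric"]], 3L, 1L),
    list(TIFF_TAGS[["StripOffsets"]], 4L, 0),     # patched below
    list(TIFF_TAGS[["SamplesPerPixel"]], 3L, nb),
    list(TIFF_TAGS[["RowsPerStrip"]], 4L, nr),
    list(TIFF_TAGS[["StripByteCounts"]], 4L, length(data)),
    list(TIFF_TAGS[["PlanarConfig"]], 3L, 1L),
    list(TIFF_TAGS[["SampleFormat"]], 3L, rep(spec$fmt, nb)),
    list(TIFF_TAGS[["ModelPixelScale"]], 12L,
         c(grid$pixel_size_x, grid$pixel_size_y, 0)),
    list(TIFF_TAGS[["ModelTiepoint"]], 12L,
         c(0, 0, 0, grid$origin_x, grid$origin_y, 0)),
    list(TIFF_TAGS[["GeoKeyDirectory"]], 3L, keydir))
  if (!is.null(citation))
    tags <- c(tags, list(list(TIFF_TAGS[["GeoAsciiParams"]], 2L, citation)))
  if (!is.null(nodata))
    tags <- c(tags, list(list(TIFF_TAGS[["GDAL_NODATA"]], 2L,
                              format(nodata, scientific = FALSE))))
  tags <- tags[order(vapply(tags, function(t) t[[1]], 1L))]

  n_entries <- length(tags)
  ifd_offset <- 8L
  ifd_size <- 2L + 12L * n_entries + 4L
  ext_offset <- ifd_offset + ifd_size

  encoded <- lapply(tags, function(t) encode_tag_value(t[[2]], t[[3]]))
  counts <- vapply(seq_along(tags), function(i) {
    if (tags[[i]][[2]] == 2L) length(encoded[[i]]) else length(tags[[i]][[3]])
  }, 1L)
  sizes <- vapply(seq_along(tags), function(i)
    counts[i] * tiff_type_size[[as.character(tags[[i]][[2]])]], 1)
  external <- sizes > 4

  offs <- ext_offset
  value_field <- vector("list", n_entries)
  ext_chunks <- list()
  for (i in seq_along(tags)) {
    if (external[i]) {
      pad <- offs %% 2L  # word-align external values
      if (pad) { ext_chunks <- c(ext_chunks, list(as.raw(0L))); offs <- offs + 1L }
      value_field[[i]] <- le_u32_wide(offs)
      ext_chunks <- c(ext_chunks, list(encoded[[i]]))
      offs <- offs + length(encoded[[i]])
    } else {
      value_field[[i]] <- c(encoded[[i]],
                            raw(4L - length(encoded[[i]])))
    }
  }
  pad_data <- offs %% 2L
  data_offset <- offs + pad_data

  # patch StripOffsets now that the data offset is known
  strip_idx <- which(vapply(tags, function(t)
    t[[1]] == TIFF_TAGS[["StripOffsets"]], TRUE))
  value_field[[strip_idx]] <- le_u32_wide(data_offset)

  entries <- lapply(seq_along(tags), function(i)
    c(le_u16(tags[[i]][[1]]), le_u16(tags[[i]][[2]]),
      le_u32_wide(counts[i]), value_field[[i]]))

  out <- c(charToRaw("II"), le_u16(42L), le_u32_wide(ifd_offset),
           le_u16(n_entries), unlist(entries), le_u32_wide(0L),
           unlist(ext_chunks), if (pad_data) as.raw(0L), data)
  writeBin(out, path)
  invisible(path)
}

# ---- reader ----

read_tag_values <- function(buf, type, count, field, endian) {
  size <- tiff_type_size[[as.character(type)]]
  if (is.null(size)) return(NULL)
  nbytes <- size * count
  bytes <- if (nbytes <= 4L) field[seq_len(nbytes)] else {
    off <- readBin(field, "integer", size = 4L, endian = endian)
    off <- as.numeric(off); if (off < 0) off <- off + 4294967296
    buf[(off + 1L):(off + nbytes)]
  }
  switch(as.character(type),
         `1` = as.integer(bytes),
         `2` = {
           s <- rawToChar(bytes[bytes != as.raw(0L)])
           s
         },
         `3` = readBin(bytes, "integer", n = count, size = 2L,
                       signed = FALSE, endian = endian),
         `4` = {
           v <- readBin(bytes, "integer", n = count, size = 4L, endian = endian)
           v <- as.numeric(v); v[v < 0] <- v[v < 0] + 4294967296
           v
         },
         `5` = {
           v <- readBin(bytes, "integer", n = 2L * count, size = 4L,
                        endian = endian)
           v <- as.numeric(v); v[v < 0] <- v[v < 0] + 4294967296
           v[seq(1, length(v), 2)] / v[seq(2, length(v), 2)]
         },
         `11` = readBin(bytes, "double", n = count, size = 4L, endian = endian),
         `12` = readBin(bytes, "double", n = count, size = 8L, endian = endian))
}

rd_u32 <- function(buf, offset, endian) {
  v <- readBin(buf[(offset + 1L):(offset + 4L)], "integer", size = 4L,
               endian = endian)
  v <- as.numeric(v); if (v < 0) v <- v + 4294967296
  v
}

#' Read a GeoTIFF raster
#'
#' Low-level reader used by [read_scene()]. Handles uncompressed baseline
#' TIFFs (either byte order, strip-organized, chunky or planar) with GeoTIFF
#' georeferencing tags.
#'
#' @param path Path to a GeoTIFF file.
#' @return A list with `planes` (list of numeric matrices, one per band),
#'   `grid` (a [grid_geometry()]) and `nodata` (numeric or `NA`).
#' @keywords internal
#' @export
read_geotiff <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  buf <- readBin(path, "raw", n = file.info(path)$size)
  order_mark <- rawToChar(buf[1:2])
  endian <- switch(order_mark, II = "little", MM = "big",
                   stop(path, " is not a TIFF file"))
  magic <- readBin(buf[3:4], "integer", size = 2L, signed = FALSE,
                   endian = endian)
  if (magic != 42L) stop(path, " is not a TIFF file")
  ifd_off <- rd_u32(buf, 4L, endian)

  n_entries <- readBin(buf[(ifd_off + 1L):(ifd_off + 2L)], "integer",
                       size = 2L, signed = FALSE, endian = endian)
  tags <- list()
  for (i in seq_len(n_entries)) {
    base <- ifd_off + 2L + (i - 1L) * 12L
    tag <- readBin(buf[(base + 1L):(base + 2L)], "integer", size = 2L,
                   signed = FALSE, endian = endian)
    type <- readBin(buf[(base + 3L):(base + 4L)], "integer", size = 2L,
                    signed = FALSE, endian = endian)
    count <- rd_u32(buf, base + 4L, endian)
    field <- buf[(base + 9L):(base + 12L)]
    tags[[as.character(tag)]] <- read_tag_values(buf, type, count, field,
                                                 endian)
  }
  tg <- function(name, default = NULL) {
    v <- tags[[as.character(TIFF_TAGS[[name]])]]
    if (is.null(v)) default else v
  }

  if (!is.null(tg("TileWidth")))
    stop("tiled TIFFs are not supported; rewrite ", path, " strip-organized")
  if (tg("Compression", 1L)[1] != 1L)
    stop("compressed TIFFs are not supported; rewrite ", path, " uncompressed")

  nc <- as.integer(tg("ImageWidth")); nr <- as.integer(tg("ImageLength"))
  if (is.null(nc) || is.null(nr)) stop("TIFF lacks image dimensions")
  nb <- as.integer(tg("SamplesPerPixel", 1L))
  bits <- tg("BitsPerSample", 1L)
  if (length(unique(bits)) != 1L) stop("mixed bit depths are not supported")
  bits <- as.integer(bits[1])
  fmt <- as.integer(tg("SampleFormat", 1L)[1])
  planar <- as.integer(tg("PlanarConfig", 1L))

  offsets <- tg("StripOffsets")
  bytecounts <- tg("StripByteCounts")
  if (is.null(offsets) || is.null(bytecounts))
    stop("TIFF lacks strip layout tags")
  data <- do.call(c, lapply(seq_along(offsets), function(i)
    buf[(offsets[i] + 1L):(offsets[i] + bytecounts[i])]))

  n_vals <- as.numeric(nr) * nc * nb
  sz <- bits %/% 8L
  if (length(data) < n_vals * sz) stop("TIFF pixel data is truncated")
  v <- if (fmt == 3L) {
    readBin(data, "double", n = n_vals, size = sz, endian = endian)
  } else if (bits == 8L) {
    as.numeric(readBin(data, "integer", n = n_vals, size = 1L,
                       signed = (fmt == 2L), endian = endian))
  } else if (bits == 16L) {
    as.numeric(readBin(data, "integer", n = n_vals, size = 2L,
                       signed = (fmt == 2L), endian = endian))
  } else {
    x <- as.numeric(readBin(data, "integer", n = n_vals, size = 4L,
                            endian = endian))
    if (fmt == 1L) x[x < 0] <- x[x < 0] + 4294967296
    x
  }

  planes <- if (planar == 2L) {
    arr <- array(v, dim = c(nc, nr, nb))
    lapply(seq_len(nb), function(b) t(arr[, , b]))
  } else {
    arr <- aperm(array(v, dim = c(nb, nc, nr)), c(3L, 2L, 1L))
    lapply(seq_len(nb), function(b) arr[, , b, drop = TRUE])
  }
  planes <- lapply(planes, function(p) matrix(p, nrow = nr, ncol = nc))

  scale <- tg("ModelPixelScale")
  tie <- tg("ModelTiepoint")
  if (is.null(scale) || is.null(tie))
    stop(path, " carries no georeferencing (ModelPixelScale/ModelTiepoint)")
  origin_x <- tie[4] - tie[1] * scale[1]
  origin_y <- tie[5] + tie[2] * scale[2]

  crs <- ""
  keydir <- tg("GeoKeyDirectory")
  if (!is.null(keydir) && length(keydir) >= 4L) {
    nk <- keydir[4]
    for (k in seq_len(nk)) {
      key <- keydir[4L * k + 1L]; loc <- keydir[4L * k + 2L]
      val <- keydir[4L * k + 4L]
      if (key %in% c(2048L, 3072L) && loc == 0L && val > 0L && val < 65535L)
        crs <- paste0("EPSG:", val)
    }
    if (!nzchar(crs)) {
      ascii <- tg("GeoAsciiParams")
      if (!is.null(ascii)) crs <- sub("\\|.*$", "", ascii)
    }
  }

  nodata <- NA_real_
  nd <- tg("GDAL_NODATA")
  if (!is.null(nd)) {
    nd <- trimws(nd)
    nodata <- if (tolower(nd) %in% c("nan", "-nan")) NaN else
      suppressWarnings(as.numeric(nd))
  }

  grid <- grid_geometry(nr, nc, scale[1], scale[2], origin_x, origin_y, crs)
  list(planes = planes, grid = grid, nodata = nodata)
}
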