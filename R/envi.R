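# --- ENVI header/data I/O ---------------------------------------------------

# ENVI numeric data-type codes supported here
envi_types <- list(`4` = list(what = "numeric", size = 4L),   # float32
                   `5` = list(what = "numeric", size = 8L),   # float64
                   `12` = list(what = "integer", size = 2L))  # uint16

parse_envi_header <- function(header_path) {
  txt <- readLines(header_path, warn = FALSE)
  if (!grepl("^ENVI", txt[1]))
    stop("not an ENVI header (missing ENVI magic line): ", header_path)
  body <- paste(txt[-1], collapse = "\n")
  fields <- list()
  # split on newlines that start a `key = value` assignment
  lines <- strsplit(body, "\n")[[1]]
  cur <- NULL
  for (ln in lines) {
    if (grepl("=", ln) && is.null(cur)) {
      kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
      key <- tolower(trimws(kv[1]))
      val <- trimws(paste(kv[-1], collapse = "="))
      if (grepl("\\{", val) && !grepl("\\}", val)) {
        cur <- list(key = key, val = val)
      } else fields[[key]] <- val
    } else if (!is.null(cur)) {
      cur$val <- paste(cur$val, trimws(ln))
      if (grepl("\\}", ln)) {
        fields[[cur$key]] <- cur$val
        cur <- NULL
      }
    }
  }
  fields
}

header_num <- function(fields, key) {
  v <- fields[[key]]
  if (is.null(v)) stop("ENVI header missing field: ", key)
  as.numeric(v)
}

header_list <- function(fields, key) {
  v <- fields[[key]]
  if (is.null(v)) return(NULL)
  v <- gsub("[{}]", "", v)
  as.numeric(trimws(strsplit(v, ",")[[1]]))
}

#' Read an ENVI hyperspectral cube
#'
#' Reads the text header and binary payload and returns the cube in
#' rows x cols x bands order regardless of the interleave on disk.
#' Supported dialects: interleaves BSQ/BIL/BIP, data types float32 (4),
#' float64 (5) and uint16 (12), both byte orders.
#'
#' @param header_path Path to the `.hdr` text header.
#' @param data_path Path to the binary cube; default is `header_path`
#'   without its `.hdr` extension.
#' @param kind Cube kind to stamp on the result (`"reflectance"` or
#'   `"raw"`); ENVI itself does not record this. Default `"reflectance"`.
#' @return A [hypercube()].
#' @export
read_envi <- function(header_path, data_path = NULL, kind = "reflectance") {
  if (is.null(data_path)) data_path <- sub("\\.hdr$", "", header_path)
  f <- parse_envi_header(header_path)
  samples <- header_num(f, "samples")  # columns
  lines <- header_num(f, "lines")      # rows
  bands <- header_num(f, "bands")
  dtype <- as.character(header_num(f, "data type"))
  interleave <- toupper(trimws(f[["interleave"]] %||% "BSQ"))
  byte_order <- header_num(f, "byte order")
  endian <- if (byte_order == 0) "little" else "big"
  wl <- header_list(f, "wavelength")
  if (is.null(wl)) stop("ENVI header missing wavelength list")
  if (length(wl) != bands)
    stop("ENVI format error: header declares ", bands, " bands but lists ",
         length(wl), " wavelengths")
  tp <- envi_types[[dtype]]
  if (is.null(tp))
    stop("unsupported ENVI data type code: ", dtype,
         " (supported: 4 float32, 5 float64, 12 uint16)")
  n <- samples * lines * bands
  expect_bytes <- n * tp$size
  if (file.size(data_path) != expect_bytes)
    stop("ENVI format error: payload is ", file.size(data_path),
         " bytes, header implies ", expect_bytes)
  con <- file(data_path, "rb")
  on.exit(close(con))
  v <- readBin(con, tp$what, n = n, size = tp$size, endian = endian,
               signed = tp$size > 2)
  if (tp$what == "integer") {
    v <- as.numeric(v)
    v[v < 0] <- v[v < 0] + 65536  # uint16 read as signed short
  }
  # on-disk fastest-varying order: BSQ = (col, row, band); BIL = (col, band,
  # row); BIP = (band, col, row)
  arr <- switch(interleave,
    BSQ = aperm(array(v, dim = c(samples, lines, bands)), c(2, 1, 3)),
    BIL = aperm(array(v, dim = c(samples, bands, lines)), c(3, 1, 2)),
    BIP = aperm(array(v, dim = c(bands, samples, lines)), c(3, 2, 1)),
    stop("unsupported interleave: ", interleave))
  hypercube(arr, wl, kind)
}

#' Write a hypercube as an ENVI header + binary pair
#'
#' @param cube A [hypercube()].
#' @param path Output path for the binary cube; the header is written to
#'   `paste0(path, ".hdr")`.
#' @param interleave One of `"BSQ"`, `"BIL"`, `"BIP"`; default BSQ.
#' @param data_type ENVI type code: 4 (float32, default), 5 (float64) or
#'   12 (uint16).
#' @param byte_order 0 little-endian (default) or 1 big-endian.
#' @return `path`, invisibly.
#' @export
write_envi <- function(cube, path, interleave = "BSQ", data_type = 4,
                       byte_order = 0) {
  stopifnot(inherits(cube, "hypercube"))
  interleave <- toupper(interleave)
  tp <- envi_types[[as.character(data_type)]]
  if (is.null(tp)) stop("unsupported ENVI data type code: ", data_type)
  d <- dim(cube$data)
  rows <- d[1]; cols <- d[2]; bands <- d[3]
  arr <- switch(interleave,
    BSQ = aperm(cube$data, c(2, 1, 3)),
    BIL = aperm(cube$data, c(2, 3, 1)),
    BIP = aperm(cube$data, c(3, 2, 1)),
    stop("unsupported interleave: ", interleave))
  v <- as.vector(arr)
  endian <- if (byte_order == 0) "little" else "big"
  con <- file(path, "wb")
  if (tp$what == "integer") {
    iv <- as.integer(round(v))
    if (any(iv < 0 | iv > 65535))
      stop("values outside uint16 range; use a float data type")
    iv[iv > 32767] <- iv[iv > 32767] - 65536L  # store as signed short bits
    writeBin(iv, con, size = 2L, endian = endian)
  } else {
    writeBin(v, con, size = tp$size, endian = endian)
  }
  close(con)
  hdr <- c(
    "ENVI",
    "description = { hypersort export }",
    paste0("samples = ", cols),
    paste0("lines = ", rows),
    paste0("bands = ", bands),
    "header offset = 0",
    "file type = ENVI Standard",
    paste0("data type = ", data_type),
    paste0("interleave = ", tolower(interleave)),
    paste0("byte order = ", byte_order),
    paste0("wavelength units = Nanometers"),
    paste0("wavelength = { ",
           paste(format(cube$wavelengths, trim = TRUE), collapse = ", "),
           " }"))
  writeLines(hdr, paste0(path, ".hdr"))
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
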