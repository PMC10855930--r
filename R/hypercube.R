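#' Construct a hyperspectral cube
#'
#' A hypercube is a rows x cols x bands array with an attached wavelength
#' axis. `kind` records whether values are raw sensor counts or calibrated
#' relative reflectance.
#'
#' @param data Numeric 3-d array, rows x cols x bands, non-negative for raw
#'   cubes (reflectance cubes may go slightly negative when the scene is
#'   darker than the dark reference).
#' @param wavelengths Numeric vector of band centers in nm; length must equal
#'   `dim(data)[3]`.
#' @param kind Either `"raw"` or `"reflectance"`.
#' @return An object of class `hypercube`.
#' @export
hypercube <- function(data, wavelengths, kind = c("raw", "reflectance")) {
  kind <- match.arg(kind)
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a rows x cols x bands array")
  if (dim(data)[3] != length(wavelengths))
    stop("bands dimension (", dim(data)[3], ") does not match wavelength axis (",
         length(wavelengths), ")")
  if (is.unsorted(wavelengths, strictly = TRUE))
    stop("`wavelengths` must be strictly increasing")
  if (kind == "reflectance" && !all(is.finite(data)))
    stop("reflectance cube contains non-finite values")
  structure(list(data = data, wavelengths = as.numeric(wavelengths), kind = kind),
            class = "hypercube")
}

#' @export
print.hypercube <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("hypercube: %d x %d pixels, %d bands (%.0f-%.0f nm), kind=%s\n",
              d[1], d[2], d[3], min(x$wavelengths), max(x$wavelengths), x$kind))
  invisible(x)
}

#' @export
dim.hypercube <- function(x) dim(x$data)

#' Construct a per-object spectrum table
#'
#' The feature table every statistical stage runs on: one row per seed
#' (object), one column per wavelength, holding that object's mean
#' reflectance spectrum.
#'
#' @param spectra Numeric matrix, n_objects x n_bands.
#' @param wavelengths Band centers in nm, length `ncol(spectra)`.
#' @param labels Optional character/factor vector of class names per object.
#' @param object_ids Optional integer ids (provenance); default 1..n.
#' @param pixel_counts Optional per-object pixel counts.
#' @return An object of class `spectrum_table`.
#' @export
spectrum_table <- function(spectra, wavelengths, labels = NULL,
                           object_ids = NULL, pixel_counts = NULL) {
  spectra <- as.matrix(spectra)
  if (ncol(spectra) != length(wavelengths))
    stop("spectra columns do not match wavelength axis")
  if (is.unsorted(wavelengths, strictly = TRUE))
    stop("`wavelengths` must be strictly increasing")
  if (nrow(spectra) < 1L) stop("empty spectrum table")
  if (!all(is.finite(spectra))) stop("non-finite spectra")
  if (!is.null(labels) && length(labels) != nrow(spectra))
    stop("labels length does not match rows")
  if (is.null(object_ids)) object_ids <- seq_len(nrow(spectra))
  structure(list(spectra = spectra, wavelengths = as.numeric(wavelengths),
                 labels = if (is.null(labels)) NULL else as.character(labels),
                 object_ids = object_ids, pixel_counts = pixel_counts),
            class = "spectrum_table")
}

#' @export
print.spectrum_table <- function(x, ...) {
  cat(sprintf("spectrum_table: %d objects x %d bands", nrow(x$spectra),
              ncol(x$spectra)))
  if (!is.null(x$labels)) {
    tab <- table(x$labels)
    cat(" [", paste(names(tab), tab, sep = ":", collapse = ", "), "]", sep = "")
  }
  cat("\n")
  invisible(x)
}

#' @export
dim.spectrum_table <- function(x) dim(x$spectra)

#' Coerce a spectrum table to a data frame
#'
#' Columns: `object_id`, `class`, `pixel_count`, then one reflectance column
#' per wavelength named `R0400` ... `R1700`. This is the interchange format
#' the analysis drivers write to disk.
#'
#' @param x A `spectrum_table`.
#' @param ... Unused.
#' @export
as.data.frame.spectrum_table <- function(x, ...) {
  df <- data.frame(
    object_id = x$object_ids,
    class = if (is.null(x$labels)) NA_character_ else x$labels,
    pixel_count = if (is.null(x$pixel_counts)) NA_integer_ else x$pixel_counts,
    stringsAsFactors = FALSE
  )
  sp <- x$spectra
  colnames(sp) <- sprintf("R%04d", round(x$wavelengths))
  cbind(df, as.data.frame(sp))
}

#' Rebuild a spectrum table from its data-frame form
#'
#' Inverse of [as.data.frame.spectrum_table()].
#'
#' @param df Data frame with `R<nnnn>` reflectance columns.
#' @return A `spectrum_table`.
#' @export
spectrum_table_from_df <- function(df) {
  rcols <- grep("^R[0-9]{4}$", names(df), value = TRUE)
  if (length(rcols) == 0L) stop("no R<nnnn> reflectance columns found")
  wl <- as.numeric(sub("^R", "", rcols))
  labels <- if ("class" %in% names(df) && !all(is.na(df$class))) df$class else NULL
  spectrum_table(as.matrix(df[, rcols, drop = FALSE]), wl, labels = labels,
                 object_ids = if ("object_id" %in% names(df)) df$object_id else NULL,
                 pixel_counts = if ("pixel_count" %in% names(df)) df$pixel_count else NULL)
}

#' Subset a spectrum table to selected wavelengths
#'
#' @param x A `spectrum_table`.
#' @param wavelengths Wavelengths (nm) to keep; must be present on the axis.
#' @return A `spectrum_table` restricted to those bands, in the given order.
#' @export
restrict_wavelengths <- function(x, wavelengths) {
  idx <- match(wavelengths, x$wavelengths)
  if (anyNA(idx))
    stop("wavelengths not on the table axis: ",
         paste(wavelengths[is.na(idx)], collapse = ", "))
  st <- x
  st$spectra <- x$spectra[, idx, drop = FALSE]
  st$wavelengths <- x$wavelengths[idx]
  st
}

# shared 5 nm acquisition grid, 400-1700 nm inclusive: 261 bands
standard_grid <- function() seq(400, 1700, by = 5)
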