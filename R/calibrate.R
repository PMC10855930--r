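# --- flat-field reflectance calibration -------------------------------------

#' Convert raw counts to relative reflectance with dark/white references
#'
#' Applies the flat-field normalisation `Rc = (R - D) / (W - D)` per pixel
#' and band, where `D` is the dark frame (0% reflectance, shutter closed)
#' and `W` the white reference panel frame. Reference frames may be full
#' cubes of the same shape or single-line acquisitions (1 x cols x bands),
#' which are broadcast across image rows as a line scanner would.
#'
#' Where the reference span `W - D <= eps` the pixel carries no usable
#' signal; the output is set to 0 there and the count of such pixels is
#' reported in the `degenerate_pixels` attribute (with a warning). Negative
#' reflectance (R < D) is kept by default so the normalisation stays exact;
#' `clip = TRUE` clamps the result into `[0, 1]`.
#'
#' @param raw Raw [hypercube()].
#' @param refs List with `dark` and `white` hypercubes.
#' @param clip Clamp output into `[0, 1]`? Default FALSE.
#' @param eps Reference-span floor on the raw-count scale; default 1e-12.
#' @return A reflectance [hypercube()] with attribute `degenerate_pixels`.
#' @export
calibrate <- function(raw, refs, clip = FALSE, eps = 1e-12) {
  stopifnot(inherits(raw, "hypercube"))
  dark <- refs$dark; white <- refs$white
  stopifnot(inherits(dark, "hypercube"), inherits(white, "hypercube"))
  d <- dim(raw$data)

  expand <- function(ref, what) {
    rd <- dim(ref$data)
    if (identical(rd, d)) return(ref$data)
    if (rd[1] == 1L && rd[2] == d[2] && rd[3] == d[3])  # single-line reference
      return(array(rep(ref$data, each = d[1]), dim = d))
    stop(what, " reference shape ", paste(rd, collapse = "x"),
         " does not match raw cube ", paste(d, collapse = "x"))
  }
  D <- expand(dark, "dark")
  W <- expand(white, "white")

  span <- W - D
  bad <- span <= eps
  nbad <- sum(bad)
  span[bad] <- 1  # placeholder; result overwritten with 0 below
  rc <- (raw$data - D) / span
  rc[bad] <- 0
  if (nbad > 0)
    warning("calibrate: ", nbad,
            " pixel/band cells had white - dark <= eps; set to 0")
  if (clip) rc <- pmin(pmax(rc, 0), 1)
  out <- hypercube(rc, raw$wavelengths, "reflectance")
  attr(out, "degenerate_pixels") <- nbad
  out
}
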