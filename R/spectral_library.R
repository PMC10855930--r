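# --- seeded evaluation ------------------------------------------------------

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  expr
}

# Gaussian-kernel smoother over the wavelength axis; `length_nm` is the
# kernel standard deviation. Returns the row-smoothed matrix.
smooth_rows <- function(x, wavelengths, length_nm) {
  d <- outer(wavelengths, wavelengths, function(a, b) a - b)
  k <- exp(-d^2 / (2 * length_nm^2))
  k <- k / rowSums(k)
  x %*% t(k)
}

default_classes <- c("broad_bean", "chickpea", "lentil", "wheat", "oat")

# --- spectral library -------------------------------------------------------

#' Build a synthetic spectral library with planted discriminative bands
#'
#' Generates one smooth endmember reflectance curve per seed class on the
#' 5 nm acquisition grid (400-1700 nm, 261 bands). All classes share a
#' common smooth base curve plus a small class-specific smooth perturbation;
#' for every class pair listed in `pair_contrasts`, localized reflectance
#' peaks of the requested contrast are planted at the given band centers,
#' with signs alternating along the pair's band list (the first class is
#' brighter at the first band, darker at the second, and so on). Away from
#' its planted bands a pair's endmembers differ by at most `contrast / 5`.
#'
#' @param pair_contrasts List of entries, each
#'   `list(pair = c("classA", "classB"), bands = c(...), contrast = x)`.
#'   Band centers must lie on the 5 nm grid; `contrast` is the minimum
#'   absolute reflectance difference planted at each band (0 allowed as the
#'   degenerate no-signal case, in which the two endmembers are identical).
#' @param smoothness Correlation length of the endmember curves in nm
#'   (Gaussian kernel sd); default 80.
#' @param classes Class names to include; default the three legumes and two
#'   gluten contaminants. `"stone"` (flat dark curve) and `"barley"` may be
#'   added explicitly.
#' @param rng_seed Integer seed; the draw is deterministic given it.
#' @return An object of class `spectral_library` with fields `wavelengths`,
#'   `endmembers` (class x band matrix in `[0,1]`), `class_names`,
#'   `informative_bands` (per-pair planted bands, contrasts and signs).
#' @export
make_spectral_library <- function(pair_contrasts = list(), smoothness = 80,
                                  classes = default_classes, rng_seed = 1L) {
  wl <- standard_grid()
  bump_sd <- 12  # nm; localized peak width, narrow against `smoothness`

  # validate pair specs
  for (pc in pair_contrasts) {
    if (!all(pc$pair %in% classes))
      stop("pair classes not in library: ", paste(pc$pair, collapse = ", "))
    off <- setdiff(pc$bands, wl)
    if (length(off))
      stop("planted band off the 5 nm grid in [400, 1700]: ",
           paste(off, collapse = ", "))
    if (pc$contrast < 0 || pc$contrast >= 1)
      stop("contrast must lie in [0, 1): got ", pc$contrast)
  }

  # class-specific perturbation amplitude: small, and zero for any class in a
  # zero-contrast pair so that such pairs come out identical
  amp <- stats::setNames(rep(0.01, length(classes)), classes)
  for (pc in pair_contrasts)
    amp[pc$pair] <- pmin(amp[pc$pair], pc$contrast / 12)

  with_seed(rng_seed, {
    base <- drop(smooth_rows(matrix(stats::rnorm(length(wl)), 1), wl, smoothness))
    base <- base - mean(base)
    # range-normalize: the shared base stays inside 0.40 +/- 0.12, leaving
    # headroom for planted peaks of contrast up to ~0.4
    base <- 0.40 + 0.12 * base / max(abs(base), 1e-12)
    pert <- smooth_rows(matrix(stats::rnorm(length(classes) * length(wl)),
                               length(classes)), wl, smoothness)
    pert <- pert - rowMeans(pert)
    # amplitude-normalize so each class deviates from the base by at most
    # `amp` anywhere — keeps the planted-contrast headroom guarantee exact
    pert <- pert / pmax(apply(abs(pert), 1, max), 1e-12) * amp
  })

  em <- matrix(rep(base, each = length(classes)), nrow = length(classes),
               dimnames = list(classes, NULL)) + pert
  if ("stone" %in% classes)
    em["stone", ] <- 0.08 + 0 * wl  # flat low-reflectance stand-in

  info <- list()
  for (pc in pair_contrasts) {
    bands <- sort(pc$bands)
    signs <- rep_len(c(1, -1), length(bands))
    for (j in seq_along(bands)) {
      # 20% headroom so the class perturbation (amplitude <= contrast/12 each)
      # cannot pull the planted difference below the requested contrast
      bump <- (pc$contrast / 2) * 1.2 * exp(-(wl - bands[j])^2 / (2 * bump_sd^2))
      em[pc$pair[1], ] <- em[pc$pair[1], ] + signs[j] * bump
      em[pc$pair[2], ] <- em[pc$pair[2], ] - signs[j] * bump
    }
    info[[paste(pc$pair, collapse = "|")]] <-
      list(pair = pc$pair, bands = bands, contrast = pc$contrast, signs = signs)
  }

  if (any(em < 0 | em > 1))
    stop("planted contrasts push endmember reflectance outside [0, 1]; ",
         "reduce contrast or overlapping pair constraints")

  # verify the planted-contrast postcondition
  for (key in names(info)) {
    pc <- info[[key]]
    d <- abs(em[pc$pair[1], ] - em[pc$pair[2], ])
    at <- match(pc$bands, wl)
    if (length(at) && any(d[at] < pc$contrast - 1e-9))
      stop("internal: planted contrast not achieved for pair ", key)
  }

  structure(list(wavelengths = wl, endmembers = em, class_names = classes,
                 informative_bands = info, smoothness = smoothness,
                 bump_sd = bump_sd),
            class = "spectral_library")
}

#' @export
print.spectral_library <- function(x, ...) {
  cat(sprintf("spectral_library: %d classes x %d bands\n",
              length(x$class_names), length(x$wavelengths)))
  for (key in names(x$informative_bands)) {
    pc <- x$informative_bands[[key]]
    cat(sprintf("  %s: bands {%s} contrast %.2f\n", key,
                paste(pc$bands, collapse = ", "), pc$contrast))
  }
  invisible(x)
}
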