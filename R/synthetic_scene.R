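# --- scene specification ----------------------------------------------------

#' Specify a synthetic acquisition scene
#'
#' Describes a tray of non-touching elliptical seeds imaged by a line
#' scanner: geometry per object, raw-count background (dark) level, additive
#' sensor noise, and a smooth multiplicative illumination profile across
#' columns (vignetting of the linear collimator).
#'
#' @param image_shape Integer c(rows, cols) in pixels.
#' @param objects Data frame with columns `class`, `row`, `col` (ellipse
#'   center, 0-based), `a`, `b` (semi-axes in px), `brightness`
#'   (multiplicative scale > 0).
#' @param background_level Dark raw-count level (sensor offset), counts.
#' @param noise_sd Additive Gaussian pixel noise sd, raw counts; default 8.
#' @param white_span Raw-count span between dark and white reference at unit
#'   illumination; default 4000.
#' @param illumination_profile Numeric vector of length `cols` (multiplicative,
#'   around 1), or NULL for a mild parabolic vignette.
#' @param rng_seed Integer seed for the pixel noise.
#' @return An object of class `scene_spec`.
#' @export
scene_spec <- function(image_shape, objects, background_level = 100,
                       noise_sd = 8, white_span = 4000,
                       illumination_profile = NULL, rng_seed = 1L) {
  stopifnot(length(image_shape) == 2L, all(image_shape >= 8L))
  need <- c("class", "row", "col", "a", "b", "brightness")
  if (!all(need %in% names(objects)))
    stop("objects must have columns: ", paste(need, collapse = ", "))
  if (any(objects$brightness <= 0)) stop("brightness_scale must be > 0")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (is.null(illumination_profile)) {
    u <- (seq_len(image_shape[2]) - (image_shape[2] + 1) / 2) /
      (image_shape[2] / 2)
    illumination_profile <- 1 - 0.08 * u^2
  }
  if (length(illumination_profile) != image_shape[2])
    stop("illumination profile length must equal column count")
  structure(list(image_shape = as.integer(image_shape), objects = objects,
                 background_level = background_level, noise_sd = noise_sd,
                 white_span = white_span,
                 illumination_profile = illumination_profile,
                 rng_seed = as.integer(rng_seed)),
            class = "scene_spec")
}

# nominal ellipse semi-axes (px) per class: broad bean large, lentil small
class_axes <- function(class) {
  ax <- list(broad_bean = c(11, 8), chickpea = c(7, 6.5), lentil = c(4.5, 4),
             wheat = c(6, 3), oat = c(7, 2.5), barley = c(6.5, 3),
             stone = c(5, 4))
  a <- ax[[class]]
  if (is.null(a)) c(6, 4) else a
}

#' Randomly place non-touching seeds on a scene
#'
#' Rejection-samples ellipse centers so that bounding circles (plus a 2 px
#' margin) are pairwise disjoint, guaranteeing the non-overlap invariant.
#'
#' @param classes Character vector, one entry per object to place.
#' @param image_shape c(rows, cols); default c(160, 220).
#' @param brightness_sdlog Lognormal sd of the per-seed brightness scale;
#'   default 0.05 (intact/broken unit variation on a tray).
#' @param rng_seed Integer seed.
#' @param ... Passed to [scene_spec()] (noise_sd, background_level, ...).
#' @return A `scene_spec`.
#' @export
random_scene_spec <- function(classes, image_shape = c(160L, 220L),
                              brightness_sdlog = 0.05, rng_seed = 1L, ...) {
  with_seed(rng_seed, {
    n <- length(classes)
    rows <- image_shape[1]; cols <- image_shape[2]
    placed <- data.frame(class = character(0), row = numeric(0),
                         col = numeric(0), a = numeric(0), b = numeric(0),
                         brightness = numeric(0))
    for (i in seq_len(n)) {
      ax <- class_axes(classes[i]) * stats::runif(1, 0.85, 1.15)
      r_eff <- max(ax) + 2
      ok <- FALSE
      for (try in 1:2000) {
        rc <- stats::runif(1, r_eff, rows - 1 - r_eff)
        cc <- stats::runif(1, r_eff, cols - 1 - r_eff)
        if (nrow(placed) == 0L ||
            all((placed$row - rc)^2 + (placed$col - cc)^2 >
                (pmax(placed$a, placed$b) + 2 + r_eff)^2)) {
          ok <- TRUE; break
        }
      }
      if (!ok) stop("could not place ", n, " non-touching objects in a ",
                    rows, "x", cols, " scene; enlarge the image")
      placed <- rbind(placed, data.frame(class = classes[i], row = rc,
                                         col = cc, a = ax[1], b = ax[2],
                                         brightness = exp(stats::rnorm(1, 0, brightness_sdlog))))
    }
    scene_spec(image_shape, placed, rng_seed = rng_seed, ...)
  })
}

# --- rendering --------------------------------------------------------------

#' Render a scene into a raw cube, reference frames and ground truth
#'
#' The sensor model is `raw = dark + illumination x reflectance x span +
#' noise`, with `reflectance = endmember x brightness` inside objects and a
#' low flat background (0.02) outside. The dark and white reference frames
#' are built from the same dark level and illumination profile and are
#' noiseless, so flat-field calibration of a noiseless object pixel recovers
#' `endmember x brightness` exactly.
#'
#' @param spec A [scene_spec()].
#' @param library A [make_spectral_library()] result.
#' @return List with elements `raw` (hypercube, raw counts), `refs`
#'   (list `dark`, `white` of raw hypercubes) and `truth` (list
#'   `label_image` rows x cols integer matrix, 0 = background, and
#'   `object_classes` named by object id).
#' @export
render_scene <- function(spec, library) {
  stopifnot(inherits(spec, "scene_spec"), inherits(library, "spectral_library"))
  missing_cls <- setdiff(spec$objects$class, library$class_names)
  if (length(missing_cls))
    stop("classes absent from library: ", paste(missing_cls, collapse = ", "))

  rows <- spec$image_shape[1]; cols <- spec$image_shape[2]
  wl <- library$wavelengths; nb <- length(wl)
  rr <- matrix(seq_len(rows) - 1, rows, cols)        # 0-based pixel coords
  cc <- matrix(seq_len(cols) - 1, rows, cols, byrow = TRUE)

  label <- matrix(0L, rows, cols)
  for (i in seq_len(nrow(spec$objects))) {
    o <- spec$objects[i, ]
    inside <- ((rr - o$row) / o$a)^2 + ((cc - o$col) / o$b)^2 <= 1
    if (any(label[inside] != 0L))
      stop("overlapping objects in scene (object ", i, ")")
    label[inside] <- i
  }

  # per-pixel reflectance matrix (pixels x bands), column-major pixel order
  refl <- matrix(0.02, rows * cols, nb)
  for (i in seq_len(nrow(spec$objects))) {
    idx <- which(label == i)
    refl[idx, ] <- matrix(library$endmembers[spec$objects$class[i], ] *
                            spec$objects$brightness[i],
                          length(idx), nb, byrow = TRUE)
  }

  illum_pix <- spec$illumination_profile[as.vector(cc) + 1]
  raw <- spec$background_level + illum_pix * refl * spec$white_span
  raw <- with_seed(spec$rng_seed, {
    if (spec$noise_sd > 0)
      raw <- raw + matrix(stats::rnorm(length(raw), 0, spec$noise_sd),
                          nrow(raw), ncol(raw))
    pmax(raw, 0)
  })

  dark <- array(spec$background_level, dim = c(rows, cols, nb))
  white <- array(spec$background_level +
                   rep(illum_pix * spec$white_span, nb),
                 dim = c(rows, cols, nb))

  list(
    raw = hypercube(array(raw, dim = c(rows, cols, nb)), wl, "raw"),
    refs = list(dark = hypercube(dark, wl, "raw"),
                white = hypercube(white, wl, "raw")),
    truth = list(label_image = label,
                 object_classes = stats::setNames(spec$objects$class,
                                                  seq_len(nrow(spec$objects))))
  )
}
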