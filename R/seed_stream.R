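# --- free-fall seed stream --------------------------------------------------

#' Generate a labelled stream of per-seed spectra
#'
#' Emulates the seed stream an industrial sorter sees: a legume lot polluted
#' with known doses of contaminant kernels, each seed contributing one mean
#' reflectance spectrum. Per-seed variation has three components, on top of
#' the class endmember: a multiplicative lognormal brightness scale (seed
#' size/orientation/intactness; common across bands), a smooth spectral
#' deviation (baseline chemistry/scattering differences; correlated along
#' wavelength), and a small independent per-band residual. With probability
#' `orientation_noise` a seed is imaged with degraded exposure (it presents
#' its profile to the optics) and its whole spectrum is attenuated by a
#' uniform exposure factor.
#'
#' @param n_legumes Number of legume seeds in the stream.
#' @param legume Legume class name (e.g. `"broad_bean"`).
#' @param dose Named numeric vector of per-contaminant-class doses as
#'   fractions of `n_legumes` (e.g. `c(wheat = 0.05, oat = 0.05)`); each
#'   contaminant count is drawn Binomial(n_legumes, dose). May be empty.
#' @param library A [make_spectral_library()] result.
#' @param orientation_noise Probability of a degraded-exposure seed;
#'   default 0.005.
#' @param rng_seed Integer seed.
#' @param brightness_sdlog Lognormal sd of the brightness scale; default
#'   0.06 (intact/broken units and free-fall presentation).
#' @param deviation_sd Per-band sd of the smooth spectral deviation
#'   (reflectance units); default 0.07. This is the dominant noise source:
#'   seed-coat scattering and composition differences shift the baseline
#'   smoothly over hundreds of nm.
#' @param deviation_length Correlation length of the smooth deviation in nm;
#'   default 450.
#' @param residual_sd Independent per-band residual sd; default 0.008.
#' @param exposure_range Range of the uniform exposure factor for degraded
#'   seeds; default c(0.2, 0.6).
#' @return A [spectrum_table()] with class labels, rows in randomized stream
#'   order.
#' @export
make_seed_stream <- function(n_legumes, legume, dose = numeric(0), library,
                             orientation_noise = 0.005, rng_seed = 1L,
                             brightness_sdlog = 0.06, deviation_sd = 0.07,
                             deviation_length = 450, residual_sd = 0.008,
                             exposure_range = c(0.2, 0.6)) {
  stopifnot(inherits(library, "spectral_library"), n_legumes >= 1)
  if (length(dose)) {
    if (any(dose < 0) || sum(dose) >= 1)
      stop("dose fractions must be >= 0 and sum to < 1")
    if (!all(names(dose) %in% library$class_names))
      stop("dose classes absent from library")
  }
  if (!legume %in% library$class_names) stop("unknown legume class: ", legume)
  if (orientation_noise < 0 || orientation_noise > 1)
    stop("orientation_noise must be a probability")

  wl <- library$wavelengths
  nb <- length(wl)

  with_seed(rng_seed, {
    counts <- c(stats::setNames(n_legumes, legume),
                vapply(dose, function(p) stats::rbinom(1, n_legumes, p),
                       numeric(1)))
    labels <- rep(names(counts), counts)
    n <- length(labels)

    em <- library$endmembers[labels, , drop = FALSE]
    bright <- exp(stats::rnorm(n, 0, brightness_sdlog))

    # smooth deviation: kernel-smoothed white noise, rescaled so every band's
    # marginal sd equals deviation_sd while keeping the correlation structure
    d <- outer(wl, wl, "-")
    k <- exp(-d^2 / (2 * deviation_length^2))
    k <- k / rowSums(k)
    sm <- matrix(stats::rnorm(n * nb), n, nb) %*% t(k)
    sm <- sweep(sm, 2, deviation_sd / sqrt(rowSums(k^2)), "*")

    sp <- em * bright + sm +
      matrix(stats::rnorm(n * nb, 0, residual_sd), n, nb)

    degraded <- stats::runif(n) < orientation_noise
    if (any(degraded)) {
      expo <- stats::runif(sum(degraded), exposure_range[1], exposure_range[2])
      sp[degraded, ] <- sp[degraded, , drop = FALSE] * expo
    }
    sp <- pmax(sp, 0)

    ord <- sample.int(n)
    st <- spectrum_table(sp[ord, , drop = FALSE], wl, labels = labels[ord])
    st$degraded <- degraded[ord]
    st
  })
}

#' Collapse class labels to the legume/contaminant dichotomy
#'
#' @param labels Character vector of class names.
#' @param legume_classes Class names counted as legumes (the positive,
#'   "accept" class); everything else is a contaminant. The literal label
#'   `"legume"` always counts as legume, so already-binary label vectors
#'   pass through unchanged.
#' @return Factor with levels `c("legume", "contaminant")`.
#' @export
binary_labels <- function(labels,
                          legume_classes = c("broad_bean", "chickpea",
                                             "lentil", "legume")) {
  factor(ifelse(labels %in% legume_classes, "legume", "contaminant"),
         levels = c("legume", "contaminant"))
}
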