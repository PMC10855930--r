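# Shared fixtures, all generated in code at test time.

# one planted pair, moderate contrast; cheap enough to rebuild per test
fixture_library <- function(bands = c(810, 1455), contrast = 0.3,
                            pair = c("broad_bean", "wheat"), rng_seed = 7) {
  make_spectral_library(list(list(pair = pair, bands = bands,
                                  contrast = contrast)),
                        rng_seed = rng_seed)
}

# the band sets of the published per-pair selections, used as planting
# positions for the paper-configuration experiments
table2_pairs <- function(contrast = 0.3) {
  list(
    broad_bean = list(
      list(pair = c("broad_bean", "wheat"), bands = c(810, 1455),
           contrast = contrast),
      list(pair = c("broad_bean", "oat"), bands = c(530, 655, 810, 1190),
           contrast = contrast)),
    lentil = list(
      list(pair = c("lentil", "wheat"), bands = c(615, 1015),
           contrast = contrast),
      list(pair = c("lentil", "oat"), bands = c(575, 1265),
           contrast = contrast)),
    chickpea = list(
      list(pair = c("chickpea", "wheat"), bands = c(670, 1100, 1595),
           contrast = contrast),
      list(pair = c("chickpea", "oat"),
           bands = c(845, 1075, 1310, 1510, 1660), contrast = contrast)))
}

# small labelled stream split for classifier tests
fixture_split <- function(n = 400, dose = 0.5, rng_seed = 11,
                          lib = fixture_library(), legume = "broad_bean",
                          contaminant = "wheat", ...) {
  stream <- make_seed_stream(round(n / (1 + dose)), legume,
                             stats::setNames(dose, contaminant), lib,
                             rng_seed = rng_seed, ...)
  split_data(stream, rng_seed = rng_seed + 1)
}

# random small code table for MI/selection oracle checks
random_code_table <- function(n_rows, n_bands, n_levels, rng_seed) {
  set.seed(rng_seed)
  codes <- matrix(sample.int(n_levels, n_rows * n_bands, replace = TRUE) - 1L,
                  n_rows, n_bands)
  y <- sample(c("a", "b"), n_rows, replace = TRUE)
  list(codes = codes, y = y)
}
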