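test_that("mutual information matches analytic and oracle values", {
  a <- rep(0:1, each = 5)
  expect_equal(mutual_information(a, a), 1.0)        # perfect dependence
  expect_equal(mutual_information(a, rep(2L, 10)), 0)  # constant partner
  # joint counts {(0,0):4, (0,1):1, (1,0):1, (1,1):4}
  b <- c(rep(0, 4), 1, 0, rep(1, 4))
  expect_equal(mutual_information(a, b), mi_oracle(a, b))
  expect_equal(mutual_information(a, b), 0.2780719, tolerance = 1e-7)
  expect_error(mutual_information(a, 1:3), "length")
})

test_that("MI is non-negative, symmetric, self-maximal, relabel-invariant", {
  for (s in 1:30) {
    tb <- random_code_table(n_rows = 40, n_bands = 2, n_levels = 4,
                            rng_seed = s)
    a <- tb$codes[, 1]; b <- tb$codes[, 2]
    expect_gte(mutual_information(a, b), 0)
    expect_equal(mutual_information(a, b), mutual_information(b, a))
    expect_gte(mutual_information(a, a) + 1e-12, mutual_information(a, b))
    perm <- sample(0:3)
    expect_equal(mutual_information(perm[a + 1], b), mutual_information(a, b))
  }
})

test_that("relevance ranks signal above permutation noise", {
  set.seed(99)
  y <- rep(c("legume", "contaminant"), each = 100)
  band <- ifelse(y == "legume", 1L, 0L)
  band[sample(200, 20)] <- 1L - band[sample(200, 20)]  # 10% flips
  v_signal <- relevance(band, y)
  null <- vapply(1:200, function(i) relevance(sample(band), y), numeric(1))
  expect_gt(v_signal, quantile(null, 0.95))
  # a band identical to y is maximally relevant for its marginal
  expect_equal(relevance(as.integer(factor(y)), y),
               entropy_oracle(y))
  expect_equal(relevance(band, y), relevance(band, y))
})

test_that("redundancy is the mean pairwise MI against the selected set", {
  tb <- random_code_table(60, 3, 4, rng_seed = 5)
  S <- tb$codes[, 1:2]
  cand <- tb$codes[, 3]
  expect_equal(redundancy(cand, S),
               mean(c(mi_oracle(cand, S[, 1]), mi_oracle(cand, S[, 2]))))
  expect_error(redundancy(cand, S[, 0]), "empty")
  # duplicated member dominates when |S| = 1
  expect_equal(redundancy(cand, matrix(cand)), mi_oracle(cand, cand))
  # permutation-independent set gives near-zero redundancy
  set.seed(6)
  indep <- matrix(sample(tb$codes[, 1]), ncol = 1)
  expect_lt(redundancy(tb$codes[, 1], indep), 0.25)
})

test_that("the MIQ score and its division guard", {
  expect_equal(miq(0, 0.5), 0)
  expect_equal(miq(0.6, 0.3), 2.0)
  expect_equal(miq(0.4, 0), 0.4 / 1e-12)  # huge but finite
  expect_gt(miq(0.4, 0), miq(10, 0.5))    # guard case ranks first
})

test_that("discretization produces balanced in-range codes", {
  set.seed(3)
  x <- matrix(rnorm(500), 100, 5)
  cd <- discretize(x, n_bins = 8)
  expect_true(all(cd >= 0 & cd <= 7))
  tab <- table(cd[, 1])
  expect_true(all(tab >= 10 & tab <= 15))  # equal frequency, n = 100
  cw <- discretize(x[, 1], n_bins = 4, binning = "equal_width")
  expect_true(all(cw >= 0 & cw <= 3))
  expect_true(all(discretize(rep(1, 50)) == 0))  # constant band
})

test_that("every greedy step matches the brute-force oracle", {
  for (s in 1:6) {
    set.seed(s + 400)
    n <- sample(40:120, 1); nb <- sample(4:8, 1)
    y <- sample(c("legume", "contaminant"), n, replace = TRUE)
    x <- matrix(rnorm(n * nb), n, nb)
    x[, 1] <- x[, 1] + (y == "legume") * runif(1, 0.5, 2)
    wl <- seq(500, by = 100, length.out = nb)
    st <- spectrum_table(x, wl, labels = y)
    sel <- forward_select(st, wrapper = NULL, max_size = nb)
    codes <- discretize(x)
    oracle <- greedy_oracle(codes, y, wl, nb)
    expect_equal(sel$selected, wl[oracle], info = paste("seed", s))
  }
})

test_that("a perfectly separating band stops selection at one step", {
  set.seed(12)
  y <- rep(c("legume", "contaminant"), each = 40)
  x <- cbind(ifelse(y == "legume", 1, 0) + rnorm(80, 0, 0.01),
             matrix(rnorm(80 * 3), 80, 3))
  st <- spectrum_table(x, c(600, 700, 800, 900), labels = y)
  sp <- split_data(st, rng_seed = 1)
  sel <- forward_select(sp$train, make_svm_wrapper(sp$train, sp$validation),
                        target_ccr = 99)
  expect_equal(sel$selected, 600)
  expect_equal(sel$stop_reason, "target_reached")
  expect_gte(tail(sel$trace, 1), 99)
})

test_that("ties break toward the lower wavelength", {
  y <- rep(c("legume", "contaminant"), each = 30)
  v <- ifelse(y == "legume", 1, 0)
  x <- cbind(v, v, v)  # three identical bands: relevance ties exactly
  st <- spectrum_table(x + 0, c(500, 700, 900), labels = y)
  sel <- forward_select(st, wrapper = NULL, max_size = 1)
  expect_equal(sel$selected, 500)
  expect_error(spectrum_table(x, c(700, 500, 900), labels = y), "increasing")
})

test_that("selection results are deterministic and well-formed", {
  fx <- fixture_split(rng_seed = 19)
  w <- make_svm_wrapper(fx$train, fx$validation)
  a <- forward_select(fx$train, w, target_ccr = 99, max_size = 6)
  b <- forward_select(fx$train, w, target_ccr = 99, max_size = 6)
  expect_identical(a$selected, b$selected)
  expect_identical(a$trace, b$trace)
  expect_equal(nrow(a$scores), length(a$selected))
  expect_equal(length(a$trace), length(a$selected))
  expect_false(any(duplicated(a$selected)))
  expect_true(all(a$selected %in% fx$train$wavelengths))
  if (a$stop_reason == "target_reached")
    expect_gte(tail(a$trace, 1), a$target_ccr)
})

test_that("wrapper failures propagate with step context", {
  fx <- fixture_split(rng_seed = 23)
  boom <- function(wls) stop("wrapper exploded")
  expect_error(forward_select(fx$train, boom, target_ccr = 99),
               "wrapper exploded")
})

test_that("the stopping rule keeps selections small and on the planted pair", {
  ok <- 0
  for (rep in 1:50) {
    seed <- 5000 + rep
    lib <- make_spectral_library(list(list(pair = c("broad_bean", "wheat"),
                                           bands = c(810, 1050),
                                           contrast = 0.2)), rng_seed = seed)
    stream <- make_seed_stream(600, "broad_bean", c(wheat = 0.5), lib,
                               rng_seed = seed + 1)
    sp <- split_data(stream, rng_seed = seed + 2)
    sel <- forward_select(sp$train, make_svm_wrapper(sp$train, sp$validation),
                          target_ccr = 99)
    ok <- ok + (length(sel$selected) <= 4 &&
                  all(vapply(c(810, 1050), function(b)
                    any(abs(sel$selected - b) <= 5), logical(1))))
  }
  expect_gte(ok, 47)  # ~95% of seeded replicates
})
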