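sorter_fixture <- function(rng_seed = 51, contrast = 0.3) {
  lib <- make_spectral_library(list(
    list(pair = c("lentil", "wheat"), bands = c(615, 1015), contrast = contrast),
    list(pair = c("lentil", "oat"), bands = c(575, 1265), contrast = contrast)),
    rng_seed = 42)
  stream <- make_seed_stream(1500, "lentil", c(wheat = 0.05, oat = 0.05), lib,
                             rng_seed = rng_seed)
  model <- train_sorter_model(stream, c(615, 1015, 575, 1265),
                              bandwidth = 15, split_seed = 5)
  list(lib = lib, model = model)
}

test_that("broadband aggregation averages the 15 nm window", {
  wl <- standard_grid <- seq(400, 1700, 5)
  sp <- matrix(seq_along(wl), 1)  # spectrum = band index
  f <- broadband_aggregate(sp, c(810), bandwidth = 15, axis = wl)
  expect_equal(drop(f), mean(match(c(805, 810, 815), wl)), ignore_attr = TRUE)
  # constant spectrum stays constant at any center
  cst <- matrix(0.42, 1, length(wl))
  f2 <- broadband_aggregate(cst, c(500, 810, 1400), bandwidth = 15, axis = wl)
  expect_true(all(f2 == 0.42))
  # bandwidth 5 is the identity
  f3 <- broadband_aggregate(sp, c(810), bandwidth = 5, axis = wl)
  expect_equal(drop(f3), match(810, wl), ignore_attr = TRUE)
  # edge windows truncate with a warning
  expect_warning(f4 <- broadband_aggregate(sp, c(1700), bandwidth = 15,
                                           axis = wl), "truncated")
  expect_equal(drop(f4), mean(match(c(1695, 1700), wl)), ignore_attr = TRUE)
  expect_error(broadband_aggregate(sp, c(810), bandwidth = 10, axis = wl),
               "odd multiple")
})

test_that("sorter configuration is validated", {
  fx <- sorter_fixture()
  expect_error(sorter_config(fx$model, "lentil", c(wheat = 0.05),
                             bandwidth = 20), "odd multiple")
  expect_error(sorter_config(fx$model, "lentil", c(wheat = 0.05),
                             n_runs = 1), "n_runs")
})

test_that("a clean stream with a sound model is fully accepted", {
  fx <- sorter_fixture()
  cfg <- sorter_config(fx$model, "lentil", doses = numeric(0),
                       stream_size = 400, n_runs = 2,
                       orientation_noise = 0, rng_seed = 3)
  run <- simulate_run(cfg, fx$lib)
  expect_equal(run$report$fnr, 0)
  expect_equal(unname(run$accept_counts["lentil"]), run$n)
})

test_that("every seed lands in exactly one vessel", {
  fx <- sorter_fixture()
  cfg <- sorter_config(fx$model, "lentil", c(wheat = 0.05, oat = 0.05),
                       stream_size = 600, n_runs = 2, rng_seed = 7)
  run <- simulate_run(cfg, fx$lib)
  expect_equal(sum(run$accept_counts) + sum(run$reject_counts), run$n)
  expect_equal(names(run$accept_counts), names(run$reject_counts))
})

test_that("model wavelengths must exist on the library grid", {
  fx <- sorter_fixture()
  m <- fx$model
  m$selected_wavelengths <- c(615, 1013)
  cfg <- sorter_config(m, "lentil", c(wheat = 0.05), stream_size = 100,
                       n_runs = 2, rng_seed = 1)
  expect_error(simulate_run(cfg, fx$lib), "configuration error")
})

test_that("spectra constant within windows decide identically at 5 and 15 nm", {
  fx <- sorter_fixture()
  stream <- make_seed_stream(300, "lentil", c(wheat = 0.1), fx$lib,
                             rng_seed = 11)
  wl <- stream$wavelengths
  for (centre in fx$model$selected_wavelengths) {
    i <- match(centre, wl)
    stream$spectra[, i - 1] <- stream$spectra[, i]
    stream$spectra[, i + 1] <- stream$spectra[, i]
  }
  f5 <- broadband_aggregate(stream, fx$model$selected_wavelengths, 5)
  f15 <- broadband_aggregate(stream, fx$model$selected_wavelengths, 15)
  expect_equal(f5, f15)
  d5 <- decision_values(fx$model, f5) > fx$model$threshold
  d15 <- decision_values(fx$model, f15) > fx$model$threshold
  expect_identical(d5, d15)
})

test_that("zero-FPR policy keeps contaminants out while FNR stays positive", {
  fx <- sorter_fixture()
  cfg <- sorter_config(fx$model, "lentil", c(wheat = 0.05, oat = 0.05),
                       stream_size = 2000, n_runs = 3, rng_seed = 13)
  rep <- replicate_and_test(cfg, fx$lib)
  contam_in_accept <- vapply(rep$runs, function(r)
    sum(r$accept_counts[c("wheat", "oat")]), numeric(1))
  expect_true(all(contam_in_accept == 0))
  fnrs <- vapply(rep$runs, function(r) r$report$fnr, numeric(1))
  expect_gt(mean(fnrs), 0)   # orientation-degraded legumes go to waste
  expect_lt(mean(fnrs), 5)
})

test_that("the replicate table has run rows plus an average row", {
  fx <- sorter_fixture()
  cfg <- sorter_config(fx$model, "lentil", c(wheat = 0.05, oat = 0.05),
                       stream_size = 400, n_runs = 5, rng_seed = 17)
  rep <- replicate_and_test(cfg, fx$lib)
  expect_equal(nrow(rep$table), 6L)
  expect_match(rep$table$Dataset[6], "average")
  expect_equal(rep$table$CCR[6],
               round(mean(rep$table$CCR[1:5]), 2), tolerance = 0.01)
  expect_false(rep$anova$degenerate)
  expect_true(is.matrix(rep$tukey) && nrow(rep$tukey) == choose(5, 2))
})

test_that("zero between-run variance is flagged, not fatal", {
  fx <- sorter_fixture()
  cfg <- sorter_config(fx$model, "lentil", doses = numeric(0),
                       stream_size = 150, n_runs = 3,
                       orientation_noise = 0, rng_seed = 19)
  rep <- replicate_and_test(cfg, fx$lib)  # every seed accepted in every run
  expect_true(rep$anova$degenerate)
  expect_null(rep$tukey)
})

test_that("sorter reports are reproducible under a fixed seed", {
  fx <- sorter_fixture()
  cfg <- sorter_config(fx$model, "lentil", c(wheat = 0.05), stream_size = 300,
                       n_runs = 2, rng_seed = 23)
  a <- replicate_and_test(cfg, fx$lib)
  b <- replicate_and_test(cfg, fx$lib)
  expect_identical(a$table, b$table)
  expect_identical(a$anova, b$anova)
})
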