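test_that("the 50/25/25 split is stratified, disjoint and exhaustive", {
  lib <- fixture_library(rng_seed = 4)
  stream <- make_seed_stream(200, "broad_bean", c(wheat = 1e-9), lib,
                             rng_seed = 2)
  # force exactly 200/200 by building the table directly
  st <- spectrum_table(rbind(stream$spectra, stream$spectra),
                       stream$wavelengths,
                       labels = rep(c("broad_bean", "wheat"), each = 200))
  sp <- split_data(st, rng_seed = 5)
  counts <- function(part) as.vector(table(part$labels))
  expect_equal(counts(sp$train), c(100, 100))
  expect_equal(counts(sp$validation), c(50, 50))
  expect_equal(counts(sp$test), c(50, 50))
  expect_equal(sort(unlist(sp$indices)), 1:400)
  sp2 <- split_data(st, rng_seed = 5)
  expect_identical(sp$indices, sp2$indices)
  expect_false(identical(sp$indices, split_data(st, rng_seed = 6)$indices))
  tiny <- spectrum_table(matrix(rnorm(12 * 261), 12), stream$wavelengths,
                         labels = c(rep("broad_bean", 9), rep("wheat", 3)))
  expect_error(split_data(tiny), "stratification")
})

test_that("separable clouds train to zero error; labels permuted to chance", {
  set.seed(8)
  y <- rep(c("broad_bean", "wheat"), each = 50)
  x <- matrix(rnorm(100), 100, 1) + ifelse(y == "broad_bean", 8, 0)
  st <- spectrum_table(x, 800, labels = y)
  m <- train_linear(st, 800)
  expect_equal(unname(mean(predict(m, st) == binary_labels(y))), 1)

  accs <- vapply(1:20, function(s) {
    set.seed(300 + s)
    yp <- sample(y)
    stp <- spectrum_table(x, 800, labels = yp)
    sp <- split_data(stp, rng_seed = s)
    mp <- train_linear(sp$train, 800)
    confusion_metrics(predict(mp, sp$validation),
                      binary_labels(sp$validation$labels))$accuracy
  }, numeric(1))
  expect_lt(abs(mean(accs) - 50), 10)  # indistinguishable from coin flips
})

test_that("a duplicated feature column does not change predictions", {
  fx <- fixture_split(rng_seed = 29)
  dup <- fx$train
  dup$spectra <- cbind(dup$spectra, dup$spectra[, dup$wavelengths == 810])
  dup$wavelengths <- c(fx$train$wavelengths, 1705)
  m1 <- train_linear(fx$train, c(810, 1455))
  m2 <- train_linear(dup, c(810, 1455, 1705))
  va <- fx$validation
  va2 <- va
  va2$spectra <- cbind(va$spectra, va$spectra[, va$wavelengths == 810])
  va2$wavelengths <- dup$wavelengths
  expect_identical(as.character(predict(m1, va)),
                   as.character(predict(m2, va2)))
})

test_that("cross-validation is stratified, seeded and exact on separable data", {
  set.seed(10)
  y <- rep(c("broad_bean", "wheat"), each = 25)
  x <- matrix(rnorm(50), 50, 1) + ifelse(y == "broad_bean", 4, 0)
  st <- spectrum_table(x, 800, labels = y)
  cv <- cross_validate(st, 800, k = 5, rng_seed = 3)
  expect_equal(cv$fold_ccr, rep(100, 5))
  expect_equal(cv$mean_ccr, 100)
  cv2 <- cross_validate(st, 800, k = 5, rng_seed = 3)
  expect_identical(cv$fold_ccr, cv2$fold_ccr)
  # leave-one-out at the class boundary runs and aggregates
  tiny <- spectrum_table(x[c(1:10, 26:35), , drop = FALSE], 800,
                         labels = y[c(1:10, 26:35)])
  loo <- cross_validate(tiny, 800, k = 10, rng_seed = 1)
  expect_length(loo$fold_ccr, 10)
  expect_error(cross_validate(tiny, 800, k = 11), "fold error")
})

test_that("confusion metrics follow the result-table conventions", {
  # 124/125 legumes correct, 50/50 contaminants correct
  truth <- c(rep("legume", 125), rep("contaminant", 50))
  pred <- truth
  pred[1] <- "contaminant"
  r <- confusion_metrics(pred, truth)
  expect_equal(r$tpr, 99.2)
  expect_equal(r$fnr, 0.8)
  expect_equal(r$fpr, 0)
  expect_equal(r$ccr, r$tpr)           # headline CCR is the legume rate
  expect_equal(r$tpr + r$fnr, 100)     # exact closure
  expect_equal(sum(r$confusion), 175)

  all_ok <- confusion_metrics(truth, truth)
  expect_equal(c(all_ok$ccr, all_ok$fpr, all_ok$fnr), c(100, 0, 0))

  flipped <- ifelse(truth == "legume", "contaminant", "legume")
  r2 <- confusion_metrics(flipped, truth)
  expect_equal(c(r2$tpr, r2$fnr, r2$fpr), c(0, 100, 100))
  expect_error(confusion_metrics(c("legume", "weed"), c("legume", "legume")),
               "unknown")
})

test_that("zero FPR means literally no contaminant in the accept class", {
  fx <- fixture_split(rng_seed = 37)
  m <- train_linear(fx$train, c(810, 1455))
  m <- set_zero_fpr_threshold(m, fx$validation)
  pred <- predict(m, fx$validation)
  truth <- binary_labels(fx$validation$labels)
  r <- confusion_metrics(pred, truth)
  expect_equal(r$fpr, 0)
  expect_equal(sum(pred == "legume" & truth == "contaminant"), 0L)
  # deployment variant: the threshold dominates the zero-spectrum value
  mg <- set_zero_fpr_threshold(m, fx$validation, guard_zero = TRUE)
  zeta <- decision_values(m, matrix(0, 1, 2))
  expect_gte(mg$threshold, zeta)
})

test_that("raising the threshold trades FPR for FNR monotonically", {
  fx <- fixture_split(rng_seed = 41)
  m <- train_linear(fx$train, c(810, 1455))
  truth <- binary_labels(fx$validation$labels)
  grid <- quantile(decision_values(m, fx$validation), seq(0.05, 0.95, 0.1))
  prev_fpr <- Inf; prev_fnr <- -Inf
  for (t in grid) {
    m$threshold <- t
    r <- confusion_metrics(predict(m, fx$validation), truth)
    expect_lte(r$fpr, prev_fpr + 1e-9)
    expect_gte(r$fnr, prev_fnr - 1e-9)
    prev_fpr <- r$fpr; prev_fnr <- r$fnr
  }
})

test_that("the family comparison harness ranks and tolerates failures", {
  fx <- fixture_split(rng_seed = 43)
  st <- fx$train
  whole <- spectrum_table(rbind(fx$train$spectra, fx$validation$spectra,
                                fx$test$spectra), st$wavelengths,
                          labels = c(fx$train$labels, fx$validation$labels,
                                     fx$test$labels))
  fam <- list(
    linear_margin = svm_linear_family(),
    always_legume = function(x, y) function(nx)
      factor(rep("legume", nrow(nx)), levels = c("legume", "contaminant")),
    broken = function(x, y) stop("no fit"))
  out <- compare_classifiers(whole, fam, c(810, 1455), rng_seed = 3)
  expect_equal(nrow(out), 3L)
  expect_equal(out$family[1], "linear_margin")
  expect_equal(out$ccr[1], 100)
  expect_true(out$failed[out$family == "broken"])
  one <- compare_classifiers(whole, fam["linear_margin"], c(810, 1455))
  expect_equal(nrow(one), 1L)
})

test_that("select + train on a planted pair reaches the accuracy criterion", {
  fx <- fixture_split(n = 400, rng_seed = 47)
  sel <- forward_select(fx$train, make_svm_wrapper(fx$train, fx$validation),
                        target_ccr = 99)
  m <- train_linear(fx$train, sel$selected)
  r <- confusion_metrics(predict(m, fx$validation),
                         binary_labels(fx$validation$labels))
  expect_gte(r$accuracy, 99)
})
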