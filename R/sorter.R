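# --- industrial sorter simulation -------------------------------------------

#' Broadband aggregation of selected wavelengths
#'
#' Deployment optics integrate a 15 nm window instead of a single 5 nm
#' band: the feature for a selected wavelength is the mean reflectance of
#' the grid bands within `[lambda - (bw-5)/2, lambda + (bw-5)/2]`
#' (bw = 15 gives `{lambda-5, lambda, lambda+5}`). Windows reaching past
#' the grid ends are truncated with a warning. `bandwidth = 5` reduces to
#' the narrowband feature.
#'
#' @param spectra Matrix (n x bands) or [spectrum_table()] on the full axis.
#' @param axis Wavelength axis of `spectra` columns (taken from the table
#'   when one is given).
#' @param selected Selected wavelengths (nm).
#' @param bandwidth Window width in nm; odd multiple of the 5 nm step
#'   (default 15).
#' @return Matrix n x length(selected) of window means, columns named by
#'   the selected wavelengths.
#' @export
broadband_aggregate <- function(spectra, selected, bandwidth = 15,
                                axis = NULL) {
  if (inherits(spectra, "spectrum_table")) {
    axis <- spectra$wavelengths
    spectra <- spectra$spectra
  }
  if (is.null(axis)) stop("need the wavelength axis of the spectra columns")
  step <- 5
  if (bandwidth < step || (bandwidth / step) %% 2 != 1)
    stop("bandwidth must be an odd multiple of the 5 nm grid step")
  half <- (bandwidth - step) / 2
  out <- vapply(selected, function(l) {
    want <- seq(l - half, l + half, by = step)
    ix <- match(want, axis)
    if (anyNA(ix)) {
      warning("broadband window around ", l,
              " nm truncated at the grid edge")
      ix <- ix[!is.na(ix)]
      if (length(ix) == 0L) stop("selected wavelength ", l,
                                 " entirely off the grid")
    }
    rowMeans(spectra[, ix, drop = FALSE])
  }, numeric(nrow(spectra)))
  out <- matrix(out, nrow = nrow(spectra),
                dimnames = list(NULL, as.character(selected)))
  out
}

#' Configuration of a sorter simulation
#'
#' @param model Trained `classifier_model` (one legume against the pooled
#'   contaminants, threshold typically at the zero-FPR operating point).
#' @param legume Legume class of the stream.
#' @param doses Named contaminant dose fractions
#'   (e.g. `c(wheat = 0.05, oat = 0.05)`).
#' @param stream_size Legume seeds per run.
#' @param n_runs Replicate runs; >= 2 for the across-run ANOVA.
#' @param bandwidth Broadband window (nm, odd multiple of 5); default 15.
#' @param orientation_noise Degraded-exposure probability in the stream;
#'   default 0.005.
#' @param rng_seed Integer seed; per-run seeds derive from it.
#' @return An object of class `sorter_config`.
#' @export
sorter_config <- function(model, legume, doses, stream_size = 5000,
                          n_runs = 5, bandwidth = 15,
                          orientation_noise = 0.005, rng_seed = 1L) {
  stopifnot(inherits(model, "classifier_model"))
  if (bandwidth < 5 || (bandwidth / 5) %% 2 != 1)
    stop("bandwidth must be an odd multiple of the 5 nm grid step")
  if (n_runs < 2) stop("n_runs must be >= 2 for the across-run ANOVA")
  structure(list(model = model, legume = legume, doses = doses,
                 stream_size = stream_size, n_runs = n_runs,
                 bandwidth = bandwidth, orientation_noise = orientation_noise,
                 rng_seed = as.integer(rng_seed)),
            class = "sorter_config")
}

#' Simulate one pass of a contaminated stream through the sorter
#'
#' Generates a seed stream, computes each seed's broadband features at the
#' model's wavelengths, and routes every seed to the accept (legume) or
#' reject (contaminant) vessel: a seed is accepted when its decision value
#' exceeds the model threshold AND its mean reflectance clears the model's
#' low-signal guard (seeds too dark to identify are rejected, as a real
#' sorter ejects anything it cannot recognize).
#'
#' @param config A [sorter_config()].
#' @param library A [make_spectral_library()] result.
#' @param rng_seed Seed for this run (defaults to the config seed).
#' @return List: `report` (an `eval_report` against true classes),
#'   `accept_counts` / `reject_counts` (by true class), `n` stream size.
#' @export
simulate_run <- function(config, library, rng_seed = config$rng_seed) {
  model <- config$model
  off_grid <- setdiff(model$selected_wavelengths, library$wavelengths)
  if (length(off_grid))
    stop("configuration error: model wavelengths absent from library grid: ",
         paste(off_grid, collapse = ", "))
  stream <- make_seed_stream(config$stream_size, config$legume, config$doses,
                             library,
                             orientation_noise = config$orientation_noise,
                             rng_seed = rng_seed)
  feats <- broadband_aggregate(stream, model$selected_wavelengths,
                               bandwidth = config$bandwidth)
  dv <- decision_values(model, feats)
  # low-signal guard on the bands the sorter actually measures
  accept <- dv > model$threshold & rowMeans(feats) > model$signal_floor
  pred <- factor(ifelse(accept, "legume", "contaminant"),
                 levels = c("legume", "contaminant"))
  truth <- binary_labels(stream$labels, model$legume_classes)
  rep <- confusion_metrics(pred, truth,
                           dataset_name = paste0(config$legume, "-contaminant"),
                           wavelengths = model$selected_wavelengths)
  all_cls <- sort(unique(stream$labels))
  acc_tab <- table(factor(stream$labels, all_cls), accept)
  accept_counts <- stats::setNames(rep(0L, length(all_cls)), all_cls)
  reject_counts <- accept_counts
  if ("TRUE" %in% colnames(acc_tab)) accept_counts[] <- acc_tab[, "TRUE"]
  if ("FALSE" %in% colnames(acc_tab)) reject_counts[] <- acc_tab[, "FALSE"]
  list(report = rep, accept_counts = accept_counts,
       reject_counts = reject_counts, n = nrow(stream$spectra),
       correct = as.integer(pred == truth))
}

#' Replicated sorter runs with across-run ANOVA and Tukey HSD
#'
#' Runs the stream simulation `n_runs` times on independent streams (run
#' seeds derived from the config seed), builds the replicate table (one row
#' per run plus an average row), and tests for between-run differences with
#' a one-way ANOVA of the per-seed correct/incorrect indicator on the run
#' factor, followed by Tukey's HSD at alpha = 0.05. When every seed in
#' every run is classified identically (zero variance) the ANOVA is
#' degenerate and flagged rather than computed.
#'
#' @param config A [sorter_config()].
#' @param library A [make_spectral_library()] result.
#' @return An object of class `sorter_run_report`: `runs` (list of
#'   [simulate_run()] results), `table` (replicate rows + average),
#'   `anova` (F, p, degenerate flag), `tukey` (pairwise run comparisons or
#'   NULL when degenerate).
#' @export
replicate_and_test <- function(config, library) {
  run_seeds <- config$rng_seed + seq_len(config$n_runs) * 1000L
  runs <- lapply(run_seeds, function(s) simulate_run(config, library, s))

  rows <- do.call(rbind, lapply(seq_along(runs), function(i) {
    r <- runs[[i]]$report
    data.frame(Dataset = sprintf("%s-contaminant-run %d", config$legume, i),
               CCR = round(r$ccr, 2), TPR = round(r$tpr, 2),
               FPR = round(r$fpr, 2), FNR = round(r$fnr, 2))
  }))
  avg <- data.frame(Dataset = sprintf("%s-contaminant-average", config$legume),
                    CCR = round(mean(vapply(runs, function(r) r$report$ccr,
                                            numeric(1))), 2),
                    TPR = round(mean(vapply(runs, function(r) r$report$tpr,
                                            numeric(1))), 2),
                    FPR = round(mean(vapply(runs, function(r) r$report$fpr,
                                            numeric(1))), 2),
                    FNR = round(mean(vapply(runs, function(r) r$report$fnr,
                                            numeric(1))), 2))
  tab <- rbind(rows, avg)

  correct <- unlist(lapply(runs, `[[`, "correct"))
  run_f <- factor(rep(seq_along(runs), vapply(runs, `[[`, integer(1), "n")))
  if (stats::var(correct) < .Machine$double.eps) {
    anova_res <- list(F = NA_real_, p = NA_real_, degenerate = TRUE)
    tukey <- NULL
  } else {
    fit <- stats::aov(correct ~ run_f)
    s <- summary(fit)[[1]]
    anova_res <- list(F = s[["F value"]][1], p = s[["Pr(>F)"]][1],
                      degenerate = FALSE)
    tukey <- stats::TukeyHSD(fit, conf.level = 0.95)$run_f
  }

  structure(list(runs = runs, table = tab, anova = anova_res, tukey = tukey,
                 config = config),
            class = "sorter_run_report")
}

#' @export
print.sorter_run_report <- function(x, ...) {
  print(x$table, row.names = FALSE)
  if (x$anova$degenerate) {
    cat("ANOVA: degenerate (zero variance across all runs)\n")
  } else {
    cat(sprintf("ANOVA across runs: F = %.3f, p = %.4f\n",
                x$anova$F, x$anova$p))
  }
  invisible(x)
}
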