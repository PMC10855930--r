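# --- mutual information and FS-MRMR wavelength selection --------------------
#
# The selection criterion is the mutual information quotient
# MIQ = V / W, with relevance V = I(band, class) and redundancy
# W = mean over the selected set S of I(band, z). Selection is forward
# addition: the first band maximizes V alone, each later band maximizes MIQ
# over the complement of S, and after every addition a wrapper classifier is
# trained and scored on held-out data; selection stops when that score
# reaches the target, the set reaches max_size, or candidates run out.

#' Discretize reflectances for mutual-information estimation
#'
#' Per-band integer codes in `0 .. n_bins-1` via equal-frequency (quantile)
#' or equal-width binning. Equal frequency is the robust default: it is
#' invariant to monotone rescaling of the reflectance axis.
#'
#' @param x Numeric matrix (rows = objects) or vector.
#' @param n_bins Number of bins; default 8.
#' @param binning `"equal_frequency"` (default) or `"equal_width"`.
#' @return Integer matrix/vector of codes.
#' @export
discretize <- function(x, n_bins = 8, binning = c("equal_frequency",
                                                  "equal_width")) {
  binning <- match.arg(binning)
  code1 <- function(v) {
    br <- if (binning == "equal_width") {
      seq(min(v), max(v), length.out = n_bins + 1L)
    } else {
      unique(stats::quantile(v, probs = seq(0, 1, length.out = n_bins + 1L),
                             type = 1))
    }
    if (length(br) < 2L) return(rep(0L, length(v)))  # constant band
    as.integer(cut(v, br, include.lowest = TRUE, labels = FALSE)) - 1L
  }
  if (is.matrix(x)) apply(x, 2, code1) else code1(x)
}

#' Plug-in mutual information of two code vectors, in bits
#'
#' `I(a, b) = sum p(a,b) log2( p(a,b) / (p(a) p(b)) )` over the empirical
#' joint distribution. Non-negative and symmetric; 0 when either argument is
#' constant.
#'
#' @param a,b Equal-length vectors of discrete codes (any atomic type).
#' @return Mutual information in bits.
#' @export
mutual_information <- function(a, b) {
  if (length(a) != length(b))
    stop("mutual_information: length mismatch (", length(a), " vs ",
         length(b), ")")
  if (length(a) < 2L) stop("mutual_information needs n >= 2")
  j <- table(a, b)
  n <- sum(j)
  pj <- j / n
  pa <- rowSums(pj)
  pb <- colSums(pj)
  nz <- pj > 0
  sum(pj[nz] * log2(pj[nz] / outer(pa, pb)[nz]))
}

#' Relevance of a band: mutual information with the class label
#'
#' @param band Integer codes of one band.
#' @param y Class labels.
#' @return Relevance in bits.
#' @export
relevance <- function(band, y) mutual_information(band, y)

#' Redundancy of a band against the selected set
#'
#' Mean mutual information between the candidate band and each already
#' selected band: `W = (1/|S|) sum_{z in S} I(band, z)`.
#'
#' @param band Integer codes of the candidate band.
#' @param S_codes Integer matrix of codes of the selected bands (columns).
#' @return Redundancy in bits.
#' @export
redundancy <- function(band, S_codes) {
  S_codes <- as.matrix(S_codes)
  if (ncol(S_codes) == 0L)
    stop("redundancy is undefined for an empty selected set")
  mean(apply(S_codes, 2, function(z) mutual_information(band, z)))
}

#' Mutual information quotient
#'
#' `MIQ = V / max(W, eps)`; the guard keeps the score finite when a
#' candidate is unredundant with everything selected so far.
#'
#' @param V Relevance (bits), >= 0.
#' @param W Redundancy (bits), >= 0.
#' @param eps Division guard; default 1e-12.
#' @return The score (dimensionless).
#' @export
miq <- function(V, W, eps = 1e-12) {
  stopifnot(all(V >= -1e-12), all(W >= -1e-12))
  V / pmax(W, eps)
}

#' Forward mRMR wavelength selection with a wrapper stopping rule
#'
#' Greedy forward addition over the full wavelength set: step 1 picks the
#' band of maximal relevance (redundancy is undefined for an empty set);
#' every later step picks the band of maximal MIQ among the remaining
#' candidates. Ties break toward the lower wavelength. After each addition
#' the wrapper trains and scores a classifier on the current set; selection
#' stops once the score reaches `target_ccr`, the set reaches `max_size`,
#' or no candidates remain.
#'
#' @param table A labelled [spectrum_table()].
#' @param wrapper Function `(selected_wavelengths) -> CCR%` scoring a
#'   classifier trained on those bands; see [make_svm_wrapper()]. NULL
#'   disables the stopping rule (pure ranking up to `max_size`).
#' @param target_ccr Stop once wrapper CCR reaches this percentage;
#'   default 99 (the design criterion of a classification rate above 99%).
#' @param max_size Selection cap; default the smaller of 10 and the number
#'   of candidate bands.
#' @param n_bins,binning Discretization for the MI estimates; defaults 8,
#'   equal frequency.
#' @return An object of class `selection_result`: `selected` (ordered nm),
#'   `scores` (per step: wavelength, V, W, MIQ), `trace` (wrapper CCR after
#'   each addition; NA when no wrapper), `stop_reason` one of
#'   `"target_reached"`, `"max_size"`, `"exhausted"`, and `target_ccr`.
#' @export
forward_select <- function(table, wrapper = NULL, target_ccr = 99,
                           max_size = NULL, n_bins = 8,
                           binning = "equal_frequency") {
  stopifnot(inherits(table, "spectrum_table"))
  if (is.null(table$labels)) stop("forward_select needs a labelled table")
  if (!is.null(wrapper) && (target_ccr <= 50 || target_ccr > 100))
    stop("target_ccr must lie in (50, 100]")
  wl <- table$wavelengths
  if (is.null(max_size)) max_size <- min(10L, length(wl))
  if (max_size > length(wl)) stop("max_size exceeds the candidate set")
  codes <- discretize(table$spectra, n_bins = n_bins, binning = binning)
  y <- table$labels

  V <- apply(codes, 2, relevance, y = y)
  selected <- integer(0)        # column indices into wl
  Wsum <- numeric(length(wl))   # running sum of I(band, z) over z in S
  scores <- data.frame(wavelength = numeric(0), V = numeric(0),
                       W = numeric(0), MIQ = numeric(0))
  trace <- numeric(0)
  stop_reason <- "exhausted"

  repeat {
    cand <- setdiff(seq_along(wl), selected)
    if (length(cand) == 0L) { stop_reason <- "exhausted"; break }
    if (length(selected) == 0L) {
      Wc <- rep(NA_real_, length(cand))
      crit <- V[cand]
    } else {
      Wc <- Wsum[cand] / length(selected)
      crit <- miq(V[cand], Wc)
    }
    # argmax with ties toward the lower wavelength (cand is in wl order)
    pick <- cand[which.max(crit)]
    kp <- match(pick, cand)
    selected <- c(selected, pick)
    scores <- rbind(scores, data.frame(
      wavelength = wl[pick], V = V[pick], W = Wc[kp],
      MIQ = if (length(selected) == 1L) NA_real_ else crit[kp]))
    # update running redundancy sums with the new member
    newI <- apply(codes, 2, mutual_information, b = codes[, pick])
    Wsum <- Wsum + newI

    ccr <- if (is.null(wrapper)) NA_real_ else wrapper(wl[selected])
    trace <- c(trace, ccr)
    if (!is.null(wrapper) && is.finite(ccr) && ccr >= target_ccr) {
      stop_reason <- "target_reached"; break
    }
    if (length(selected) >= max_size) { stop_reason <- "max_size"; break }
  }

  structure(list(selected = wl[selected], scores = scores, trace = trace,
                 stop_reason = stop_reason, target_ccr = target_ccr),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat("selection_result:", length(x$selected), "wavelengths [",
      paste(x$selected, collapse = ", "), "] stop:", x$stop_reason, "\n")
  if (any(is.finite(x$trace)))
    cat("  wrapper CCR trace:", paste(sprintf("%.1f", x$trace), collapse = " "),
        "\n")
  invisible(x)
}
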