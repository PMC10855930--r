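# Independent oracles, deliberately written on different code paths than the
# package: entropy-based MI with explicit loops, and a step-by-step greedy
# re-evaluation of the selection criterion.

# H(x) in bits by explicit summation over observed levels
entropy_oracle <- function(x) {
  p <- as.vector(table(x)) / length(x)
  h <- 0
  for (pi in p) if (pi > 0) h <- h - pi * log2(pi)
  h
}

# I(a, b) = H(a) + H(b) - H(a, b); joint via pasted level pairs
mi_oracle <- function(a, b) {
  entropy_oracle(a) + entropy_oracle(b) -
    entropy_oracle(paste(a, b, sep = "\r"))
}

# Brute-force forward mRMR trace on a code matrix: at every step evaluate
# V, W, MIQ for every remaining candidate with mi_oracle and take the
# argmax (ties to the lower wavelength). Returns the selected column order.
greedy_oracle <- function(codes, y, wavelengths, n_steps) {
  remaining <- seq_len(ncol(codes))
  selected <- integer(0)
  for (step in seq_len(n_steps)) {
    best <- NA_integer_; best_crit <- -Inf
    for (j in remaining) {
      V <- mi_oracle(codes[, j], y)
      crit <- if (length(selected) == 0L) {
        V
      } else {
        W <- mean(vapply(selected, function(z) mi_oracle(codes[, j], codes[, z]),
                         numeric(1)))
        V / max(W, 1e-12)
      }
      if (crit > best_crit + 1e-12 ||
          (abs(crit - best_crit) <= 1e-12 && !is.na(best) &&
           wavelengths[j] < wavelengths[best])) {
        best <- j; best_crit <- crit
      }
    }
    selected <- c(selected, best)
    remaining <- setdiff(remaining, best)
  }
  selected
}
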