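# Independent brute-force oracles used to cross-check the implementation.
# These deliberately share no code with the package internals.

# Greedy maximin selection recomputed naively from scratch at every step
# (O(n^3)); ties toward the lowest index.
ks_oracle <- function(X, n_train) {
  D <- as.matrix(dist(as.matrix(X)))
  n <- nrow(D)
  pair <- which(D == max(D), arr.ind = TRUE)
  pair <- pair[pair[, 1] < pair[, 2], , drop = FALSE]
  pair <- pair[order(pair[, 1], pair[, 2]), , drop = FALSE][1, ]
  sel <- as.integer(pair)
  while (length(sel) < n_train) {
    cand <- setdiff(seq_len(n), sel)
    mind <- vapply(cand, function(i0) min(D[i0, sel]), numeric(1))
    sel <- c(sel, cand[which.max(mind)])
  }
  sel
}

# Upper convex hull by pairwise chords: the hull value at band k is the
# maximum over all chords (i, j) spanning k of the chord evaluated at k.
hull_chord_oracle <- function(w, r) {
  n <- length(w)
  vapply(seq_len(n), function(k) {
    best <- r[k]
    for (i in seq_len(k)) for (j in k:n) {
      if (i == j) next
      val <- r[i] + (r[j] - r[i]) * (w[k] - w[i]) / (w[j] - w[i])
      if (val > best) best <- val
    }
    best
  }, numeric(1))
}

# Savitzky-Golay by direct per-window least squares (interior bands only):
# fit a degree-`polyorder` polynomial in band-step units centred on band k
# and read off the value or first derivative at the centre.
sg_oracle <- function(x, window, polyorder, deriv) {
  n <- length(x)
  h <- (window - 1) / 2
  out <- rep(NA_real_, n)
  for (k in (h + 1):(n - h)) {
    z <- (-h):h
    fit <- lm(x[(k - h):(k + h)] ~ poly(z, polyorder, raw = TRUE))
    out[k] <- if (deriv == 0) coef(fit)[1] else coef(fit)[2]
  }
  out
}

# Small helpers for building fixtures
tiny_library <- function(n = 12, subset = "mineral", seed = 1, ...) {
  socspec::generate_library(n, subset, seed = seed, ...)
}

noiseless_catalog <- function(...) {
  socspec::band_catalog(noise = list(scan_sd = 0, scan_sd_sand = 0,
                                     lab_sd = 0), ...)
}

# Reference validation statistics published for continental-scale SOC
# models of the LUCAS library (used for internal-consistency arithmetic).
reference_performance <- function() {
  read.csv(system.file("extdata", "reference_performance.csv",
                       package = "socspec"), stringsAsFactors = FALSE)
}
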