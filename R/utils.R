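# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

.stop <- function(...) stop(..., call. = FALSE)

.assert <- function(cond, ...) if (!isTRUE(cond)) .stop(sprintf(...))

# run code with a locally seeded RNG, restoring the caller's stream
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
  force(code)
}

# per-row sample variances of a channels x samples matrix (denominator n-1)
.row_vars <- function(m) {
  n <- ncol(m)
  mu <- rowMeans(m)
  rowSums((m - mu)^2) / (n - 1)
}

# flip eigenvector signs so the largest-|.| entry of each column is positive;
# makes eigendecompositions deterministic across LAPACK builds
.fix_signs <- function(v) {
  for (j in seq_len(ncol(v))) {
    i <- which.max(abs(v[, j]))
    if (v[i, j] < 0) v[, j] <- -v[, j]
  }
  v
}

# round half away from zero (matches how the study tables are printed;
# base round() is half-to-even)
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Butterworth band-pass coefficients; `order` is the overall band-pass order
# (signal::butter doubles the prototype order for type = "pass")
.bp_design <- function(low_hz, high_hz, sampling_rate, order) {
  .assert(order >= 2 && order %% 2 == 0,
          "filter order must be a positive even number, got %s", order)
  nyq <- sampling_rate / 2
  .assert(low_hz > 0 && low_hz < high_hz && high_hz < nyq,
          "band [%g, %g] Hz must satisfy 0 < low < high < Nyquist (%g Hz)",
          low_hz, high_hz, nyq)
  signal::butter(order / 2, c(low_hz, high_hz) / nyq, type = "pass")
}

# zero-phase filtering with odd-reflection padding to tame edge transients
.filtfilt_padded <- function(filt, x, pad) {
  n <- length(x)
  if (pad > 0) {
    pad <- min(pad, n - 1)
    left  <- 2 * x[1] - x[(pad + 1):2]
    right <- 2 * x[n] - x[(n - 1):(n - pad)]
    y <- signal::filtfilt(filt, c(left, x, right))
    y[(pad + 1):(pad + n)]
  } else {
    signal::filtfilt(filt, x)
  }
}

# apply zero-phase band-pass to each row of a channels x samples matrix
.bp_matrix <- function(m, filt, pad) {
  t(apply(m, 1L, function(r) .filtfilt_padded(filt, r, pad)))
}
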