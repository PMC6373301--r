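# Shared fixtures, built in code at test time.

# A small epoch with known content: channels x samples at 125 Hz.
toy_epoch <- function(data = NULL, baseline = NULL, fs = 125,
                      task = "force", level = 2L, seed = 42) {
  if (is.null(data)) {
    data <- withr::with_seed(seed, matrix(rnorm(9 * 3 * fs), 9))
  }
  if (is.null(baseline)) {
    baseline <- withr::with_seed(seed + 1, matrix(rnorm(9 * fs), 9))
  }
  eeg_epoch(data, baseline, fs = fs, task = task, mode = "actual",
            level = level)
}

# Lightweight generator configs.
recovery_config <- function(seed = 1, snr = 5) {
  synth_config(seed = seed, snr = snr, mvar_scale = 0)
}

tiny_config <- function(seed = 1, ...) {
  synth_config(n_subjects = 2, n_sessions = 2, trials_per_class = 2,
               seed = seed, ...)
}

# Stable random MVAR model with given coupling, at the pipeline rate.
toy_mvar <- function(coeffs, noise_cov = NULL, fs = 125) {
  n <- nrow(coeffs[[1]])
  structure(
    list(order = length(coeffs), coeffs = coeffs,
         noise_cov = noise_cov %||% diag(n), fs = fs, aic = NA,
         stable = TRUE, spectral_radius = NA, n_channels = n),
    class = "mvar_model"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Simulate data from explicit MVAR coefficient matrices.
simulate_mvar_series <- function(coeffs, n, seed = 1, burn = 200) {
  N <- nrow(coeffs[[1]])
  p <- length(coeffs)
  withr::with_seed(seed, {
    x <- matrix(0, N, n + burn)
    e <- matrix(rnorm(N * (n + burn)), N)
    for (t in (p + 1):(n + burn)) {
      acc <- e[, t]
      for (l in seq_len(p)) acc <- acc + coeffs[[l]] %*% x[, t - l]
      x[, t] <- acc
    }
    x[, burn + seq_len(n), drop = FALSE]
  })
}

# Independent brute-force PDC evaluation (straight from the definition,
# scalar loops; deliberately unvectorized and separate from the package).
brute_pdc <- function(coeffs, fs, freqs) {
  N <- nrow(coeffs[[1]])
  out <- array(NA_real_, c(N, N, length(freqs)))
  for (fi in seq_along(freqs)) {
    f <- freqs[fi]
    abar <- matrix(0+0i, N, N)
    for (k in 1:N) for (j in 1:N) {
      a <- if (k == j) 1+0i else 0+0i
      for (l in seq_along(coeffs)) {
        a <- a - coeffs[[l]][k, j] * exp(-2i * pi * f * l / fs)
      }
      abar[k, j] <- a
    }
    for (j in 1:N) {
      den <- sqrt(sum(Mod(abar[, j])^2))
      for (k in 1:N) out[k, j, fi] <- Mod(abar[k, j]) / den
    }
  }
  out
}
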