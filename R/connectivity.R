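#' Fit a multivariate autoregressive (MVAR) model to one epoch
#'
#' Ordinary least squares on stacked lagged regressors: each channel at time
#' `t` is predicted from `p` lags of all channels,
#' `x(t) = sum_i C_i x(t - i) + e(t)`. With `p = "auto"` the order minimizing
#' AIC over `1..p_max` is used. Stability (companion-matrix spectral radius
#' < 1) is checked and a warning emitted otherwise.
#'
#' @param epoch_data matrix `[n_channels x n_samples]` or an [eeg_epoch()]
#'   (task window used).
#' @param p lag order (>= 1) or `"auto"`.
#' @param p_max search ceiling for `p = "auto"` (default 20).
#' @param fs sampling rate in Hz (taken from the epoch if given).
#' @return Object of class `mvar_model`: `order`, `coeffs` (list of
#'   `N x N` matrices), `noise_cov`, `fs`, `aic`, `stable`.
#' @export
fit_mvar <- function(epoch_data, p = "auto", p_max = 20, fs = NULL) {
  if (inherits(epoch_data, "eeg_epoch")) {
    fs <- epoch_data$fs
    epoch_data <- epoch_data$data
  }
  check_matrix(epoch_data)
  x <- t(epoch_data)                       # samples x channels
  n <- nrow(x); N <- ncol(x)
  sds <- apply(x, 2, stats::sd)
  if (any(sds < 1e-12)) {
    stop_invalid("channel %d is constant; MVAR regression is rank-deficient",
                 which(sds < 1e-12)[1])
  }
  fit_order <- function(p) {
    if (n <= N * p + 10) stop_invalid("too few samples for MVAR order %d", p)
    rows <- (p + 1):n
    X <- do.call(cbind, lapply(1:p, function(l) x[rows - l, , drop = FALSE]))
    Y <- x[rows, , drop = FALSE]
    # Average-referenced EEG is exactly rank-1 deficient (channels sum to
    # zero), so plain OLS is singular by construction; a minimum-norm ridge
    # (tiny, scale-relative) picks the canonical solution. A channel that is
    # an exact copy of another is still a user error worth naming.
    dup <- which(duplicated(round(t(x), 10)))
    if (length(dup)) {
      stop_invalid("rank-deficient MVAR regression: channel %d duplicates another",
                   dup[1])
    }
    xtx <- crossprod(X)
    lambda <- 1e-10 * mean(diag(xtx))
    B <- solve(xtx + diag(lambda, ncol(X)), crossprod(X, Y))
    resid <- Y - X %*% B
    sigma <- crossprod(resid) / (length(rows) - N * p)
    aic <- length(rows) * determinant(
      crossprod(resid) / length(rows), logarithm = TRUE)$modulus[1] +
      2 * p * N^2
    list(B = B, sigma = sigma, aic = aic, p = p)
  }
  fit <- if (identical(p, "auto")) {
    fits <- lapply(seq_len(p_max), function(pp) fit_order(pp))
    fits[[which.min(vapply(fits, `[[`, 0, "aic"))]]
  } else {
    if (!is.numeric(p) || p < 1) stop_invalid("`p` must be >= 1 or \"auto\"")
    fit_order(as.integer(p))
  }
  p <- fit$p
  # B rows are ordered lag-1 block, lag-2 block, ...; C_i[k, j] multiplies
  # x_j(t - i) in the equation for x_k(t), so C_i = t(B[lag-i block, ]).
  coeffs <- lapply(seq_len(p), function(i) {
    t(fit$B[((i - 1) * N + 1):(i * N), , drop = FALSE])
  })
  companion <- matrix(0, N * p, N * p)
  companion[seq_len(N), ] <- do.call(cbind, coeffs)
  if (p > 1) {
    companion[(N + 1):(N * p), seq_len(N * (p - 1))] <- diag(N * (p - 1))
  }
  radius <- max(Mod(eigen(companion, only.values = TRUE)$values))
  stable <- radius < 1
  if (!stable) {
    rlang::inform(sprintf("fitted MVAR is unstable (spectral radius %.3f)",
                          radius))
  }
  structure(
    list(order = p, coeffs = coeffs, noise_cov = fit$sigma,
         fs = fs %||% NA_real_, aic = fit$aic, stable = stable,
         spectral_radius = radius, n_channels = N),
    class = "mvar_model"
  )
}

#' @export
print.mvar_model <- function(x, ...) {
  cat(sprintf("<mvar_model> %d channels, order %d, radius %.3f%s\n",
              x$n_channels, x$order, x$spectral_radius,
              if (x$stable) "" else " (UNSTABLE)"))
  invisible(x)
}

#' Partial directed coherence of an MVAR model
#'
#' With `Abar(f) = I - sum_i C_i exp(-1i * 2 * pi * f * i / fs)`, the PDC
#' from source channel `j` to sink `k` at frequency `f` is
#' `|Abar[k, j](f)| / sqrt(sum_i |Abar[i, j](f)|^2)` — the proportion of the
#' outflow of `j` that reaches `k`. Values lie in `[0, 1]` and the squares
#' sum to 1 over sinks for every source and frequency.
#'
#' @param m an [fit_mvar()] model.
#' @param freqs frequencies (Hz) inside `(0, fs/2)`; default 1-45 Hz in 1 Hz
#'   steps (clipped below Nyquist).
#' @return Object of class `pdc_spectrum`: `values` array `[N x N x F]`
#'   (entry `(k, j, f)` = PDC from j to k), `freqs`, `fs`.
#' @export
compute_pdc <- function(m, freqs = NULL) {
  stopifnot(inherits(m, "mvar_model"))
  fs <- m$fs
  if (is.na(fs)) stop_invalid("model carries no sampling rate")
  if (is.null(freqs)) freqs <- seq(1, min(45, fs / 2 - 1), by = 1)
  if (any(freqs <= 0 | freqs >= fs / 2)) {
    stop_invalid("frequencies must lie inside (0, fs/2)")
  }
  N <- m$n_channels
  vals <- array(NA_real_, c(N, N, length(freqs)))
  for (fi in seq_along(freqs)) {
    f <- freqs[fi]
    Abar <- diag(N) + 0i
    for (i in seq_along(m$coeffs)) {
      Abar <- Abar - m$coeffs[[i]] * exp(-1i * 2 * pi * f * i / fs)
    }
    amag <- Mod(Abar)
    denom <- sqrt(colSums(amag^2))
    if (any(denom < 1e-300)) stop_invalid("zero PDC denominator column")
    vals[, , fi] <- sweep(amag, 2, denom, "/")
  }
  structure(list(values = vals, freqs = freqs, fs = fs),
            class = "pdc_spectrum")
}

#' @export
print.pdc_spectrum <- function(x, ...) {
  cat(sprintf("<pdc_spectrum> %d x %d channels, %d frequencies (%g-%g Hz)\n",
              dim(x$values)[1], dim(x$values)[2], length(x$freqs),
              min(x$freqs), max(x$freqs)))
  invisible(x)
}

#' Canonical EEG frequency bands
#'
#' Theta 4-8 Hz, alpha 8-13 Hz, beta 13-30 Hz; half-open `[lo, hi)`.
#'
#' @return Named list of `c(lo, hi)` pairs.
#' @export
eeg_bands <- function() {
  list(theta = c(4, 8), alpha = c(8, 13), beta = c(13, 30))
}

#' Band-averaged PDC connectivity matrices
#'
#' Entrywise mean of the PDC spectrum over the frequencies inside each band
#' (half-open `[lo, hi)`).
#'
#' @param p a [compute_pdc()] spectrum.
#' @param bands named list of `c(lo, hi)` band edges; default [eeg_bands()].
#' @return Object of class `band_connectivity`: named list `matrices` of
#'   `N x N` mean-PDC matrices plus the band definitions.
#' @export
band_average <- function(p, bands = eeg_bands()) {
  stopifnot(inherits(p, "pdc_spectrum"))
  mats <- lapply(bands, function(edges) {
    sel <- p$freqs >= edges[1] & p$freqs < edges[2]
    if (!any(sel)) {
      stop_invalid("band [%g, %g) contains no evaluated frequency",
                   edges[1], edges[2])
    }
    apply(p$values[, , sel, drop = FALSE], c(1, 2), mean)
  })
  structure(list(matrices = mats, bands = bands), class = "band_connectivity")
}

#' @export
print.band_connectivity <- function(x, ...) {
  cat(sprintf("<band_connectivity> bands: %s; %d x %d channels\n",
              paste(names(x$matrices), collapse = ", "),
              nrow(x$matrices[[1]]), ncol(x$matrices[[1]])))
  invisible(x)
}

#' Write band connectivity matrices as delimited files
#'
#' One `N x N` tab-separated matrix per band, channel labels as header.
#'
#' @param bc a [band_average()] result.
#' @param dir output directory.
#' @param channel_labels channel names for the header.
#' @return Paths written, invisibly.
#' @export
write_band_connectivity <- function(bc, dir, channel_labels = NULL) {
  stopifnot(inherits(bc, "band_connectivity"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  labels <- channel_labels %||% paste0("ch", seq_len(nrow(bc$matrices[[1]])))
  paths <- vapply(names(bc$matrices), function(b) {
    path <- file.path(dir, paste0("pdc_", b, ".tsv"))
    m <- bc$matrices[[b]]
    dimnames(m) <- list(labels, labels)
    write.table(m, path, sep = "\t", quote = FALSE, col.names = NA)
    path
  }, "")
  invisible(paths)
}
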