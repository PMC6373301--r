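#' ERD/ERS relative band energy features
#'
#' Event-related (de)synchronization quantified as the relative energy change
#' `E_n(%) = (e_n - e_c) / e_c * 100`, where `e_c` is the mean squared
#' amplitude of the 1 s pre-task baseline and `e_n` the mean squared
#' amplitude of each of the three 1 s task windows, per channel. Negative
#' values are desynchronization, positive synchronization.
#'
#' @param epoch an [eeg_epoch()] with a 3 s task window and 1 s baseline.
#' @return Numeric matrix `[3 windows x n_channels]` of percent changes
#'   (27 values on the nine-channel montage).
#' @export
erd_energy <- function(epoch) {
  stopifnot(inherits(epoch, "eeg_epoch"))
  fs <- epoch$fs
  n_win <- ncol(epoch$data) %/% fs
  if (n_win < 1) stop_invalid("task window shorter than one second")
  e_c <- rowMeans(epoch$baseline^2)
  if (any(e_c <= 0)) stop_invalid("zero baseline energy on channel %d",
                                  which(e_c <= 0)[1])
  out <- matrix(NA_real_, n_win, nrow(epoch$data),
                dimnames = list(paste0("w", seq_len(n_win)),
                                paste0("ch", seq_len(nrow(epoch$data)))))
  for (w in seq_len(n_win)) {
    idx <- ((w - 1) * fs + 1):(w * fs)
    e_n <- rowMeans(epoch$data[, idx, drop = FALSE]^2)
    out[w, ] <- (e_n - e_c) / e_c * 100
  }
  out
}

#' Autoregressive power-spectrum features
#'
#' Per channel and per 1 s task window, a univariate AR(`p`) model is fit by
#' Burg's method and its spectrum
#' `P(w) = sigma^2 / |1 - sum_i phi_i exp(-1i w i)|^2` is evaluated on a
#' uniform grid of as many frequency points as the window has samples (125 at
#' the pipeline rate), then normalized to unit total mass. The scalar band
#' ratio is the normalized mass falling in the mu (8-13 Hz) plus beta
#' (13-30 Hz) rhythms, counting both spectral half-axes.
#'
#' @param epoch an [eeg_epoch()].
#' @param p AR order (default 10).
#' @return List of class `ar_spectrum_features`: `values` array
#'   `[n_windows x n_channels x n_freq]` of normalized spectral mass (sums to
#'   1 per window/channel) and `band_ratio` matrix `[n_windows x n_channels]`
#'   in `[0, 1]`.
#' @export
ar_spectrum <- function(epoch, p = 10) {
  stopifnot(inherits(epoch, "eeg_epoch"))
  fs <- epoch$fs
  n_win <- ncol(epoch$data) %/% fs
  nf <- as.integer(fs)                      # one point per Hz over [0, fs)
  nch <- nrow(epoch$data)
  freqs <- (seq_len(nf) - 1) * fs / nf
  f_fold <- pmin(freqs, fs - freqs)         # alias to the physical half-axis
  in_band <- f_fold >= 8 & f_fold < 30
  vals <- array(NA_real_, c(n_win, nch, nf),
                dimnames = list(paste0("w", seq_len(n_win)),
                                paste0("ch", seq_len(nch)),
                                paste0("f", seq_len(nf) - 1)))
  ratio <- matrix(NA_real_, n_win, nch)
  for (w in seq_len(n_win)) {
    idx <- ((w - 1) * fs + 1):(w * fs)
    for (ch in seq_len(nch)) {
      x <- epoch$data[ch, idx]
      if (stats::sd(x) < 1e-12) {
        stop_invalid("constant signal: AR fit failed (channel %d, window %d)",
                     ch, w)
      }
      fit <- stats::ar.burg(x, aic = FALSE, order.max = p, demean = TRUE)
      phi <- fit$ar
      roots <- polyroot(c(1, -phi))
      if (any(Mod(roots) <= 1 + 1e-10)) {
        stop_invalid("unstable AR fit (channel %d, window %d)", ch, w)
      }
      denom <- Mod(stats::fft(c(1, -phi, numeric(nf - p - 1))))^2
      pw <- fit$var.pred / denom
      pw <- pw / sum(pw)
      vals[w, ch, ] <- pw
      ratio[w, ch] <- sum(pw[in_band])
    }
  }
  structure(list(values = vals, band_ratio = ratio, freqs = freqs),
            class = "ar_spectrum_features")
}

# Orthonormal Daubechies-4 (8-tap) scaling filter.
db4_filter <- function() {
  c(0.230377813308855, 0.714846570552542, 0.630880767929590,
    -0.027983769416984, -0.187034811718881, 0.030841381835987,
    0.032883011666983, -0.010597401784997)
}

# One analysis step: symmetric (whole-point reflection) extension, convolve
# with the decomposition filter, keep the centrally aligned coefficients,
# downsample by 2. The trim keeps ceil(n/2) coefficients per child so the
# transform neither grows nor double-counts boundary energy.
wp_step <- function(x, f) {
  L <- length(f)
  n <- length(x)
  pre <- x[pmin(n, L:1)]
  post <- x[pmax(1, n:(n - L + 1))]
  xe <- c(pre, x, post)
  y <- stats::convolve(xe, f, type = "filter")  # length n + L + 1
  y <- y[(L %/% 2 + 1):(L %/% 2 + n)]
  y[seq(2, length(y), by = 2)]
}

#' Frequency-ordered wavelet-packet node energies
#'
#' Full `level`-deep wavelet-packet decomposition with the db4 filter pair
#' and symmetric boundary extension. Nodes are returned in frequency
#' (sequency) order, so node `m` (0-based) covers approximately
#' `[m, m + 1) * fs / 2^(level + 1)` Hz; the energy of a node is the sum of
#' its squared coefficients.
#'
#' @param x numeric vector (one channel's task window).
#' @param level decomposition depth (default 3, eight nodes).
#' @return Numeric vector of `2^level` node energies, frequency ordered.
#' @export
wp_node_energies <- function(x, level = 3) {
  h <- db4_filter()
  if (length(x) <= 2^level + length(h)) {
    stop_invalid("signal shorter than the wavelet filter support")
  }
  dec_lo <- rev(h)
  dec_hi <- h * c(1, -1)                       # quadrature mirror of dec_lo
  nodes <- list(x)                             # frequency-ordered at level 0
  for (l in seq_len(level)) {
    nxt <- vector("list", 2 * length(nodes))
    for (m in seq_along(nodes)) {
      lo <- wp_step(nodes[[m]], dec_lo)
      hi <- wp_step(nodes[[m]], dec_hi)
      # frequency ordering: spectral ordering of the two children flips for
      # nodes at odd frequency position (aliasing of the downsampled band)
      if ((m - 1) %% 2 == 0) {
        nxt[[2 * m - 1]] <- lo; nxt[[2 * m]] <- hi
      } else {
        nxt[[2 * m - 1]] <- hi; nxt[[2 * m]] <- lo
      }
    }
    nodes <- nxt
  }
  vapply(nodes, function(d) sum(d^2), 0)
}

#' Wavelet-packet node-energy features
#'
#' Three-level db4 wavelet-packet decomposition per channel; the features are
#' the energies of the four frequency-ordered level-3 nodes covering
#' approximately 7.8-39 Hz (node 1: ~7.8-15.6 Hz near alpha; nodes 2-4 near
#' beta), i.e. `4 x n_channels` values.
#'
#' @param epoch an [eeg_epoch()].
#' @param level decomposition depth (default 3).
#' @param nodes 0-based frequency-ordered node indices to keep (default 1:4).
#' @return Numeric matrix `[length(nodes) x n_channels]` of node energies.
#' @export
wavelet_packet_features <- function(epoch, level = 3, nodes = 1:4) {
  stopifnot(inherits(epoch, "eeg_epoch"))
  nch <- nrow(epoch$data)
  out <- matrix(NA_real_, length(nodes), nch,
                dimnames = list(paste0("n", nodes),
                                paste0("ch", seq_len(nch))))
  for (ch in seq_len(nch)) {
    en <- wp_node_energies(epoch$data[ch, ], level = level)
    out[, ch] <- en[nodes + 1L]
  }
  out
}

#' Canonical feature block order
#'
#' The fixed concatenation order of the five feature families; on the
#' nine-channel, 3 s, 125 Hz epoch their dimensionalities are microstate 12,
#' network 6, energy 27, AR 3375, wavelet 36.
#'
#' @return Character vector of block names.
#' @export
feature_block_order <- function() {
  c("microstate", "network", "energy", "ar", "wavelet")
}

#' Assemble a single-trial feature vector from named blocks
#'
#' Concatenates the requested feature blocks in fixed canonical order
#' (microstate, network, energy, AR spectrum, wavelet packet). On the
#' standard montage the combined five-block vector has length
#' `12 + 6 + 27 + 3375 + 36 = 3456`.
#'
#' @param epoch an [eeg_epoch()].
#' @param blocks character subset of
#'   `c("microstate", "network", "energy", "ar", "wavelet")`.
#' @param typical typical `microstate_model`, required for the microstate
#'   block.
#' @param density graph binarization density for the network block.
#' @param mvar_order MVAR order for PDC (integer or `"auto"`).
#' @param ar_order univariate AR order for the spectrum block.
#' @param seed integer seed (trial-level clustering determinism).
#' @return Named numeric feature vector with a `block` attribute mapping
#'   names to blocks.
#' @export
assemble_features <- function(epoch,
                              blocks = feature_block_order(),
                              typical = NULL, density = 0.3,
                              mvar_order = 8, ar_order = 10, seed = NULL) {
  stopifnot(inherits(epoch, "eeg_epoch"))
  blocks <- unique(blocks)
  unknown <- setdiff(blocks, feature_block_order())
  if (length(unknown)) stop_invalid("unknown block(s): %s",
                                    paste(unknown, collapse = ", "))
  if ("microstate" %in% blocks && is.null(typical)) {
    stop_invalid("missing block input: microstate needs a `typical` model")
  }
  blocks <- intersect(feature_block_order(), blocks)
  pieces <- list()
  for (b in blocks) {
    pieces[[b]] <- switch(
      b,
      microstate = microstate_features(epoch, typical, seed = seed),
      network = {
        m <- fit_mvar(epoch, p = mvar_order)
        network_features(band_average(compute_pdc(m)), density = density)
      },
      energy = {
        e <- erd_energy(epoch)
        stats::setNames(as.numeric(e), outer(rownames(e), colnames(e),
                                             function(a, b) paste0("en_", a, "_", b)))
      },
      ar = {
        s <- ar_spectrum(epoch, p = ar_order)
        v <- s$values
        nm <- outer(
          outer(dimnames(v)[[1]], dimnames(v)[[2]],
                function(a, b) paste0("ar_", a, "_", b)),
          dimnames(v)[[3]], function(a, b) paste0(a, "_", b))
        stats::setNames(as.numeric(v), as.character(nm))
      },
      wavelet = {
        wv <- wavelet_packet_features(epoch)
        stats::setNames(as.numeric(wv), outer(rownames(wv), colnames(wv),
                                              function(a, b) paste0("wp_", a, "_", b)))
      }
    )
  }
  out <- unlist(pieces, use.names = TRUE)
  names(out) <- sub("^[a-z]+\\.", "", names(out))
  attr(out, "block") <- rep(blocks, vapply(pieces, length, 1L))
  out
}
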