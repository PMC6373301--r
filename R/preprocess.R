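#' Re-reference a recording to the common average
#'
#' Subtracts the instantaneous mean across channels from every channel, so at
#' each sample the spatial mean is zero. Idempotent.
#'
#' @param rec an [eeg_recording()] with at least two channels.
#' @return The re-referenced [eeg_recording()], same shape.
#' @export
#' @examples
#' rec <- eeg_recording(matrix(rnorm(9 * 100), 9), fs = 125)
#' colMeans(common_average_reference(rec)$data)[1:3]
common_average_reference <- function(rec) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (nrow(rec$data) < 2) stop_invalid("CAR needs at least 2 channels")
  rec$data <- sweep(rec$data, 2, colMeans(rec$data), "-")
  rec
}

# Causal FIR filtering of a vector by coefficients b, via FFT linear
# convolution (keeps the first length(x) samples of the full convolution,
# i.e. exactly what a direct-form FIR would emit).
fft_causal_fir <- function(x, b) {
  n <- length(x); L <- length(b)
  nfft <- 2^ceiling(log2(n + L))
  y <- Re(stats::fft(stats::fft(c(x, numeric(nfft - n))) *
                       stats::fft(c(b, numeric(nfft - L))), inverse = TRUE)) / nfft
  y[seq_len(n)]
}

# Zero-phase (forward-backward) FIR filtering with odd-reflection edge
# padding, applied row-wise to a channels-x-samples matrix.
fir_filtfilt <- function(mat, b) {
  L <- length(b)
  n <- ncol(mat)
  if (n <= L) stop_invalid("signal shorter than filter support")
  t(apply(mat, 1, function(x) {
    pre <- 2 * x[1] - x[(L + 1):2]
    post <- 2 * x[n] - x[(n - 1):(n - L)]
    xe <- c(pre, x, post)
    y <- fft_causal_fir(xe, b)
    y <- rev(fft_causal_fir(rev(y), b))
    y[(L + 1):(L + n)]
  }))
}

#' Zero-phase FIR band-limiting
#'
#' High-pass at `hp_hz` (offset/trend removal) and low-pass at `lp_hz`,
#' applied as forward-backward (zero-phase) filtering of a linear-phase
#' windowed FIR. When `hp_hz` is below the frequency resolution any epoch-
#' length FIR can realize (cutoffs like 0.05 Hz), the high-pass is effected
#' exactly by removing each channel's mean and linear trend, and only the
#' low-pass FIR is applied; the DC-rejection contract is identical.
#'
#' @param rec an [eeg_recording()].
#' @param hp_hz high-pass cutoff in Hz, `0 < hp_hz < lp_hz`.
#' @param lp_hz low-pass cutoff in Hz, `< fs/2`.
#' @param order FIR order (even); default scales with the recording length.
#' @return The filtered [eeg_recording()].
#' @export
fir_bandlimit <- function(rec, hp_hz = 0.05, lp_hz = 48, order = NULL) {
  stopifnot(inherits(rec, "eeg_recording"))
  fs <- rec$fs
  if (!(hp_hz > 0 && hp_hz < lp_hz)) stop_invalid("need 0 < hp_hz < lp_hz")
  if (lp_hz >= fs / 2) stop_invalid("low-pass cutoff must be below Nyquist (%g Hz)", fs / 2)
  n <- ncol(rec$data)
  if (is.null(order)) order <- max(16L, min(500L, 2L * ((n - 2L) %/% 6L)))
  order <- as.integer(order) + as.integer(order) %% 2L  # force even
  hp_realizable <- hp_hz > 2 * fs / order
  b <- if (hp_realizable) {
    signal::fir1(order, c(hp_hz, lp_hz) / (fs / 2), type = "pass")
  } else {
    signal::fir1(order, lp_hz / (fs / 2), type = "low")
  }
  x <- rec$data
  if (!hp_realizable) {
    # exact offset and linear-trend removal per channel
    tt <- seq_len(n) - (n + 1) / 2
    beta <- (x %*% tt) / sum(tt^2)
    x <- x - rowMeans(x) - beta %*% t(tt)
  }
  rec$data <- fir_filtfilt(x, as.numeric(b))
  rec
}

#' Decimate a recording to a lower sampling rate
#'
#' Applies an anti-alias zero-phase FIR low-pass at 80% of the target Nyquist
#' and keeps every `fs/target_fs`-th sample. Event sample indices are rescaled
#' with floor rounding.
#'
#' @param rec an [eeg_recording()].
#' @param target_fs target rate in Hz; must divide `fs`.
#' @return The decimated [eeg_recording()].
#' @export
downsample <- function(rec, target_fs = 125) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (target_fs > rec$fs) stop_invalid("target_fs exceeds the sampling rate")
  if (target_fs == rec$fs) return(rec)
  factor <- rec$fs / target_fs
  if (abs(factor - round(factor)) > 1e-9) {
    stop_invalid("fs (%g) must be an integer multiple of target_fs (%g)",
                 rec$fs, target_fs)
  }
  factor <- as.integer(round(factor))
  cutoff <- 0.8 * target_fs / 2
  order <- max(16L, min(400L, 2L * ((ncol(rec$data) - 2L) %/% 6L)))
  b <- signal::fir1(order, cutoff / (rec$fs / 2), type = "low")
  filtered <- fir_filtfilt(rec$data, as.numeric(b))
  keep <- seq(1L, ncol(filtered), by = factor)  # 0-based samples 0, f, 2f, ...
  rec$data <- filtered[, keep, drop = FALSE]
  rec$fs <- target_fs
  if (!is.null(rec$events)) {
    rec$events$sample <- pmin(ncol(rec$data) - 1L,
                              as.integer(rec$events$sample %/% factor))
  }
  rec
}

#' Cut labeled task epochs (plus baselines) out of a recording
#'
#' Each event `e` yields a task window spanning `[e, e + task_s)` seconds and
#' a baseline spanning `[e - baseline_s, e)` (half-open, 0-based sample
#' indexing). Events too close to either edge are skipped with a warning.
#'
#' @param rec an [eeg_recording()] carrying events labeled
#'   `"task:mode:level"`.
#' @param task_s task window length in seconds (default 3).
#' @param baseline_s baseline length in seconds (default 1).
#' @param subject_id,session_id provenance identifiers stamped on the epochs.
#' @return An [epoch_set()].
#' @export
extract_epochs <- function(rec, task_s = 3, baseline_s = 1,
                           subject_id = 1L, session_id = 1L) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (is.null(rec$events) || !nrow(rec$events)) {
    stop_invalid("recording carries no events")
  }
  n_task <- as.integer(round(task_s * rec$fs))
  n_base <- as.integer(round(baseline_s * rec$fs))
  ns <- ncol(rec$data)
  lab <- parse_event_label(rec$events$label)
  epochs <- list()
  skipped <- 0L
  for (i in seq_len(nrow(rec$events))) {
    e0 <- rec$events$sample[i]  # 0-based
    if (e0 - n_base < 0 || e0 + n_task > ns) {
      skipped <- skipped + 1L
      next
    }
    task_idx <- (e0 + 1L):(e0 + n_task)
    base_idx <- (e0 - n_base + 1L):e0
    epochs[[length(epochs) + 1L]] <- eeg_epoch(
      rec$data[, task_idx, drop = FALSE],
      rec$data[, base_idx, drop = FALSE],
      fs = rec$fs, task = lab$task[i], mode = lab$mode[i],
      level = lab$level[i], subject_id = subject_id,
      session_id = session_id, trial_id = i
    )
  }
  if (skipped > 0) {
    rlang::warn(sprintf("skipped %d event(s) too close to the recording edge",
                        skipped))
  }
  if (!length(epochs)) stop_invalid("no epoch could be extracted")
  epoch_set(epochs, rec$channel_labels)
}

#' Reject epochs with gross amplitude artifacts
#'
#' Removes any epoch whose absolute amplitude exceeds `peak_uv` on any channel
#' in either the task or baseline window. A simple, configurable stand-in for
#' component-based artifact screening.
#'
#' @param es an [epoch_set()].
#' @param peak_uv rejection threshold in microvolts (default 100).
#' @return The cleaned [epoch_set()].
#' @export
reject_artifacts <- function(es, peak_uv = 100) {
  stopifnot(inherits(es, "epoch_set"))
  if (peak_uv <= 0) stop_invalid("`peak_uv` must be positive")
  ok <- vapply(es$epochs, function(e) {
    max(abs(e$data), abs(e$baseline)) <= peak_uv
  }, TRUE)
  n_rej <- sum(!ok)
  if (n_rej > 0) {
    rlang::inform(sprintf("rejected %d/%d epoch(s) exceeding %g uV",
                          n_rej, length(ok), peak_uv))
  }
  if (!any(ok)) {
    rlang::abort("all epochs rejected by the amplitude threshold",
                 class = "gripnet_empty_set")
  }
  epoch_set(es$epochs[ok], es$channel_labels)
}

#' Run the standard preprocessing chain on a raw recording
#'
#' Common average reference, zero-phase FIR band-limit (0.05-48 Hz),
#' decimation to the pipeline rate, epoching, and amplitude-based artifact
#' rejection.
#'
#' @param rec an [eeg_recording()] with events.
#' @param target_fs pipeline rate (default 125 Hz).
#' @param hp_hz,lp_hz band-limit cutoffs.
#' @param peak_uv artifact rejection threshold; `NULL` skips rejection.
#' @param subject_id,session_id stamped on the epochs.
#' @return An [epoch_set()].
#' @export
preprocess_recording <- function(rec, target_fs = 125, hp_hz = 0.05,
                                 lp_hz = 48, peak_uv = 100,
                                 subject_id = 1L, session_id = 1L) {
  rec <- common_average_reference(rec)
  rec <- fir_bandlimit(rec, hp_hz = hp_hz, lp_hz = lp_hz)
  rec <- downsample(rec, target_fs)
  es <- extract_epochs(rec, subject_id = subject_id, session_id = session_id)
  if (!is.null(peak_uv)) es <- reject_artifacts(es, peak_uv) else es
}
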