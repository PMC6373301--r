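#' Construct a raw multichannel EEG recording
#'
#' The container for continuous EEG: a channels-by-samples matrix of scalp
#' potentials in microvolts, its sampling rate, ordered channel labels, and an
#' optional event table marking trial onsets.
#'
#' @param data numeric matrix `[n_channels x n_samples]`, microvolts.
#' @param fs sampling rate in Hz (> 0).
#' @param channel_labels character vector of unique channel names, one per row
#'   of `data`. Defaults to the standard nine-electrode motor montage when the
#'   recording has nine channels.
#' @param events optional data frame with columns `sample` (0-based sample
#'   index of the task onset) and `label` (a string `"task:mode:level"`, e.g.
#'   `"force:actual:2"`).
#'
#' @return An object of class `eeg_recording`.
#' @export
#' @examples
#' rec <- eeg_recording(matrix(rnorm(9 * 500), 9), fs = 125)
eeg_recording <- function(data, fs, channel_labels = NULL, events = NULL) {
  check_matrix(data)
  if (nrow(data) < 2) stop_invalid("a recording needs at least 2 channels")
  if (!is.numeric(fs) || length(fs) != 1 || fs <= 0) {
    stop_invalid("`fs` must be a single positive number")
  }
  if (is.null(channel_labels)) {
    channel_labels <- if (nrow(data) == 9) motor_montage() else
      paste0("ch", seq_len(nrow(data)))
  }
  if (length(channel_labels) != nrow(data) || anyDuplicated(channel_labels)) {
    stop_invalid("`channel_labels` must be unique, one per channel")
  }
  if (!is.null(events)) {
    events <- tibble::as_tibble(events)
    if (!all(c("sample", "label") %in% names(events))) {
      stop_invalid("`events` needs columns `sample` and `label`")
    }
    if (nrow(events) && (any(events$sample < 0) ||
                         any(events$sample >= ncol(data)))) {
      stop_invalid("event sample indices must lie within [0, n_samples)")
    }
  }
  structure(
    list(data = data, fs = fs, channel_labels = channel_labels,
         events = events),
    class = "eeg_recording"
  )
}

#' Standard nine-electrode motor montage
#'
#' Channel order used throughout: FC3, FCz, FC4, C3, Cz, C4, CP3, Pz, CP4 —
#' the sensorimotor strip plus midline parietal.
#'
#' @return Character vector of nine channel labels.
#' @export
motor_montage <- function() {
  c("FC3", "FCz", "FC4", "C3", "Cz", "C4", "CP3", "Pz", "CP4")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf(
    "<eeg_recording> %d channels x %d samples @ %g Hz (%.1f s), %d events\n",
    nrow(x$data), ncol(x$data), x$fs, ncol(x$data) / x$fs,
    if (is.null(x$events)) 0L else nrow(x$events)
  ))
  invisible(x)
}

#' @export
dim.eeg_recording <- function(x) dim(x$data)

#' Read a recording from a delimited text matrix
#'
#' Fixture-friendly raw format: a tab-separated matrix of channels x samples
#' with a one-line header `# fs=<Hz> channels=<comma-separated labels>`.
#'
#' @param path file path.
#' @param events_path optional path to a two-column delimited table
#'   (`sample`, `label`) of trial events.
#' @return An [eeg_recording()].
#' @export
#' @examples
#' rec <- read_recording_tsv(
#'   system.file("extdata", "demo_recording.tsv", package = "gripnet"),
#'   system.file("extdata", "demo_events.tsv", package = "gripnet"))
#' rec
read_recording_tsv <- function(path, events_path = NULL) {
  header <- readLines(path, n = 1L)
  if (!startsWith(header, "#")) stop_invalid("missing `# fs=... channels=...` header")
  fs <- as.numeric(sub(".*fs=([0-9.eE+-]+).*", "\\1", header))
  labels <- strsplit(sub(".*channels=([^ ]+).*", "\\1", header), ",")[[1]]
  mat <- as.matrix(read.table(path, skip = 1L, sep = "\t"))
  dimnames(mat) <- NULL
  events <- if (!is.null(events_path)) read_events_tsv(events_path)
  eeg_recording(mat, fs = fs, channel_labels = labels, events = events)
}

#' Write a recording as a delimited text matrix
#'
#' @param rec an [eeg_recording()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_recording_tsv <- function(rec, path) {
  stopifnot(inherits(rec, "eeg_recording"))
  header <- sprintf("# fs=%g channels=%s", rec$fs,
                    paste(rec$channel_labels, collapse = ","))
  writeLines(header, path)
  suppressWarnings(write.table(
    rec$data, path, append = TRUE, sep = "\t",
    row.names = FALSE, col.names = FALSE
  ))
  invisible(path)
}

#' Read trial events from a delimited table
#'
#' Two tab-separated columns without header: 0-based sample index and a label
#' string `"task:mode:level"`.
#'
#' @param path file path.
#' @return A tibble with columns `sample` and `label`.
#' @export
read_events_tsv <- function(path) {
  ev <- read.table(path, sep = "\t", col.names = c("sample", "label"),
                   colClasses = c("integer", "character"))
  tibble::as_tibble(ev)
}

#' Write trial events to a delimited table
#'
#' @param events tibble with `sample` and `label` columns.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_events_tsv <- function(events, path) {
  write.table(events[, c("sample", "label")], path, sep = "\t",
              row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

# Parse "task:mode:level" labels into a tibble.
parse_event_label <- function(label) {
  parts <- strsplit(label, ":", fixed = TRUE)
  bad <- vapply(parts, length, 1L) != 3L
  if (any(bad)) stop_invalid("event labels must be \"task:mode:level\"")
  tibble::tibble(
    task = vapply(parts, `[[`, "", 1L),
    mode = vapply(parts, `[[`, "", 2L),
    level = as.integer(vapply(parts, `[[`, "", 3L))
  )
}
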