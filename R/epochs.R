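#' Construct a single labeled EEG epoch
#'
#' The pipeline's currency: one trial's task window (3 s at the pipeline rate)
#' plus its 1 s pre-task baseline, with task/mode/level labels and provenance
#' identifiers.
#'
#' @param data numeric matrix `[n_channels x n_task_samples]`, microvolts.
#' @param baseline numeric matrix `[n_channels x n_baseline_samples]`.
#' @param fs sampling rate in Hz.
#' @param task `"force"` or `"speed"`.
#' @param mode `"actual"` or `"imagined"`.
#' @param level grade of the task, 1, 2 or 3.
#' @param subject_id,session_id,trial_id provenance identifiers.
#' @return An object of class `eeg_epoch`.
#' @export
eeg_epoch <- function(data, baseline, fs, task, mode, level,
                      subject_id = 1L, session_id = 1L, trial_id = 1L) {
  check_matrix(data); check_matrix(baseline, "baseline")
  if (nrow(data) != nrow(baseline)) {
    stop_invalid("task and baseline windows must share channels")
  }
  if (!level %in% 1:3) stop_invalid("`level` must be 1, 2 or 3")
  if (!task %in% c("force", "speed")) stop_invalid("unknown task %s", task)
  if (!mode %in% c("actual", "imagined")) stop_invalid("unknown mode %s", mode)
  structure(
    list(data = data, baseline = baseline, fs = fs, task = task, mode = mode,
         level = as.integer(level), subject_id = subject_id,
         session_id = session_id, trial_id = trial_id),
    class = "eeg_epoch"
  )
}

#' @export
print.eeg_epoch <- function(x, ...) {
  cat(sprintf(
    "<eeg_epoch> %s/%s level %d | subj %s sess %s trial %s | %d ch x %d samp @ %g Hz\n",
    x$task, x$mode, x$level, x$subject_id, x$session_id, x$trial_id,
    nrow(x$data), ncol(x$data), x$fs
  ))
  invisible(x)
}

#' Bundle epochs sharing a montage into an epoch set
#'
#' @param epochs list of [eeg_epoch()] objects with identical sampling rate,
#'   channel count and channel order.
#' @param channel_labels channel names shared by all epochs.
#' @return An object of class `epoch_set`.
#' @export
epoch_set <- function(epochs, channel_labels) {
  if (!length(epochs)) stop_invalid("empty epoch set")
  fs <- epochs[[1]]$fs
  nch <- nrow(epochs[[1]]$data)
  same <- vapply(epochs, function(e) e$fs == fs && nrow(e$data) == nch, TRUE)
  if (!all(same)) stop_invalid("all epochs must share fs and channel count")
  if (length(channel_labels) != nch) {
    stop_invalid("`channel_labels` length must equal channel count")
  }
  structure(list(epochs = epochs, channel_labels = channel_labels),
            class = "epoch_set")
}

#' @export
length.epoch_set <- function(x) length(x$epochs)

#' @export
print.epoch_set <- function(x, ...) {
  cat(sprintf("<epoch_set> %d epochs, %d channels @ %g Hz\n",
              length(x$epochs), length(x$channel_labels), x$epochs[[1]]$fs))
  invisible(x)
}

#' Trial manifest of an epoch set
#'
#' @param es an [epoch_set()].
#' @return Tibble with one row per epoch: subject, session, trial, task,
#'   mode, level.
#' @export
epoch_manifest <- function(es) {
  stopifnot(inherits(es, "epoch_set"))
  purrr::map_dfr(es$epochs, function(e) {
    tibble::tibble(subject = e$subject_id, session = e$session_id,
                   trial = e$trial_id, task = e$task, mode = e$mode,
                   level = e$level)
  })
}

#' Write an epoch set as delimited matrices plus a manifest
#'
#' One tab-separated channels-x-samples matrix per epoch (task window and
#' baseline stacked side by side, split column recorded in the manifest) and
#' a `manifest.tsv` naming each file and its labels.
#'
#' @param es an [epoch_set()].
#' @param dir output directory (created if missing).
#' @return The manifest tibble, invisibly.
#' @export
write_epoch_set <- function(es, dir) {
  stopifnot(inherits(es, "epoch_set"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  man <- epoch_manifest(es)
  man$file <- sprintf("epoch_%04d.tsv", seq_len(nrow(man)))
  man$n_task <- vapply(es$epochs, function(e) ncol(e$data), 1L)
  man$fs <- vapply(es$epochs, function(e) e$fs, 1.0)
  for (i in seq_along(es$epochs)) {
    e <- es$epochs[[i]]
    write.table(cbind(e$data, e$baseline), file.path(dir, man$file[i]),
                sep = "\t", row.names = FALSE, col.names = FALSE)
  }
  utils::write.table(man, file.path(dir, "manifest.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  writeLines(paste(es$channel_labels, collapse = ","),
             file.path(dir, "channels.txt"))
  invisible(tibble::as_tibble(man))
}

#' Read an epoch set written by [write_epoch_set()]
#'
#' @param dir directory holding `manifest.tsv`, `channels.txt` and the
#'   per-epoch matrices.
#' @return An [epoch_set()].
#' @export
read_epoch_set <- function(dir) {
  man <- read.table(file.path(dir, "manifest.tsv"), header = TRUE, sep = "\t")
  labels <- strsplit(readLines(file.path(dir, "channels.txt"), n = 1L), ",")[[1]]
  epochs <- lapply(seq_len(nrow(man)), function(i) {
    m <- as.matrix(read.table(file.path(dir, man$file[i]), sep = "\t"))
    dimnames(m) <- NULL
    nt <- man$n_task[i]
    eeg_epoch(m[, seq_len(nt), drop = FALSE],
              m[, -seq_len(nt), drop = FALSE],
              fs = man$fs[i], task = man$task[i], mode = man$mode[i],
              level = man$level[i], subject_id = man$subject[i],
              session_id = man$session[i], trial_id = man$trial[i])
  })
  epoch_set(epochs, labels)
}
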