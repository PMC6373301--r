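# Minimal 16-bit EDF (European Data Format) reader/writer: standard 256-byte
# fixed header, 256 bytes per signal, little-endian int16 data records with
# per-signal linear physical scaling. Covers plain continuous recordings
# (no EDF+ annotations); trial events travel in the separate events table.

pad_field <- function(x, width) {
  x <- substr(as.character(x), 1, width)
  formatC(x, width = width, flag = "-")
}

#' Write a recording as a 16-bit EDF file
#'
#' One-second data records; trailing samples that do not fill a whole record
#' are dropped with a warning. Amplitudes are scaled to the int16 range per
#' channel, so the round trip is exact up to quantization (about 2^-15 of
#' the channel's amplitude range).
#'
#' @param rec an [eeg_recording()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path) {
  stopifnot(inherits(rec, "eeg_recording"))
  ns <- nrow(rec$data)
  spr <- as.integer(round(rec$fs))            # samples per 1 s record
  n_rec <- ncol(rec$data) %/% spr
  if (n_rec < 1) stop_invalid("recording shorter than one EDF record (1 s)")
  if (ncol(rec$data) %% spr != 0) {
    rlang::warn(sprintf("dropping %d trailing sample(s) not filling an EDF record",
                        ncol(rec$data) %% spr))
  }
  pmin <- apply(rec$data, 1, min); pmax <- apply(rec$data, 1, max)
  flat <- pmax - pmin < 1e-9
  pmax[flat] <- pmax[flat] + 1; pmin[flat] <- pmin[flat] - 1
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(paste0(
    pad_field("0", 8), pad_field("synthetic subject", 80),
    pad_field("gripnet recording", 80),
    pad_field("01.01.00", 8), pad_field("00.00.00", 8),
    pad_field(256 * (ns + 1), 8), pad_field("", 44),
    pad_field(n_rec, 8), pad_field(1, 8), pad_field(ns, 4)
  ), con, eos = NULL)
  fields <- list(
    list(rec$channel_labels, 16), list(rep("AgAgCl electrode", ns), 80),
    list(rep("uV", ns), 8), list(formatC(pmin, digits = 6, format = "g"), 8),
    list(formatC(pmax, digits = 6, format = "g"), 8),
    list(rep(-32768L, ns), 8), list(rep(32767L, ns), 8),
    list(rep("", ns), 80), list(rep(spr, ns), 8), list(rep("", ns), 32)
  )
  for (f in fields) {
    writeChar(paste(vapply(f[[1]], pad_field, "", width = f[[2]]),
                    collapse = ""), con, eos = NULL)
  }
  scale <- (pmax - pmin) / (32767 - (-32768))
  for (r in seq_len(n_rec)) {
    cols <- ((r - 1) * spr + 1):(r * spr)
    for (ch in seq_len(ns)) {
      dig <- round((rec$data[ch, cols] - pmin[ch]) / scale[ch] - 32768)
      writeBin(as.integer(pmax(-32768, pmin(32767, dig))), con,
               size = 2, endian = "little")
    }
  }
  invisible(path)
}

#' Read a 16-bit EDF file into a recording
#'
#' @param path EDF file path.
#' @param events_path optional events table, see [read_events_tsv()].
#' @return An [eeg_recording()].
#' @export
read_edf <- function(path, events_path = NULL) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(n) trimws(readChar(con, n, useBytes = TRUE))
  rd(8); rd(80); rd(80); rd(8); rd(8)
  rd(8); rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  if (is.na(ns) || ns < 1) stop_invalid("malformed EDF header")
  labels <- vapply(seq_len(ns), function(i) rd(16), "")
  rd(80 * ns)
  rd(8 * ns)                                   # physical dimension
  pmin <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  pmax <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  dmin <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  dmax <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  rd(80 * ns)
  spr <- as.integer(vapply(seq_len(ns), function(i) rd(8), ""))
  rd(32 * ns)
  if (length(unique(spr)) != 1) {
    stop_invalid("EDF with per-signal sampling rates is not supported")
  }
  fs <- spr[1] / rec_dur
  scale <- (pmax - pmin) / (dmax - dmin)
  data <- matrix(NA_real_, ns, n_rec * spr[1])
  for (r in seq_len(n_rec)) {
    for (ch in seq_len(ns)) {
      dig <- readBin(con, "integer", n = spr[ch], size = 2, signed = TRUE,
                     endian = "little")
      data[ch, ((r - 1) * spr[1] + 1):(r * spr[1])] <-
        (dig - dmin[ch]) * scale[ch] + pmin[ch]
    }
  }
  events <- if (!is.null(events_path)) read_events_tsv(events_path)
  eeg_recording(data, fs = fs, channel_labels = labels, events = events)
}
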