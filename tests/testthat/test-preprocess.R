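test_that("common average reference zeroes the spatial mean and is idempotent", {
  # symmetric two-channel case is a fixed point
  rec <- eeg_recording(rbind(rep(1, 50), rep(-1, 50)), fs = 100)
  expect_equal(common_average_reference(rec)$data, rec$data)
  # plain mean subtraction
  rec2 <- eeg_recording(rbind(rep(2, 50), rep(0, 50)), fs = 100)
  expect_equal(common_average_reference(rec2)$data,
               rbind(rep(1, 50), rep(-1, 50)))
  # random matrix: column means exactly zero, shape unchanged
  rec3 <- eeg_recording(withr::with_seed(1, matrix(rnorm(9000), 9)), fs = 1000)
  out <- common_average_reference(rec3)
  expect_equal(dim(out$data), c(9L, 1000L))
  expect_lt(max(abs(colMeans(out$data))), 1e-12)
  # idempotence
  expect_equal(common_average_reference(out)$data, out$data)
})

test_that("single-channel input is rejected everywhere it is meaningless", {
  expect_error(eeg_recording(matrix(1, 1, 10), fs = 10), class = "gripnet_invalid_input")
  expect_error(compute_gfp(matrix(1, 1, 10)), class = "gripnet_invalid_input")
})

test_that("band-limiting keeps mid-band tones at zero lag and kills DC and stopband", {
  fs <- 1000
  tt <- seq_len(4 * fs) / fs
  tone10 <- sin(2 * pi * 10 * tt)
  rec <- eeg_recording(rbind(tone10 + 50, tone10 * 0.5 + rnorm(length(tt), 0, 1e-6)),
                       fs = fs)
  out <- fir_bandlimit(rec, hp_hz = 0.05, lp_hz = 48)
  mid <- 500:3500  # interior, away from filter edges
  # DC offset removed
  expect_lt(abs(mean(out$data[1, ])), 0.05)
  # amplitude preserved within 1% on the interior
  amp_ratio <- sd(out$data[1, mid]) / sd(tone10[mid])
  expect_gt(amp_ratio, 0.99)
  expect_lt(amp_ratio, 1.01)
  # zero phase: cross-correlation with the input peaks at lag 0
  ccf_out <- ccf(out$data[1, mid], tone10[mid], lag.max = 20, plot = FALSE)
  expect_equal(ccf_out$lag[which.max(ccf_out$acf)], 0)
  # 60 Hz tone attenuated by >= 20 dB with the 48 Hz low-pass
  tone60 <- sin(2 * pi * 60 * tt)
  out60 <- fir_bandlimit(eeg_recording(rbind(tone60, tone60), fs = fs),
                         hp_hz = 0.05, lp_hz = 48)
  atten_db <- 20 * log10(sd(out60$data[1, mid]) / sd(tone60[mid]))
  expect_lt(atten_db, -20)
  # cutoffs at/above Nyquist rejected
  expect_error(fir_bandlimit(rec, hp_hz = 0.05, lp_hz = 500),
               class = "gripnet_invalid_input")
})

test_that("downsampling decimates cleanly and preserves in-band content", {
  fs <- 1000
  tt <- seq_len(10 * fs) / fs
  x <- rbind(sin(2 * pi * 5 * tt), cos(2 * pi * 5 * tt))
  rec <- eeg_recording(x, fs = fs)
  out <- downsample(rec, 125)
  expect_equal(out$fs, 125)
  expect_equal(ncol(out$data), 1250L)
  # 5 Hz tone survives with amplitude within 2%
  mid <- 100:1150
  expect_lt(abs(sd(out$data[1, mid]) / sd(x[1, ]) - 1), 0.02)
  # identity when target equals fs
  expect_identical(downsample(rec, fs)$data, rec$data)
  # upsampling requests are rejected
  expect_error(downsample(rec, 2000), class = "gripnet_invalid_input")
  # non-integer factors are rejected
  expect_error(downsample(rec, 300), class = "gripnet_invalid_input")
})

test_that("filter-downsample chain preserves a 10 Hz tone's spectral peak", {
  fs <- 1000
  tt <- seq_len(8 * fs) / fs
  rec <- eeg_recording(rbind(sin(2 * pi * 10 * tt), rnorm(length(tt), 0, 0.1)),
                       fs = fs)
  out <- downsample(fir_bandlimit(common_average_reference(rec)), 125)
  spec <- Mod(fft(out$data[1, ]))^2
  n <- ncol(out$data)
  freqs <- (seq_len(n) - 1) * 125 / n
  peak_f <- freqs[which.max(spec[2:(n / 2)]) + 1]
  expect_lt(abs(peak_f - 10), 0.3)
})

test_that("epoch extraction follows the half-open window convention exactly", {
  fs <- 125
  n <- 2000
  # encode the 0-based sample index in the data values
  data <- rbind(0:(n - 1), 0:(n - 1) + 0.5)
  rec <- eeg_recording(data, fs = fs,
                       events = tibble::tibble(sample = 1000L,
                                               label = "force:actual:2"))
  es <- extract_epochs(rec)
  ep <- es$epochs[[1]]
  # task window [1000, 1375), baseline [875, 1000)
  expect_equal(ncol(ep$data), 375L)
  expect_equal(ncol(ep$baseline), 125L)
  expect_equal(ep$data[1, 1], 1000)
  expect_equal(ep$data[1, 375], 1374)
  expect_equal(ep$baseline[1, 1], 875)
  expect_equal(ep$baseline[1, 125], 999)
  expect_equal(ep$task, "force")
  expect_equal(ep$level, 2L)
})

test_that("epoch extraction is count- and label-preserving, minus logged skips", {
  fs <- 125
  n <- 30 * 500 + 600
  rec <- eeg_recording(matrix(rnorm(2 * n), 2), fs = fs)
  labels <- sprintf("force:actual:%d", rep(1:3, 10))
  rec$events <- tibble::tibble(sample = 200L + (0:29) * 500L, label = labels)
  es <- extract_epochs(rec)
  expect_length(es$epochs, 30L)
  expect_equal(vapply(es$epochs, `[[`, 1L, "level"), rep(1:3, 10))
  # an event without a full baseline is skipped with a warning
  rec$events <- tibble::tibble(sample = c(50L, 1000L),
                               label = rep("force:actual:1", 2))
  expect_warning(es2 <- extract_epochs(rec), "skipped")
  expect_length(es2$epochs, 1L)
})

test_that("amplitude artifact rejection removes only offending epochs", {
  fs <- 125
  mk <- function(spike) {
    d <- matrix(rnorm(9 * 375, 0, 10), 9)
    if (spike) d[3, 100] <- 500
    eeg_epoch(d, matrix(rnorm(9 * 125, 0, 10), 9), fs = fs,
              task = "force", mode = "actual", level = 1L)
  }
  es <- epoch_set(list(mk(FALSE), mk(TRUE), mk(FALSE)), motor_montage())
  expect_message(out <- reject_artifacts(es, peak_uv = 100), "rejected 1/3")
  expect_length(out$epochs, 2L)
  # all-clean set passes unchanged
  es_clean <- epoch_set(list(mk(FALSE), mk(FALSE)), motor_montage())
  expect_length(reject_artifacts(es_clean, 100)$epochs, 2L)
  # threshold below the noise floor empties the set
  expect_error(suppressMessages(reject_artifacts(es_clean, 0.1)),
               class = "gripnet_empty_set")
})
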