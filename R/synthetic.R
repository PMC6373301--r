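#' Configuration for the synthetic EEG generator
#'
#' Defaults emulate the study design the pipeline assumes: 20 subjects, 3
#' sessions, 30 trials per session (10 per grade level), nine channels, raw
#' generation at 1000 Hz passed through the real preprocessing chain to the
#' 125 Hz pipeline rate. Each trial superimposes (i) a microstate-like
#' component — an alpha-modulated sequence of three orthogonal template
#' topographies whose segment durations and amplitudes carry class-dependent
#' gradients — (ii) a multivariate autoregressive component with beta-band
#' (~20 Hz) directed coupling whose structure and strength grade with the
#' class (denser/stronger with force level, sparser/weaker with speed
#' level), and (iii) 1/f plus white noise; the 1 s baseline is noise only.
#'
#' @param n_subjects,n_sessions,trials_per_class study layout (20 / 3 / 10).
#' @param n_channels electrodes (9).
#' @param fs_raw raw generation rate (1000 Hz).
#' @param fs pipeline rate after decimation (125 Hz).
#' @param q number of template maps (3: A, B, C).
#' @param task_s,baseline_s,pad_s epoch windows and edge padding (s).
#' @param snr microstate-component RMS over noise RMS (default 5).
#' @param pink_frac fraction of noise power with a 1/f spectrum (0.5).
#' @param mvar_scale MVAR-component RMS relative to the microstate component
#'   (default 2.2: the coupled beta network must dominate the beta band, or
#'   the microstate component's modulation sidebands — whose spatial pattern
#'   depends on the drawn templates — would bias the estimated networks).
#' @param alpha_hz modulation frequency of the topography envelope (10.2 Hz,
#'   giving GFP peaks every ~49 ms).
#' @param subject_jitter subject-level random effects: template rotation
#'   (`rot`), multiplicative SNR spread (`snr_sd`).
#' @param seed master seed.
#' @return Object of class `synth_config`.
#' @export
synth_config <- function(n_subjects = 20, n_sessions = 3,
                         trials_per_class = 10, n_channels = 9,
                         fs_raw = 1000, fs = 125, q = 3,
                         task_s = 3, baseline_s = 1, pad_s = 0.6,
                         snr = 5, pink_frac = 0.5, mvar_scale = 2.2,
                         alpha_hz = 10.2,
                         subject_jitter = list(rot = 0.15, snr_sd = 0.1),
                         seed = 1) {
  stopifnot(n_subjects >= 1, n_sessions >= 1, trials_per_class >= 1,
            q >= 2, q <= n_channels - 1, snr > 0, fs_raw %% fs == 0)
  structure(
    list(n_subjects = n_subjects, n_sessions = n_sessions,
         trials_per_class = trials_per_class, n_channels = n_channels,
         fs_raw = fs_raw, fs = fs, q = q, task_s = task_s,
         baseline_s = baseline_s, pad_s = pad_s, snr = snr,
         pink_frac = pink_frac, mvar_scale = mvar_scale,
         alpha_hz = alpha_hz, subject_jitter = subject_jitter, seed = seed),
    class = "synth_config"
  )
}

#' Orthonormal average-referenced template topographies
#'
#' `q` mutually orthogonal unit-norm maps drawn from a seeded random rotation
#' of the zero-mean (average-referenced) subspace, so they survive the common
#' average reference unchanged and have pairwise spatial correlation 0.
#'
#' @param n_channels electrode count.
#' @param q number of templates (<= `n_channels - 1`).
#' @param seed integer seed.
#' @return Matrix `[q x n_channels]`, rows unit-norm and zero-mean.
#' @export
make_templates <- function(n_channels = 9, q = 3, seed = 1) {
  if (q > n_channels - 1) {
    stop_invalid("q = %d exceeds the zero-mean subspace dimension %d",
                 q, n_channels - 1)
  }
  with_seed(seed, {
    g <- matrix(rnorm(n_channels * n_channels), n_channels)
    g <- sweep(g, 2, colMeans(g), "-")      # columns into zero-sum subspace
    t(qr.Q(qr(g))[, seq_len(q), drop = FALSE])
  })
}

#' Class-dependent generator profile
#'
#' The per-class gradients the generator encodes, mirroring the qualitative
#' trends the pipeline is meant to detect: for the force task, map C's
#' duration and amplitude and the beta-band coupling density/strength all
#' increase with level; for the speed task, map A's duration increases while
#' map C's duration and the beta coupling decrease with level. Imagined mode
#' scales amplitudes and couplings by 0.8.
#'
#' @param task `"force"` or `"speed"`.
#' @param mode `"actual"` or `"imagined"`.
#' @param level grade 1-3.
#' @return List with `duration_ms`, `amplitude_uv` (per template A, B, C),
#'   `edges` (directed coupling edge matrix), `g` (coupling strength).
#' @export
class_profile <- function(task, mode, level) {
  stopifnot(task %in% c("force", "speed"), mode %in% c("actual", "imagined"),
            level %in% 1:3)
  # Feed-forward (acyclic) coupling graphs — no directed cycles, so the
  # generator's poles stay at the oscillator modulus for any coupling
  # gain. Levels 1 and 2 share a triangle-free chain (long paths, no
  # clustering) at rising gain; the top level switches to a 5-clique with
  # a spoke from every outer node (dense triangles, everything within two
  # hops of the clique) at a stronger gain still. Every structure touches
  # all nine nodes, and the clique carries more candidate edges (14) than
  # the density-0.3 binarization keeps (11), so estimation-noise edges
  # cannot dilute its compactness. The estimated beta network then grades
  # monotonically in both metrics: clustering up and path length down as
  # coupling densifies and strengthens with the level.
  chain9 <- rbind(cbind(1:8, 2:9), c(1, 4), c(6, 9))
  clique5spoke <- {
    p <- expand.grid(from = 1:5, to = 1:5)
    rbind(as.matrix(p[p$from < p$to, ]),
          c(6, 1), c(7, 2), c(8, 3), c(9, 4))
  }
  # Gains rise with level; the clique needs a disproportionately large
  # gain because an acyclic 5-clique necessarily has high out-degree
  # sources whose PDC outflow normalization dilutes every edge.
  structures <- list(chain9, chain9, clique5spoke)
  strengths <- c(0.40, 0.60, 2.00)
  if (task == "force") {
    dur <- c(A = 100, B = 100, C = 80 + 30 * (level - 1))
    amp <- c(A = 16, B = 20, C = 22 + 3 * (level - 1))
    k <- level
  } else {
    dur <- c(A = 80 + 30 * (level - 1), B = 70, C = 140 - 30 * (level - 1))
    amp <- c(A = c(18, 18, 14)[level], B = 19, C = 21)
    k <- 4 - level
  }
  scale <- if (mode == "imagined") 0.8 else 1
  list(duration_ms = dur, amplitude_uv = amp * scale,
       edges = structures[[k]], g = strengths[k] * scale)
}

# 1/f^alpha noise via spectral shaping, one channel per row.
pink_noise <- function(n_channels, n, alpha = 1) {
  f <- c(1, pmin(seq_len(n - 1), n - seq_len(n - 1)))  # symmetric spectrum
  shape <- 1 / sqrt(f^alpha)
  t(vapply(seq_len(n_channels), function(i) {
    w <- stats::fft(rnorm(n))
    x <- Re(stats::fft(w * shape, inverse = TRUE)) / n
    x / stats::sd(x)
  }, numeric(n)))
}

# Draw a microstate label sequence (cycling A -> B -> C) with gamma-jittered
# segment durations; returns per-sample labels for `n` samples at `fs_raw`.
label_sequence <- function(n, fs_raw, duration_ms, q) {
  labels <- integer(0)
  state <- 1L
  while (length(labels) < n) {
    d_ms <- stats::rgamma(1, shape = 12,
                          rate = 12 / duration_ms[(state - 1L) %% q + 1L])
    len <- max(1L, round(d_ms / 1000 * fs_raw))
    labels <- c(labels, rep((state - 1L) %% q + 1L, len))
    state <- state + 1L
  }
  labels[seq_len(n)]
}

# Band-limited upsampling by an integer factor via FFT zero-padding.
fft_upsample <- function(x, factor) {
  n <- length(x)
  m <- n * factor
  xf <- stats::fft(x)
  half <- (n - 1) %/% 2
  yf <- complex(m)
  yf[1:(half + 1)] <- xf[1:(half + 1)]
  yf[(m - (n - half - 1) + 1):m] <- xf[(half + 2):n]
  Re(stats::fft(yf, inverse = TRUE)) * factor / m
}

# Coupling coefficient matrices of the beta-band MVAR generator at the
# pipeline rate: AR(2) oscillators at `beta_hz` plus lag-1 directed coupling
# of strength `g` on the feed-forward `edges`.
mvar_generator_coeffs <- function(n_channels, edges, g, beta_hz = 20,
                                  fs = 125, rho = 0.8) {
  theta <- 2 * pi * beta_hz / fs
  a1 <- diag(2 * rho * cos(theta), n_channels)
  if (nrow(edges) > 0) {
    a1[edges[, c(2, 1), drop = FALSE]] <- a1[edges[, c(2, 1), drop = FALSE]] + g
  }
  list(a1 = a1, a2 = diag(-rho^2, n_channels))
}

# Simulate the coupled beta-band MVAR component at the pipeline rate
# (channels x n), rescaled to unit overall RMS. Generated at 125 Hz — where
# a 20 Hz resonance keeps a wide stability margin under coupling — and
# band-limited-upsampled to the raw rate by the caller.
mvar_component <- function(n_channels, n, edges, g, beta_hz = 20, fs = 125,
                           rho = 0.8) {
  co <- mvar_generator_coeffs(n_channels, edges, g, beta_hz, fs, rho)
  burn <- 200L
  x <- matrix(0, n_channels, n + burn)
  e <- matrix(rnorm(n_channels * (n + burn)), n_channels)
  for (t in 3:(n + burn)) {
    x[, t] <- co$a1 %*% x[, t - 1] + co$a2 %*% x[, t - 2] + e[, t]
  }
  x <- x[, burn + seq_len(n), drop = FALSE]
  x / sqrt(mean(x^2))
}

#' Simulate one raw trial recording
#'
#' Builds the 1000 Hz raw segment for a single trial — edge padding, noise-
#' only baseline, then the 3 s task window carrying the template-sequence
#' and coupled-MVAR components — and returns it as an [eeg_recording()] with
#' a single event at the task onset.
#'
#' @param cfg a [synth_config()].
#' @param task,mode,level the class.
#' @param seed integer seed.
#' @param templates optional `[q x n_channels]` template matrix (e.g. a
#'   subject-specific rotation); defaults to `make_templates(seed = cfg$seed)`.
#' @param snr overrides `cfg$snr` (subject-level jitter).
#' @return An [eeg_recording()] with one labeled event.
#' @export
simulate_trial_raw <- function(cfg, task, mode, level, seed = 1,
                               templates = NULL, snr = NULL) {
  stopifnot(inherits(cfg, "synth_config"))
  prof <- class_profile(task, mode, level)
  snr <- snr %||% cfg$snr
  templates <- templates %||% make_templates(cfg$n_channels, cfg$q,
                                             seed = cfg$seed)
  fsr <- cfg$fs_raw
  n_pad <- round(cfg$pad_s * fsr)
  n_base <- round(cfg$baseline_s * fsr)
  n_task <- round(cfg$task_s * fsr)
  n_tot <- 2 * n_pad + n_base + n_task
  event <- n_pad + n_base                      # 0-based task onset
  with_seed(seed, {
    # microstate component: amplitude-modulated template sequence with a
    # short linear crossfade between states — hard switches would inject
    # broadband transients whose rate depends on the class's segment
    # durations, bleeding class-dependent power into the beta band
    lab <- label_sequence(n_task, fsr, prof$duration_ms, cfg$q)
    ind <- matrix(0, n_task, cfg$q)
    ind[cbind(seq_len(n_task), lab)] <- 1
    k <- max(1L, round(0.024 * fsr))
    w <- apply(ind, 2, function(col) {
      sm <- stats::filter(col, rep(1 / k, k), sides = 2)
      ifelse(is.na(sm), col, as.numeric(sm))
    })
    w <- w / rowSums(w)
    tt <- seq_len(n_task) / fsr
    envelope <- sin(2 * pi * cfg$alpha_hz * tt)
    ms <- t((w %*% (templates * prof$amplitude_uv)) * envelope)
    ms_rms <- sqrt(mean(ms^2))
    # coupled beta-band MVAR component, upsampled to the raw rate
    factor_up <- fsr / cfg$fs
    mv125 <- mvar_component(cfg$n_channels, n_task / factor_up,
                            prof$edges, prof$g, fs = cfg$fs)
    mv <- t(apply(mv125, 1, fft_upsample, factor = factor_up)) *
      (cfg$mvar_scale * ms_rms)
    # 1/f + white noise over the whole segment
    noise_rms <- ms_rms / snr
    noise <- (sqrt(cfg$pink_frac) * pink_noise(cfg$n_channels, n_tot) +
                sqrt(1 - cfg$pink_frac) *
                matrix(rnorm(cfg$n_channels * n_tot), cfg$n_channels)) *
      noise_rms
    data <- noise
    task_cols <- event + seq_len(n_task)
    data[, task_cols] <- data[, task_cols] + ms + mv
    eeg_recording(
      data, fs = fsr,
      events = tibble::tibble(sample = event,
                              label = sprintf("%s:%s:%d", task, mode, level))
    )
  })
}

#' Simulate one preprocessed trial epoch
#'
#' [simulate_trial_raw()] passed through the real preprocessing chain
#' (common average reference, 0.05-48 Hz zero-phase FIR, decimation to the
#' pipeline rate, epoching). The generating label sequence (at the pipeline
#' rate) is attached as attribute `"true_labels"` for recovery tests.
#'
#' @inheritParams simulate_trial_raw
#' @param subject_id,session_id,trial_id stamped on the epoch.
#' @return An [eeg_epoch()].
#' @export
simulate_trial <- function(cfg, task, mode, level, seed = 1,
                           templates = NULL, snr = NULL,
                           subject_id = 1L, session_id = 1L, trial_id = 1L) {
  rec <- simulate_trial_raw(cfg, task, mode, level, seed = seed,
                            templates = templates, snr = snr)
  es <- preprocess_recording(rec, target_fs = cfg$fs, peak_uv = NULL,
                             subject_id = subject_id,
                             session_id = session_id)
  ep <- es$epochs[[1]]
  ep$trial_id <- trial_id
  # regenerate the label sequence deterministically for ground truth
  prof <- class_profile(task, mode, level)
  lab_raw <- with_seed(seed, label_sequence(round(cfg$task_s * cfg$fs_raw),
                                            cfg$fs_raw, prof$duration_ms,
                                            cfg$q))
  factor_ds <- cfg$fs_raw / cfg$fs
  attr(ep, "true_labels") <- lab_raw[seq(1, length(lab_raw), by = factor_ds)]
  ep
}

#' Simulate a full multi-subject dataset
#'
#' Generates `n_subjects x n_sessions x (3 x trials_per_class)` preprocessed
#' epochs for one task/mode, with randomized class order within each session
#' and subject-level random effects (template rotation and SNR jitter) so
#' that leave-one-subject-out validation is non-trivial. Fully reproducible
#' from `cfg$seed`.
#'
#' @param cfg a [synth_config()].
#' @param task,mode the condition to generate (default actual force).
#' @return List with `epochs` (an [epoch_set()]), `manifest` (tibble),
#'   `templates` (the population template maps).
#' @export
simulate_dataset <- function(cfg, task = "force", mode = "actual") {
  stopifnot(inherits(cfg, "synth_config"))
  pop_templates <- make_templates(cfg$n_channels, cfg$q, seed = cfg$seed)
  epochs <- list()
  trial_counter <- 0L
  for (s in seq_len(cfg$n_subjects)) {
    subj_seed <- derive_seed(cfg$seed, 1000L + s)
    subj <- with_seed(subj_seed, {
      jit <- cfg$subject_jitter
      pert <- pop_templates +
        jit$rot * matrix(rnorm(length(pop_templates)), nrow(pop_templates))
      pert <- pert - rowMeans(pert)
      tnew <- t(qr.Q(qr(t(pert))))
      tnew <- tnew * sign(diag(tcrossprod(tnew, pop_templates)))
      list(templates = tnew,
           snr = cfg$snr * exp(rnorm(1, 0, jit$snr_sd)))
    })
    for (sess in seq_len(cfg$n_sessions)) {
      class_order <- with_seed(derive_seed(subj_seed, sess),
                               sample(rep(1:3, cfg$trials_per_class)))
      for (tr in seq_along(class_order)) {
        trial_counter <- trial_counter + 1L
        epochs[[trial_counter]] <- simulate_trial(
          cfg, task, mode, class_order[tr],
          seed = derive_seed(subj_seed, 100L * sess + tr),
          templates = subj$templates, snr = subj$snr,
          subject_id = s, session_id = sess, trial_id = tr
        )
      }
    }
  }
  es <- epoch_set(epochs, if (cfg$n_channels == 9) motor_montage() else
    paste0("ch", seq_len(cfg$n_channels)))
  list(epochs = es, manifest = epoch_manifest(es), templates = pop_templates)
}
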