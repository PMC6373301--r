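#' Global field power of a multichannel epoch
#'
#' GFP at sample `t` is the spatial standard deviation of the potentials
#' across the `k` electrodes,
#' `GFP(t) = sqrt( sum_i (V_i(t) - V_mean(t))^2 / k )` — the instantaneous
#' electric field strength over the array. Its local maxima mark moments of
#' highest topographic signal-to-noise and are where microstate maps are
#' sampled.
#'
#' @param epoch_data numeric matrix `[n_channels x n_samples]` (or an
#'   [eeg_epoch()], whose task window is used).
#' @param fs sampling rate in Hz (taken from the epoch if one is given).
#' @return An object of class `gfp_curve`: list with `values` (length
#'   `n_samples`, microvolts) and `fs`.
#' @export
#' @examples
#' g <- compute_gfp(matrix(rnorm(9 * 375), 9), fs = 125)
compute_gfp <- function(epoch_data, fs = NULL) {
  if (inherits(epoch_data, "eeg_epoch")) {
    fs <- epoch_data$fs
    epoch_data <- epoch_data$data
  }
  check_matrix(epoch_data)
  if (nrow(epoch_data) < 2) stop_invalid("GFP needs at least 2 channels")
  centered <- sweep(epoch_data, 2, colMeans(epoch_data), "-")
  structure(list(values = sqrt(colMeans(centered^2)), fs = fs %||% NA_real_),
            class = "gfp_curve")
}

#' @export
print.gfp_curve <- function(x, ...) {
  cat(sprintf("<gfp_curve> %d samples @ %g Hz, mean %.3g uV\n",
              length(x$values), x$fs, mean(x$values)))
  invisible(x)
}

#' Local maxima of a GFP curve
#'
#' A peak is a sample `t` with `g[t-1] < g[t] >= g[t+1]` (so the first of two
#' equal adjacent maxima is kept); endpoints are never peaks. Peaks closer
#' than `min_distance_ms` are pruned, keeping the larger of a conflicting
#' pair.
#'
#' @param g a [compute_gfp()] curve.
#' @param min_distance_ms minimum separation between retained peaks (default
#'   10 ms, enough to suppress one-sample jitter at 125 Hz).
#' @return Integer vector of peak positions (1-based sample indices within
#'   the curve); empty for monotone curves.
#' @export
find_gfp_peaks <- function(g, min_distance_ms = 10) {
  stopifnot(inherits(g, "gfp_curve"))
  v <- g$values
  n <- length(v)
  if (n < 3) stop_invalid("curve too short for peak finding")
  idx <- which(v[2:(n - 1)] > v[1:(n - 2)] & v[2:(n - 1)] >= v[3:n]) + 1L
  if (!length(idx)) return(integer(0))
  min_gap <- min_distance_ms / 1000 * g$fs
  if (is.finite(min_gap) && min_gap > 1) {
    # greedy by height: a peak survives unless a taller retained peak is near
    keep <- logical(length(idx))
    for (j in order(v[idx], decreasing = TRUE)) {
      if (!any(keep & abs(idx - idx[j]) < min_gap)) keep[j] <- TRUE
    }
    idx <- sort(idx[keep])
  }
  idx
}

#' Topographies at the GFP peaks of an epoch
#'
#' @param epoch_data matrix `[n_channels x n_samples]` or an [eeg_epoch()].
#' @param fs sampling rate (taken from the epoch if given).
#' @param min_distance_ms peak pruning distance, see [find_gfp_peaks()].
#' @return Object of class `topography_set`: `maps` (`n_peaks x n_channels`,
#'   one row per GFP peak) and `peak_indices`.
#' @export
gfp_peak_maps <- function(epoch_data, fs = NULL, min_distance_ms = 10) {
  if (inherits(epoch_data, "eeg_epoch")) {
    fs <- epoch_data$fs
    epoch_data <- epoch_data$data
  }
  g <- compute_gfp(epoch_data, fs)
  peaks <- find_gfp_peaks(g, min_distance_ms)
  structure(list(maps = t(epoch_data[, peaks, drop = FALSE]),
                 peak_indices = peaks),
            class = "topography_set")
}

# Row-center and L2-normalize a maps matrix (rows = maps). Average-referenced
# maps are already row-centered; centering makes cosine equal Pearson r.
normalize_maps <- function(maps) {
  maps <- maps - rowMeans(maps)
  nrm <- sqrt(rowSums(maps^2))
  nrm[nrm < 1e-12] <- 1
  maps / nrm
}

#' Spatial correlation between two sets of maps
#'
#' Pearson correlation across channels between every row of `a` and every row
#' of `b`.
#'
#' @param a,b matrices with maps in rows and a shared channel order.
#' @return Matrix `[nrow(a) x nrow(b)]` of correlations.
#' @export
spatial_correlation <- function(a, b) {
  if (ncol(a) != ncol(b)) stop_invalid("channel counts differ")
  tcrossprod(normalize_maps(a), normalize_maps(b))
}

#' Cluster GFP-peak topographies into microstate templates
#'
#' A modified k-means over maps: each map is assigned to the template with the
#' highest spatial correlation — in the default polarity-invariant mode the
#' absolute correlation, so a map and its sign-flip are one state — and each
#' template is re-estimated from its assigned maps (first principal direction
#' in invariant mode; normalized mean in sensitive mode). The best of
#' `n_restarts` seeded initializations by explained variance is returned.
#' Templates are relabelled A, B, C, ... by the time of their first assigned
#' peak, so labels are reproducible.
#'
#' @param ts a [gfp_peak_maps()] topography set, or a plain matrix with maps
#'   in rows.
#' @param q number of templates (>= 2, <= number of maps).
#' @param polarity `"invariant"` (default, standard microstate practice) or
#'   `"sensitive"` (signed correlation).
#' @param n_restarts random restarts (default 10).
#' @param seed integer seed for reproducibility.
#' @param max_iter assignment/update iterations per restart.
#' @return Object of class `microstate_model`: unit-norm `templates`
#'   (`q x n_channels`), `labels`, `polarity`, explained variance `ev`,
#'   per-map `assignment`, and `cv_score` (predictive residual criterion).
#' @export
cluster_maps <- function(ts, q, polarity = c("invariant", "sensitive"),
                         n_restarts = 10, seed = NULL, max_iter = 50) {
  polarity <- match.arg(polarity)
  maps <- if (inherits(ts, "topography_set")) ts$maps else ts
  check_matrix(maps, "maps")
  n <- nrow(maps); k <- ncol(maps)
  if (q < 1) stop_invalid("`q` must be >= 1")
  if (q > n) stop_invalid("q = %d exceeds the %d available maps", q, n)
  v <- normalize_maps(maps)
  vc <- maps - rowMeans(maps)          # centered, unnormalized
  tot_ss <- sum(vc^2)
  run_once <- function() {
    templ <- v[sample.int(n, q), , drop = FALSE]
    lab <- integer(n)
    for (it in seq_len(max_iter)) {
      s <- tcrossprod(v, templ)                    # n x q cosines
      score <- if (polarity == "invariant") abs(s) else s
      new_lab <- max.col(score, ties.method = "first")
      if (identical(new_lab, lab)) break
      lab <- new_lab
      for (j in seq_len(q)) {
        rows <- which(lab == j)
        if (!length(rows)) {        # reseed empty cluster with worst-fit map
          worst <- which.min(apply(score, 1, max))
          templ[j, ] <- v[worst, ]
          next
        }
        if (polarity == "invariant") {
          m <- crossprod(v[rows, , drop = FALSE])
          templ[j, ] <- eigen(m, symmetric = TRUE)$vectors[, 1]
        } else {
          mu <- colMeans(v[rows, , drop = FALSE])
          templ[j, ] <- mu / max(sqrt(sum(mu^2)), 1e-12)
        }
      }
    }
    s <- tcrossprod(vc, templ)
    score <- if (polarity == "invariant") abs(s) else s
    lab <- max.col(score, ties.method = "first")
    fit <- s[cbind(seq_len(n), lab)]
    list(templ = templ, lab = lab, ev = sum(fit^2) / tot_ss)
  }
  best <- with_seed(seed, {
    res <- lapply(seq_len(n_restarts), function(i) run_once())
    res[[which.max(vapply(res, `[[`, 0, "ev"))]]
  })
  # order templates by first occurrence (first assigned map index)
  first_seen <- vapply(seq_len(q), function(j) {
    w <- which(best$lab == j)
    if (length(w)) min(w) else n + j
  }, 1L)
  ord <- order(first_seen)
  templ <- best$templ[ord, , drop = FALSE]
  lab <- match(best$lab, ord)
  # degenerate duplicate clusters (near-identical templates) are flagged
  if (q > 1) {
    ct <- abs(tcrossprod(normalize_maps(templ)))
    if (max(ct[upper.tri(ct)]) > 0.999) {
      rlang::warn("degenerate clustering: near-duplicate templates")
    }
  }
  resid <- sum(vc^2) - sum((tcrossprod(vc, templ)[cbind(seq_len(n), lab)])^2)
  sigma2 <- resid / (n * (k - 1))
  cv <- if (k - 1 - q > 0) sigma2 * ((k - 1) / (k - 1 - q))^2 else NA_real_
  structure(
    list(templates = templ, q = q, labels = LETTERS[seq_len(q)],
         polarity = polarity, ev = best$ev, assignment = lab,
         sigma2 = sigma2, cv_score = cv, n_maps = n),
    class = "microstate_model"
  )
}

#' @export
print.microstate_model <- function(x, ...) {
  cat(sprintf(
    "<microstate_model> q = %d (%s), polarity-%s, EV = %.3f, CV = %.4g\n",
    x$q, paste(x$labels, collapse = ""), x$polarity, x$ev, x$cv_score
  ))
  invisible(x)
}

#' Choose the number of microstate templates by a predictive residual criterion
#'
#' Fits [cluster_maps()] for every `q` in `q_range` and scores each fit with
#' the cross-validation criterion
#' `CV(q) = sigma2_q * ((k - 1) / (k - 1 - q))^2`, where `sigma2_q` is the
#' mean residual variance of the peak maps around their assigned template and
#' `k` the channel count. The model minimizing CV is returned, with the whole
#' CV curve attached. A nearly flat curve (relative range below 2%) triggers
#' a low-confidence warning, as happens on structureless maps.
#'
#' @inheritParams cluster_maps
#' @param q_range integer candidates, each in `[2, min(n_maps, k - 2)]`.
#' @return The selected `microstate_model`, with a `cv_curve` tibble
#'   (`q`, `cv`) attached.
#' @export
select_optimal_q <- function(ts, q_range = 2:6,
                             polarity = c("invariant", "sensitive"),
                             n_restarts = 10, seed = NULL) {
  polarity <- match.arg(polarity)
  maps <- if (inherits(ts, "topography_set")) ts$maps else ts
  q_range <- sort(unique(as.integer(q_range)))
  if (!length(q_range)) stop_invalid("`q_range` is empty")
  q_max <- min(nrow(maps), ncol(maps) - 2L)
  q_range <- q_range[q_range >= 2 & q_range <= q_max]
  if (!length(q_range)) {
    stop_invalid("no admissible q: need 2 <= q <= %d", q_max)
  }
  fits <- lapply(seq_along(q_range), function(i) {
    cluster_maps(maps, q_range[i], polarity = polarity,
                 n_restarts = n_restarts,
                 seed = if (is.null(seed)) NULL else derive_seed(seed, i))
  })
  cvs <- vapply(fits, `[[`, 0, "cv_score")
  best <- fits[[which.min(cvs)]]
  # structureless maps (e.g. pure noise) leave little variance explained at
  # any q and a near-flat/boundary-minimized criterion: flag the selection
  flat <- length(cvs) > 1 &&
    diff(range(cvs)) / max(min(cvs), 1e-12) < 0.10
  if (flat || best$ev < 0.5) {
    rlang::warn(sprintf(
      "q selection is low-confidence (EV = %.2f%s)", best$ev,
      if (flat) ", CV criterion nearly flat" else ""))
  }
  best$cv_curve <- tibble::tibble(q = q_range, cv = cvs)
  best
}

#' Backfit microstate templates onto an epoch
#'
#' Each GFP peak is labeled by the template with which its topography
#' correlates best (absolute correlation in polarity-invariant mode; ties go
#' to the lower template index). Sample labels are then filled by extending
#' each peak's label from the midpoint to the previous peak to the midpoint
#' to the next peak; epoch edges belong to the nearest peak.
#'
#' @param epoch_data matrix `[n_channels x n_samples]` or an [eeg_epoch()].
#' @param g the epoch's [compute_gfp()] curve (recomputed if `NULL`).
#' @param model a [cluster_maps()] model with matching channel count.
#' @param min_distance_ms peak pruning distance.
#' @return Object of class `ms_segmentation`: `sample_labels` (integer per
#'   sample), `peak_labels`, `peak_indices`, `fs`.
#' @export
backfit <- function(epoch_data, g = NULL, model, min_distance_ms = 10) {
  if (inherits(epoch_data, "eeg_epoch")) {
    if (is.null(g)) g <- compute_gfp(epoch_data)
    epoch_data <- epoch_data$data
  }
  stopifnot(inherits(model, "microstate_model"))
  if (nrow(epoch_data) != ncol(model$templates)) {
    stop_invalid("epoch channels (%d) do not match model channels (%d)",
                 nrow(epoch_data), ncol(model$templates))
  }
  if (is.null(g)) stop_invalid("supply the GFP curve or an eeg_epoch")
  peaks <- find_gfp_peaks(g, min_distance_ms)
  if (!length(peaks)) {
    rlang::abort("no GFP peaks: segmentation undefined",
                 class = "gripnet_invalid_input")
  }
  pk_maps <- t(epoch_data[, peaks, drop = FALSE])
  s <- spatial_correlation(pk_maps, model$templates)
  if (model$polarity == "invariant") s <- abs(s)
  peak_labels <- max.col(s, ties.method = "first")
  n <- length(g$values)
  m <- length(peaks)
  cuts <- if (m > 1) floor((peaks[-m] + peaks[-1]) / 2) else integer(0)
  bounds <- c(0L, as.integer(cuts), n)
  sample_labels <- integer(n)
  for (i in seq_len(m)) {
    sample_labels[(bounds[i] + 1L):bounds[i + 1L]] <- peak_labels[i]
  }
  structure(list(sample_labels = sample_labels, peak_labels = peak_labels,
                 peak_indices = peaks, fs = g$fs, q = model$q,
                 labels = model$labels),
            class = "ms_segmentation")
}

#' @export
print.ms_segmentation <- function(x, ...) {
  cat(sprintf("<ms_segmentation> %d samples, %d peaks, %d states\n",
              length(x$sample_labels), length(x$peak_indices), x$q))
  invisible(x)
}

#' The four microstate parameters of a segmentation
#'
#' Per template: *duration* — mean length of its contiguous runs (ms);
#' *occurrence* — number of runs per second; *coverage* — fraction of samples
#' it labels; *amplitude* — mean GFP over those samples. Templates that never
#' occur get all-zero rows. When every sample is assigned, coverages sum
#' to 1.
#'
#' @param seg a [backfit()] segmentation.
#' @param g the matching GFP curve.
#' @param model the microstate model (for labels); optional.
#' @return Tibble with columns `template`, `duration_ms`, `occurrence_hz`,
#'   `coverage`, `amplitude_uv`.
#' @export
compute_params <- function(seg, g, model = NULL) {
  stopifnot(inherits(seg, "ms_segmentation"), inherits(g, "gfp_curve"))
  n <- length(seg$sample_labels)
  if (n != length(g$values)) stop_invalid("segmentation and GFP lengths differ")
  fs <- seg$fs
  total_s <- n / fs
  runs <- label_runs(seg$sample_labels)
  q <- seg$q
  out <- tibble::tibble(
    template = seg$labels %||% LETTERS[seq_len(q)],
    duration_ms = 0, occurrence_hz = 0, coverage = 0, amplitude_uv = 0
  )
  for (j in seq_len(q)) {
    rj <- runs[runs$label == j, ]
    if (!nrow(rj)) next
    sel <- seg$sample_labels == j
    out$duration_ms[j] <- mean(rj$length) / fs * 1000
    out$occurrence_hz[j] <- nrow(rj) / total_s
    out$coverage[j] <- sum(sel) / n
    out$amplitude_uv[j] <- mean(g$values[sel])
  }
  out
}

#' Default template-matching correlation threshold per task
#'
#' Trial maps count as matched to a typical map when their spatial
#' correlation exceeds 0.55 for the force task and 0.45 for the speed task.
#'
#' @param task `"force"` or `"speed"`.
#' @return The threshold.
#' @export
match_threshold <- function(task) {
  switch(task, force = 0.55, speed = 0.45,
         stop_invalid("unknown task %s", task))
}

#' Match trial templates to typical templates and collect their parameters
#'
#' For each typical template the best-correlated trial template with
#' `r > threshold` is matched, greedily by descending correlation with each
#' trial template used at most once. Matched typical templates take the trial
#' template's microstate parameters; unmatched ones contribute zeros.
#'
#' @param trial_model the single trial's [cluster_maps()] model.
#' @param trial_params the trial's [compute_params()] tibble (rows aligned
#'   with `trial_model$templates`).
#' @param typical the typical (reference) `microstate_model`, same channel
#'   order.
#' @param threshold correlation threshold; see [match_threshold()].
#' @return Tibble with one row per typical template: `template`, `matched`
#'   (trial template label or `NA`), `r`, and the four parameters.
#' @export
match_templates <- function(trial_model, trial_params, typical,
                            threshold = 0.55) {
  stopifnot(inherits(trial_model, "microstate_model"),
            inherits(typical, "microstate_model"))
  if (ncol(trial_model$templates) != ncol(typical$templates)) {
    stop_invalid("channel order mismatch between trial and typical models")
  }
  r <- spatial_correlation(typical$templates, trial_model$templates)
  if (typical$polarity == "invariant") r <- abs(r)
  qt <- nrow(typical$templates); qr <- nrow(trial_model$templates)
  out <- tibble::tibble(
    template = typical$labels, matched = NA_character_, r = NA_real_,
    duration_ms = 0, occurrence_hz = 0, coverage = 0, amplitude_uv = 0
  )
  used <- logical(qr)
  ord <- order(r, decreasing = TRUE)
  for (o in ord) {
    i <- (o - 1L) %% qt + 1L   # typical index (row)
    j <- (o - 1L) %/% qt + 1L  # trial index (column)
    if (r[i, j] <= threshold) break
    if (!is.na(out$matched[i]) || used[j]) next
    out$matched[i] <- trial_model$labels[j]
    out$r[i] <- r[i, j]
    out[i, c("duration_ms", "occurrence_hz", "coverage", "amplitude_uv")] <-
      trial_params[j, c("duration_ms", "occurrence_hz", "coverage",
                        "amplitude_uv")]
    used[j] <- TRUE
  }
  out
}

#' Single-trial microstate feature block
#'
#' Clusters the trial's GFP-peak maps into as many templates as the typical
#' model has, backfits, computes the four microstate parameters, and matches
#' the trial templates to the typical maps. The feature block is the matched
#' parameter table flattened to `4 * q` named values (zeros for unmatched
#' typical templates) — `3 x 4 = 12` features for the standard three-map
#' model.
#'
#' @param epoch an [eeg_epoch()].
#' @param typical the typical `microstate_model` (fit on training data).
#' @param threshold match threshold; defaults per the epoch's task, see
#'   [match_threshold()].
#' @param n_restarts restarts for the trial-level clustering.
#' @param seed integer seed.
#' @return Named numeric vector of length `4 * q_typical`.
#' @export
microstate_features <- function(epoch, typical, threshold = NULL,
                                n_restarts = 5, seed = NULL) {
  stopifnot(inherits(epoch, "eeg_epoch"))
  threshold <- threshold %||% match_threshold(epoch$task)
  g <- compute_gfp(epoch)
  ts <- gfp_peak_maps(epoch)
  tm <- cluster_maps(ts, q = min(typical$q, nrow(ts$maps)),
                     polarity = typical$polarity,
                     n_restarts = n_restarts, seed = seed)
  seg <- backfit(epoch$data, g, tm)
  par <- compute_params(seg, g, tm)
  matched <- match_templates(tm, par, typical, threshold)
  vals <- as.matrix(matched[, c("duration_ms", "occurrence_hz", "coverage",
                                "amplitude_uv")])
  out <- as.numeric(t(vals))
  names(out) <- paste0(
    "ms_", rep(matched$template, each = 4), "_",
    rep(c("duration_ms", "occurrence_hz", "coverage", "amplitude_uv"),
        times = nrow(matched))
  )
  out
}
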