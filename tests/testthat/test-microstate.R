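test_that("GFP equals the brute-force spatial standard deviation", {
  # zero-variance field
  expect_equal(compute_gfp(matrix(5, 4, 10), fs = 125)$values, rep(0, 10))
  # two channels +1/-1: mean 0, population variance 1
  expect_equal(compute_gfp(rbind(rep(1, 5), rep(-1, 5)), fs = 125)$values,
               rep(1, 5))
  # random 9-channel epoch vs a scalar-loop evaluation of the definition
  x <- withr::with_seed(7, matrix(rnorm(9 * 50), 9))
  g <- compute_gfp(x, fs = 125)
  brute <- vapply(seq_len(ncol(x)), function(t) {
    v <- x[, t]
    sqrt(sum((v - mean(v))^2) / length(v))
  }, 0)
  expect_lt(max(abs(g$values - brute)), 1e-10)
})

test_that("GFP peak finding handles periodic, monotone and tied curves", {
  fs <- 1000
  # triangle wave, period 80 ms -> one peak per period
  period <- 80
  tt <- seq_len(fs)  # 1 s in ms steps
  tri <- abs(((tt %% period) / period) - 0.5)
  g <- structure(list(values = max(tri) - tri + 1, fs = fs),
                 class = "gfp_curve")
  peaks <- find_gfp_peaks(g, min_distance_ms = 10)
  expect_equal(length(peaks), floor(length(tt) / period), tolerance = 0.1)
  # strictly increasing curve has no peaks
  g2 <- structure(list(values = seq(0, 1, length.out = 100), fs = fs),
                  class = "gfp_curve")
  expect_length(find_gfp_peaks(g2), 0L)
  # two equal adjacent maxima: the first is retained under the >= rule
  v <- c(0, 1, 1, 0, 0)
  g3 <- structure(list(values = v, fs = fs), class = "gfp_curve")
  expect_equal(find_gfp_peaks(g3, min_distance_ms = 0), 2L)
  # pruning keeps the larger of two close peaks
  v4 <- c(0, 3, 0, 5, 0)
  g4 <- structure(list(values = v4, fs = 100), class = "gfp_curve")
  expect_equal(find_gfp_peaks(g4, min_distance_ms = 50), 4L)
})

test_that("map clustering recovers generating templates up to sign and permutation", {
  tmpl <- make_templates(9, 3, seed = 2)
  maps <- withr::with_seed(3, {
    lab <- sample(1:3, 150, replace = TRUE)
    sgn <- sample(c(-1, 1), 150, replace = TRUE)
    tmpl[lab, ] * (sgn * runif(150, 0.5, 2))
  })
  m <- cluster_maps(maps, 3, seed = 9)
  r <- abs(spatial_correlation(m$templates, tmpl))
  expect_true(all(apply(r, 2, max) >= 0.999))
  # templates are unit norm
  expect_equal(rowSums(m$templates^2), rep(1, 3), tolerance = 1e-8)
  # determinism under a fixed seed
  m2 <- cluster_maps(maps, 3, seed = 9)
  expect_identical(m$templates, m2$templates)
})

test_that("q = 1 clustering matches the dominant principal direction", {
  maps <- withr::with_seed(4, {
    base <- make_templates(9, 2, seed = 5)
    outer(runif(80, 0.5, 2), base[1, ]) + matrix(rnorm(80 * 9, 0, 0.05), 80)
  })
  m <- cluster_maps(maps, 1, seed = 1)
  centered <- maps - rowMeans(maps)
  pc1 <- svd(centered)$v[, 1]
  expect_gt(abs(sum(m$templates[1, ] * pc1 / sqrt(sum(pc1^2)))), 0.999)
})

test_that("degenerate inputs are flagged and invalid q rejected", {
  maps <- matrix(rep(make_templates(9, 1, seed = 1), each = 20), 20)
  expect_warning(cluster_maps(maps, 2, seed = 1), "degenerate")
  expect_error(cluster_maps(maps, 50, seed = 1), class = "gripnet_invalid_input")
})

test_that("the predictive residual criterion recovers the generating map count", {
  hits <- vapply(1:10, function(i) {
    tmpl <- make_templates(9, 3, seed = 60 + i)
    maps <- withr::with_seed(80 + i, {
      lab <- sample(1:3, 150, replace = TRUE)
      tmpl[lab, ] * runif(150, 0.8, 1.2) + matrix(rnorm(150 * 9, 0, 0.12), 150)
    })
    select_optimal_q(maps, 2:6, seed = i, n_restarts = 5)$q
  }, 1L)
  expect_gte(mean(hits == 3L), 0.9)
  # q_range of one candidate returns that model
  tmpl <- make_templates(9, 3, seed = 1)
  maps <- tmpl[rep(1:3, 20), ] + withr::with_seed(1, matrix(rnorm(540, 0, 0.1), 60))
  expect_equal(select_optimal_q(maps, q_range = 2, seed = 1)$q, 2L)
  expect_error(select_optimal_q(maps, integer(0)), class = "gripnet_invalid_input")
  # structureless maps give a flat criterion and a low-confidence warning
  noise <- withr::with_seed(2, matrix(rnorm(200 * 9), 200))
  expect_warning(select_optimal_q(noise, 2:5, seed = 3, n_restarts = 3),
                 "low-confidence")
})

test_that("backfitting recovers a constructed label sequence and its edges", {
  tmpl <- make_templates(9, 3, seed = 11)
  fs <- 125
  lab_true <- rep(c(1L, 2L, 3L), each = 125)  # 1 s per state
  tt <- seq_len(375) / fs
  env <- sin(2 * pi * 10 * tt)
  x <- t(tmpl[lab_true, ] * (10 * env))
  g <- compute_gfp(x, fs)
  model <- structure(
    list(templates = tmpl, q = 3L, labels = c("A", "B", "C"),
         polarity = "invariant", ev = 1, cv_score = 0),
    class = "microstate_model")
  seg <- backfit(x, g, model)
  agreement <- mean(seg$sample_labels == lab_true)
  expect_gt(agreement, 0.97)
  expect_true(all(seg$peak_labels == lab_true[seg$peak_indices]))
  # labels are piecewise constant between boundaries
  expect_lte(length(rle(seg$sample_labels)$lengths), 5L)
})

test_that("single-peak and tied-correlation backfits follow documented rules", {
  tmpl <- make_templates(9, 2, seed = 12)
  model <- structure(
    list(templates = tmpl, q = 2L, labels = c("A", "B"),
         polarity = "invariant", ev = 1, cv_score = 0),
    class = "microstate_model")
  # single GFP peak: whole epoch takes its label
  x <- t(tmpl[rep(1L, 51), ] * c(seq(0.1, 5, length.out = 26),
                                 seq(4.9, 0.3, length.out = 25)))
  g <- compute_gfp(x, 125)
  seg <- backfit(x, g, model)
  expect_equal(unique(seg$sample_labels), 1L)
  # a map equidistant to both templates goes to the lower index
  mix <- (tmpl[1, ] + tmpl[2, ]) / sqrt(2)
  xm <- t(rbind(mix, mix, mix) * c(1, 3, 1))
  gm <- compute_gfp(xm, 125)
  segm <- backfit(xm, gm, model)
  expect_equal(segm$peak_labels, 1L)
  # flat curve: no peaks, segmentation undefined
  flat <- matrix(1, 9, 20) * rep(1, 20)
  expect_error(backfit(flat, compute_gfp(flat, 125), model),
               class = "gripnet_invalid_input")
})

test_that("microstate parameters follow their definitions on constructed runs", {
  fs <- 125
  lab <- rep(c(1L, 2L, 3L), each = 125)
  seg <- structure(list(sample_labels = lab, peak_labels = c(1L, 2L, 3L),
                        peak_indices = c(60L, 180L, 300L), fs = fs, q = 3L,
                        labels = c("A", "B", "C")),
                   class = "ms_segmentation")
  g <- structure(list(values = rep(c(2, 4, 6), each = 125), fs = fs),
                 class = "gfp_curve")
  par <- compute_params(seg, g)
  expect_equal(par$coverage, rep(1 / 3, 3))
  expect_equal(par$occurrence_hz, rep(1 / 3, 3))
  expect_equal(par$duration_ms, rep(1000, 3))
  expect_equal(par$amplitude_uv, c(2, 4, 6))
  # 6 runs of A within 3 s -> occurrence 2 per second
  lab6 <- c(rep(rep(c(1L, 2L), times = 6), each = 31L), rep(2L, 3))
  seg6 <- structure(list(sample_labels = lab6, peak_labels = 1L,
                         peak_indices = 10L, fs = fs, q = 2L,
                         labels = c("A", "B")),
                    class = "ms_segmentation")
  par6 <- compute_params(seg6, structure(list(values = rep(1, 375), fs = fs),
                                         class = "gfp_curve"))
  expect_equal(par6$occurrence_hz[1], 6 / 3)
  # partition property on a random segmentation
  labr <- withr::with_seed(5, sample(1:3, 375, replace = TRUE))
  segr <- structure(list(sample_labels = labr, peak_labels = 1L,
                         peak_indices = 10L, fs = fs, q = 3L,
                         labels = c("A", "B", "C")),
                    class = "ms_segmentation")
  parr <- compute_params(segr, structure(list(values = runif(375), fs = fs),
                                         class = "gfp_curve"))
  expect_equal(sum(parr$coverage), 1, tolerance = 1e-9)
  # duration * occurrence ~ coverage (within one sample per run)
  expect_equal(parr$duration_ms / 1000 * parr$occurrence_hz, parr$coverage,
               tolerance = 0.02)
})

test_that("template matching is thresholded, greedy and unique", {
  tmpl <- make_templates(9, 3, seed = 21)
  typical <- structure(
    list(templates = tmpl, q = 3L, labels = c("A", "B", "C"),
         polarity = "invariant", ev = 1, cv_score = 0),
    class = "microstate_model")
  params <- tibble::tibble(template = c("A", "B", "C"),
                           duration_ms = c(100, 120, 140),
                           occurrence_hz = c(3, 2, 1),
                           coverage = c(0.3, 0.3, 0.4),
                           amplitude_uv = c(2, 3, 4))
  # identical trial templates match perfectly and carry their parameters
  out <- match_templates(typical, params, typical, threshold = 0.55)
  expect_equal(out$r, rep(1, 3))
  expect_equal(out$duration_ms, params$duration_ms)
  expect_equal(out$matched, c("A", "B", "C"))
  # orthogonal trial templates: nothing crosses the threshold, zero block
  other <- typical
  other$templates <- make_templates(9, 3, seed = 22)
  # orthogonalize against the typical maps to force near-zero correlations
  proj <- other$templates %*% t(tmpl) %*% tmpl
  other$templates <- normalize_rows <- {
    m <- other$templates - proj
    m / sqrt(rowSums(m^2))
  }
  out2 <- match_templates(other, params, typical, threshold = 0.55)
  expect_true(all(is.na(out2$matched)))
  expect_equal(out2$duration_ms, rep(0, 3))
  # task-specific default thresholds
  expect_equal(match_threshold("force"), 0.55)
  expect_equal(match_threshold("speed"), 0.45)
  # channel mismatch rejected
  small <- typical
  small$templates <- typical$templates[, 1:5]
  expect_error(match_templates(small, params, typical),
               class = "gripnet_invalid_input")
})
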