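#' Default pipeline configuration
#'
#' Nested list mirroring the YAML schema: `seed`, `synth` (generator layout
#' and condition), `preprocess` (band limits, pipeline rate, artifact
#' threshold), `features` (blocks and their knobs), `classify` (protocol,
#' classifiers, permutations), `output` (directory or `NULL`).
#'
#' @return Named list.
#' @export
default_pipeline_config <- function() {
  list(
    seed = 1L,
    synth = list(n_subjects = 20L, n_sessions = 3L, trials_per_class = 10L,
                 task = "force", mode = "actual", snr = 5, mvar_scale = 2.2),
    preprocess = list(target_fs = 125, hp_hz = 0.05, lp_hz = 48,
                      peak_uv = 100),
    features = list(blocks = c("microstate", "network", "energy", "ar",
                               "wavelet"),
                    q = 3L, density = 0.3, mvar_order = 8L, ar_order = 10L),
    classify = list(protocol = "loso", classifiers = c("elm", "svm"),
                    n_hidden = 200L, n_perm = 0L),
    output = list(dir = NULL)
  )
}

# Schema: leaf validators keyed exactly like the config; unknown keys are
# rejected before any stage runs.
config_schema <- function() {
  num1 <- function(lo = -Inf, hi = Inf) function(x) {
    is.numeric(x) && length(x) == 1 && x >= lo && x <= hi
  }
  chr1 <- function(...) {
    allowed <- c(...)
    function(x) is.character(x) && length(x) == 1 &&
      (!length(allowed) || x %in% allowed)
  }
  list(
    seed = num1(0, 2^31 - 1),
    synth = list(n_subjects = num1(1), n_sessions = num1(1),
                 trials_per_class = num1(1),
                 task = chr1("force", "speed"),
                 mode = chr1("actual", "imagined"),
                 snr = num1(0.1), mvar_scale = num1(0)),
    preprocess = list(target_fs = num1(1), hp_hz = num1(0), lp_hz = num1(1),
                      peak_uv = function(x) is.null(x) || num1(1)(x)),
    features = list(
      blocks = function(x) is.character(x) &&
        all(x %in% feature_block_order()),
      q = num1(2, 8), density = num1(0.01, 1), mvar_order = num1(1, 30),
      ar_order = num1(1, 30)),
    classify = list(protocol = chr1("loso", "per_subject"),
                    classifiers = function(x) is.character(x) &&
                      all(x %in% c("elm", "svm", "lda")),
                    n_hidden = num1(1), n_perm = num1(0)),
    output = list(dir = function(x) is.null(x) || chr1()(x))
  )
}

validate_node <- function(cfg, schema, path = "") {
  unknown <- setdiff(names(cfg), names(schema))
  if (length(unknown)) {
    stop_invalid("unknown config key(s): %s",
                 paste0(path, unknown, collapse = ", "))
  }
  for (k in names(cfg)) {
    if (is.list(schema[[k]]) && !is.function(schema[[k]])) {
      if (!is.list(cfg[[k]])) stop_invalid("config key %s%s must be a section",
                                           path, k)
      validate_node(cfg[[k]], schema[[k]], paste0(path, k, "."))
    } else if (!isTRUE(schema[[k]](cfg[[k]]))) {
      stop_invalid("invalid value for config key %s%s", path, k)
    }
  }
  invisible(TRUE)
}

#' Validate a pipeline configuration against the schema
#'
#' Missing keys are filled from [default_pipeline_config()]; unknown keys or
#' out-of-range values raise an error before any stage runs.
#'
#' @param cfg nested list (e.g. from [read_pipeline_config()]).
#' @return The completed, validated config.
#' @export
validate_pipeline_config <- function(cfg) {
  def <- default_pipeline_config()
  merge2 <- function(d, c) {
    for (k in names(c)) {
      d[[k]] <- if (is.list(d[[k]]) && is.list(c[[k]])) {
        merge2(d[[k]], c[[k]])
      } else c[[k]]
    }
    d
  }
  validate_node(cfg, config_schema())
  merge2(def, cfg)
}

#' Read a YAML pipeline configuration
#'
#' @param path YAML file.
#' @return Validated config list.
#' @export
read_pipeline_config <- function(path) {
  validate_pipeline_config(yaml::read_yaml(path))
}

# Per-trial microstate precomputation: trial-level model + parameters (label-
# free, so they can be reused across CV folds) and the trial's GFP-peak maps
# for typical-template fitting.
trial_microstate_models <- function(es, q = 3, seed = 1, n_restarts = 5) {
  lapply(seq_along(es$epochs), function(i) {
    ep <- es$epochs[[i]]
    g <- compute_gfp(ep)
    ts <- gfp_peak_maps(ep)
    m <- cluster_maps(ts, q = min(q, nrow(ts$maps)),
                      n_restarts = n_restarts, seed = derive_seed(seed, i))
    seg <- backfit(ep$data, g, m)
    list(model = m, params = compute_params(seg, g, m), maps = ts$maps)
  })
}

# Fit typical templates on the pooled GFP-peak maps of the given trials
# (training partition only, to avoid leakage), subsampled for speed.
fit_typical_maps <- function(trial_ms, idx, q = 3, seed = 1,
                             max_maps = 2000) {
  maps <- do.call(rbind, lapply(trial_ms[idx], `[[`, "maps"))
  if (nrow(maps) > max_maps) {
    keep <- with_seed(seed, sample.int(nrow(maps), max_maps))
    maps <- maps[keep, , drop = FALSE]
  }
  cluster_maps(maps, q = q, n_restarts = 5, seed = seed)
}

# 12-column microstate block for every trial against the given typical maps.
ms_feature_block <- function(trial_ms, typical, task) {
  thr <- match_threshold(task)
  t(vapply(trial_ms, function(tm) {
    out <- match_templates(tm$model, tm$params, typical, thr)
    vals <- as.matrix(out[, c("duration_ms", "occurrence_hz", "coverage",
                              "amplitude_uv")])
    as.numeric(t(vals))
  }, numeric(4 * typical$q)))
}

#' Extract the feature table for an epoch set
#'
#' Computes the label-independent feature blocks per trial. The microstate
#' block needs typical template maps: when `typical` is `NULL` and the block
#' is requested, typical maps are fit on all trials (fine for exploration;
#' the cross-validation protocols refit them per training fold via
#' [pipeline_classify()]).
#'
#' @param es an [epoch_set()].
#' @param blocks feature blocks, see [assemble_features()].
#' @param q microstate template count.
#' @param density,mvar_order,ar_order block parameters.
#' @param seed integer seed.
#' @param typical optional pre-fit typical `microstate_model`.
#' @return List: `features` (matrix `[n_trials x n_features]`), `manifest`,
#'   `trial_ms` (per-trial microstate precomputation, `NULL` unless the
#'   microstate block was requested), `typical`.
#' @export
pipeline_features <- function(es, blocks = feature_block_order(), q = 3,
                              density = 0.3, mvar_order = 8, ar_order = 10,
                              seed = 1, typical = NULL) {
  stopifnot(inherits(es, "epoch_set"))
  manifest <- epoch_manifest(es)
  base_blocks <- setdiff(blocks, "microstate")
  base <- NULL
  if (length(base_blocks)) {
    base <- do.call(rbind, lapply(es$epochs, function(ep) {
      assemble_features(ep, blocks = base_blocks, density = density,
                        mvar_order = mvar_order, ar_order = ar_order)
    }))
  }
  trial_ms <- NULL
  ms <- NULL
  if ("microstate" %in% blocks) {
    trial_ms <- trial_microstate_models(es, q = q, seed = seed)
    if (is.null(typical)) {
      typical <- fit_typical_maps(trial_ms, seq_along(trial_ms), q = q,
                                  seed = derive_seed(seed, 999L))
    }
    ms <- ms_feature_block(trial_ms, typical, es$epochs[[1]]$task)
    colnames(ms) <- paste0(
      "ms_", rep(typical$labels, each = 4), "_",
      rep(c("duration_ms", "occurrence_hz", "coverage", "amplitude_uv"),
          times = typical$q))
  }
  features <- if (is.null(base)) ms else if (is.null(ms)) base else
    cbind(ms, base)
  list(features = features, manifest = manifest, trial_ms = trial_ms,
       typical = typical, base = base)
}

#' Cross-validate a feature set with leakage-safe microstate matching
#'
#' Runs the requested protocol for one classifier. Under LOSO with a
#' microstate block, the typical template maps are refit on each training
#' fold (pooled GFP-peak maps of training trials only) and the matched
#' microstate block is rebuilt for both partitions, so no test-subject
#' information enters the features; remaining blocks are label- and
#' fold-independent. Standardization always uses training-fold statistics.
#' Under the per-subject protocol the microstate block from
#' [pipeline_features()] is used as-is: its typical maps are class-agnostic,
#' so no label information can leak, but they are not refit per session
#' fold.
#'
#' @param feat result of [pipeline_features()].
#' @param spec a [classifier()] specification.
#' @param q microstate template count.
#' @param protocol `"loso"` or `"per_subject"`.
#' @param seed integer seed.
#' @param n_perm permutations for the chance level (0 = skip).
#' @return List: `cv` (a `cv_result`), `null` (a `null_distribution` or
#'   `NULL`).
#' @export
pipeline_classify <- function(feat, spec = classifier("elm"), q = 3,
                              protocol = c("loso", "per_subject"), seed = 1,
                              n_perm = 0) {
  protocol <- match.arg(protocol)
  man <- feat$manifest
  task <- man$task[1]
  fb <- NULL
  if (!is.null(feat$trial_ms)) {
    fb <- function(train_idx, test_idx) {
      typ <- fit_typical_maps(feat$trial_ms, train_idx, q = q,
                              seed = derive_seed(seed, 77L))
      ms <- ms_feature_block(feat$trial_ms, typ, task)
      join <- function(idx) {
        if (is.null(feat$base)) ms[idx, , drop = FALSE] else
          cbind(ms[idx, , drop = FALSE], feat$base[idx, , drop = FALSE])
      }
      list(train = join(train_idx), test = join(test_idx))
    }
  }
  d <- trial_dataset(feat$features, man$level, man$subject, man$session)
  cv <- if (protocol == "loso") {
    loso_cv(d, spec, seed = seed, feature_builder = fb)
  } else {
    per_subject_cv(d, spec, seed = seed)
  }
  null <- NULL
  if (n_perm > 0) {
    null <- permutation_chance(d, spec, n_perm = n_perm,
                               seed = derive_seed(seed, 13L),
                               protocol = protocol, feature_builder = fb)
  }
  list(cv = cv, null = null)
}

#' Run the full pipeline from a validated configuration
#'
#' Generates (or loads) the dataset, extracts features, cross-validates each
#' configured classifier, optionally estimates the permutation chance level,
#' and — when an output directory is configured — writes the feature table,
#' per-fold and summary result tables, and a run log carrying the config
#' hash and seeds. Idempotent given identical config and seed.
#'
#' @param cfg config list (validated via [validate_pipeline_config()]).
#' @param epochs optional pre-built [epoch_set()] (skips the synth stage).
#' @param quiet suppress progress messages.
#' @return List: `config`, `config_hash`, `manifest`, `results` (summary
#'   tibble), `cv` (named list of `cv_result`), `null` (named list),
#'   `features` dimensions.
#' @export
run_pipeline <- function(cfg = default_pipeline_config(), epochs = NULL,
                         quiet = FALSE) {
  cfg <- validate_pipeline_config(cfg)
  hash <- config_hash(cfg)
  say <- function(...) if (!quiet) rlang::inform(sprintf(...))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      rlang::abort(sprintf("pipeline stage `%s` failed: %s", name,
                           conditionMessage(e)), parent = e)
    })
  }
  if (is.null(epochs)) {
    say("synth: generating %d subjects x %d sessions (%s/%s)",
        cfg$synth$n_subjects, cfg$synth$n_sessions, cfg$synth$task,
        cfg$synth$mode)
    epochs <- stage("synth", {
      scfg <- synth_config(
        n_subjects = cfg$synth$n_subjects, n_sessions = cfg$synth$n_sessions,
        trials_per_class = cfg$synth$trials_per_class, snr = cfg$synth$snr,
        mvar_scale = cfg$synth$mvar_scale, seed = cfg$seed)
      simulate_dataset(scfg, task = cfg$synth$task,
                       mode = cfg$synth$mode)$epochs
    })
  }
  say("features: %d trials, blocks %s", length(epochs),
      paste(cfg$features$blocks, collapse = "+"))
  feat <- stage("features", pipeline_features(
    epochs, blocks = cfg$features$blocks, q = cfg$features$q,
    density = cfg$features$density, mvar_order = cfg$features$mvar_order,
    ar_order = cfg$features$ar_order, seed = derive_seed(cfg$seed, 2L)))
  cvs <- list(); nulls <- list()
  for (clf in cfg$classify$classifiers) {
    say("classify: %s under %s", clf, cfg$classify$protocol)
    spec <- if (clf == "elm") classifier("elm",
                                         n_hidden = cfg$classify$n_hidden)
            else classifier(clf)
    out <- stage(paste0("classify-", clf), pipeline_classify(
      feat, spec, q = cfg$features$q, protocol = cfg$classify$protocol,
      seed = derive_seed(cfg$seed, 3L), n_perm = cfg$classify$n_perm))
    cvs[[clf]] <- out$cv
    nulls[[clf]] <- out$null
  }
  results <- purrr::map_dfr(names(cvs), function(clf) {
    tibble::tibble(
      task = cfg$synth$task, mode = cfg$synth$mode,
      feature_set = paste(cfg$features$blocks, collapse = "+"),
      classifier = clf, protocol = cfg$classify$protocol,
      mean_accuracy = cvs[[clf]]$mean, sd_accuracy = cvs[[clf]]$std,
      chance = if (is.null(nulls[[clf]])) NA_real_ else nulls[[clf]]$chance)
  })
  bundle <- list(config = cfg, config_hash = hash, manifest = feat$manifest,
                 results = results, cv = cvs, null = nulls,
                 feature_dim = dim(feat$features))
  if (!is.null(cfg$output$dir)) {
    stage("write", write_pipeline_outputs(bundle, feat, cfg$output$dir))
  }
  bundle
}

config_hash <- function(cfg) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(yaml::as.yaml(cfg), tmp)
  unname(tools::md5sum(tmp))
}

write_pipeline_outputs <- function(bundle, feat, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fm <- cbind(feat$manifest, as.data.frame(feat$features))
  utils::write.table(fm, file.path(dir, "features.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  utils::write.table(bundle$results, file.path(dir, "results.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  folds <- purrr::map_dfr(names(bundle$cv), function(clf) {
    dplyr::mutate(bundle$cv[[clf]]$folds, classifier = clf)
  })
  utils::write.table(folds, file.path(dir, "folds.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  if (any(!vapply(bundle$null, is.null, TRUE))) {
    chance <- purrr::map_dfr(names(bundle$null), function(clf) {
      n <- bundle$null[[clf]]
      if (is.null(n)) return(tibble::tibble())
      dplyr::mutate(tidy(n), classifier = clf)
    })
    utils::write.table(chance, file.path(dir, "chance.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
  }
  log_lines <- c(
    sprintf("gripnet %s | R %s", as.character(utils::packageVersion("gripnet")),
            paste(R.version$major, R.version$minor, sep = ".")),
    sprintf("config_hash: %s", bundle$config_hash),
    sprintf("seed: %d", bundle$config$seed),
    sprintf("timestamp: %s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
    "config:", strsplit(yaml::as.yaml(bundle$config), "\n")[[1]])
  writeLines(log_lines, file.path(dir, "run_log.txt"))
  invisible(dir)
}
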