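#' Bundle trial features and labels into a dataset
#'
#' @param features numeric matrix `[n_trials x n_features]`.
#' @param labels integer class labels (levels 1-3).
#' @param subjects,sessions grouping vectors aligned with the rows.
#' @return Object of class `trial_dataset`.
#' @export
trial_dataset <- function(features, labels, subjects, sessions = NULL) {
  features <- as.matrix(features)
  n <- nrow(features)
  if (length(labels) != n || length(subjects) != n) {
    stop_invalid("labels and subjects must align with feature rows")
  }
  if (length(unique(labels)) < 2) stop_invalid("need at least two classes")
  structure(
    list(features = features, labels = as.integer(labels),
         subjects = subjects, sessions = sessions %||% rep(1L, n)),
    class = "trial_dataset"
  )
}

#' @export
print.trial_dataset <- function(x, ...) {
  cat(sprintf("<trial_dataset> %d trials x %d features, %d subjects, %d classes\n",
              nrow(x$features), ncol(x$features), length(unique(x$subjects)),
              length(unique(x$labels))))
  invisible(x)
}

#' Describe a classifier for the cross-validation protocols
#'
#' @param method `"elm"` (extreme learning machine, implemented here),
#'   `"svm"` (RBF support vector machine via e1071) or `"lda"` (linear
#'   discriminant analysis; MASS when `n > p`, shrinkage variant otherwise).
#' @param ... hyperparameters: `n_hidden` (ELM, default 200), `lambda`
#'   (shrinkage LDA, default 0.5), others passed through.
#' @return A classifier specification.
#' @export
classifier <- function(method = c("elm", "svm", "lda"), ...) {
  method <- match.arg(method)
  structure(list(method = method, args = list(...)), class = "clf_spec")
}

#' Train an extreme learning machine
#'
#' Single-hidden-layer network with fixed random input weights: weights and
#' biases are drawn from a seeded uniform(-1, 1), hidden activations are
#' `H = sigmoid(X W + b)`, and the output weights solve the least-squares
#' problem against one-hot targets via the Moore-Penrose pseudoinverse.
#' Deterministic given the seed.
#'
#' @param x numeric feature matrix `[n x d]` (standardize beforehand).
#' @param y integer/factor class labels.
#' @param n_hidden hidden units (default 200).
#' @param seed integer seed for the random hidden layer.
#' @return Object of class `elm_model`.
#' @export
elm_train <- function(x, y, n_hidden = 200, seed = 1) {
  x <- as.matrix(x)
  if (n_hidden < 1) stop_invalid("`n_hidden` must be >= 1")
  if (nrow(unique(x)) == 1) {
    rlang::warn("degenerate training set: all feature rows identical")
  }
  classes <- sort(unique(as.integer(y)))
  target <- outer(as.integer(y), classes, `==`) * 1
  d <- ncol(x)
  wb <- with_seed(seed, {
    list(w = matrix(runif(d * n_hidden, -1, 1), d, n_hidden),
         b = runif(n_hidden, -1, 1))
  })
  h <- stats::plogis(x %*% wb$w + matrix(wb$b, nrow(x), n_hidden, byrow = TRUE))
  beta <- MASS::ginv(h) %*% target
  structure(
    list(input_weights = wb$w, biases = wb$b, output_weights = beta,
         classes = classes, activation = "sigmoid", seed = seed),
    class = "elm_model"
  )
}

#' Predict classes with a trained ELM
#'
#' Argmax over the class scores; ties resolve to the lowest class index.
#'
#' @param m an [elm_train()] model.
#' @param x feature matrix with the training dimensionality.
#' @return Integer vector of predicted class labels.
#' @export
elm_predict <- function(m, x) {
  stopifnot(inherits(m, "elm_model"))
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  if (ncol(x) != nrow(m$input_weights)) {
    stop_invalid("feature dimension %d does not match model (%d)",
                 ncol(x), nrow(m$input_weights))
  }
  storage.mode(x) <- "double"
  h <- stats::plogis(x %*% m$input_weights +
                       matrix(m$biases, nrow(x), length(m$biases), byrow = TRUE))
  scores <- h %*% m$output_weights
  m$classes[max.col(scores, ties.method = "first")]
}

# Shrinkage LDA for the n < p regime: pooled covariance shrunk toward its
# average diagonal, Sigma_l = (1 - l) S + l * mean(diag(S)) I.
lda_shrink_train <- function(x, y, lambda = 0.5) {
  classes <- sort(unique(as.integer(y)))
  mu <- t(vapply(classes, function(c) colMeans(x[y == c, , drop = FALSE]),
                 numeric(ncol(x))))
  centered <- x - mu[match(as.integer(y), classes), , drop = FALSE]
  s <- crossprod(centered) / max(nrow(x) - length(classes), 1)
  shr <- (1 - lambda) * s
  diag(shr) <- diag(shr) + lambda * mean(diag(s))
  w <- solve(shr, t(mu))                       # d x C
  const <- -0.5 * colSums(t(mu) * w) +
    log(tabulate(match(y, classes)) / length(y))
  list(w = w, const = const, classes = classes)
}

lda_shrink_predict <- function(m, x) {
  scores <- x %*% m$w + matrix(m$const, nrow(x), length(m$const), byrow = TRUE)
  m$classes[max.col(scores, ties.method = "first")]
}

# Fit/predict under a common contract for the three classifier families.
fit_classifier <- function(spec, x, y, seed = 1) {
  stopifnot(inherits(spec, "clf_spec"))
  a <- spec$args
  model <- switch(
    spec$method,
    elm = elm_train(x, y, n_hidden = a$n_hidden %||% 200,
                    seed = a$seed %||% seed),
    svm = {
      if (!requireNamespace("e1071", quietly = TRUE)) {
        stop_invalid("the svm classifier needs the e1071 package")
      }
      e1071::svm(x, factor(y), kernel = "radial", scale = FALSE)
    },
    lda = {
      if (nrow(x) > 2 * ncol(x)) {
        MASS::lda(x, grouping = factor(y))
      } else {
        lda_shrink_train(x, y, lambda = a$lambda %||% 0.5)
      }
    }
  )
  structure(list(spec = spec, model = model), class = "gripnet_clf")
}

predict_classifier <- function(fit, x) {
  m <- fit$model
  switch(
    fit$spec$method,
    elm = elm_predict(m, x),
    svm = as.integer(as.character(predict(m, x))),
    lda = if (inherits(m, "lda")) {
      as.integer(as.character(predict(m, x)$class))
    } else {
      lda_shrink_predict(m, x)
    }
  )
}

# Run one train/test fold: standardize on training statistics only.
run_fold <- function(spec, x_train, y_train, x_test, y_test, seed = 1) {
  if (length(unique(y_train)) < 2) {
    stop_invalid("a training fold contains a single class")
  }
  std <- standardizer(x_train)
  fit <- fit_classifier(spec, std$apply(x_train), y_train, seed = seed)
  pred <- predict_classifier(fit, std$apply(x_test))
  mean(pred == y_test)
}

new_cv_result <- function(folds, protocol) {
  structure(
    list(folds = folds, fold_accuracies = folds$accuracy,
         mean = mean(folds$accuracy), std = stats::sd(folds$accuracy),
         protocol = protocol),
    class = "cv_result"
  )
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> %s: accuracy %.3f +/- %.3f over %d folds\n",
              x$protocol, x$mean, x$std, nrow(x$folds)))
  invisible(x)
}

#' Leave-one-subject-out cross-validation
#'
#' One fold per subject: the held-out subject's trials are the test set, all
#' other subjects' trials the training set. Features are standardized with
#' training-fold statistics only. With the standard design (20 subjects x 90
#' trials) every fold trains on 1710 trials and tests on 90.
#'
#' @param d a [trial_dataset()].
#' @param spec a [classifier()] specification.
#' @param seed integer seed (per-fold classifier randomness).
#' @param feature_builder optional `function(train_idx, test_idx)` returning
#'   `list(train =, test =)` feature matrices built from training information
#'   only (e.g. fold-specific microstate matching); defaults to slicing
#'   `d$features`.
#' @return A `cv_result`: per-fold tibble (`fold`, `subject`, `n_train`,
#'   `n_test`, `accuracy`), mean and standard deviation.
#' @export
loso_cv <- function(d, spec = classifier("elm"), seed = 1,
                    feature_builder = NULL) {
  stopifnot(inherits(d, "trial_dataset"))
  subjects <- unique(d$subjects)
  if (length(subjects) < 2) stop_invalid("LOSO needs at least 2 subjects")
  folds <- purrr::map_dfr(seq_along(subjects), function(i) {
    test_idx <- which(d$subjects == subjects[i])
    train_idx <- which(d$subjects != subjects[i])
    xs <- if (is.null(feature_builder)) {
      list(train = d$features[train_idx, , drop = FALSE],
           test = d$features[test_idx, , drop = FALSE])
    } else {
      feature_builder(train_idx, test_idx)
    }
    acc <- run_fold(spec, xs$train, d$labels[train_idx],
                    xs$test, d$labels[test_idx],
                    seed = derive_seed(seed, i))
    tibble::tibble(fold = i, subject = subjects[i],
                   n_train = length(train_idx), n_test = length(test_idx),
                   accuracy = acc)
  })
  new_cv_result(folds, "leave-one-subject-out")
}

#' Per-subject session-rotation cross-validation
#'
#' For each subject with at least two sessions, each session in turn is held
#' out for testing while the remaining sessions train a subject-specific
#' classifier (two train / one test in the standard three-session design).
#' Subjects with fewer than two sessions are skipped with a warning.
#'
#' @inheritParams loso_cv
#' @return A `cv_result` whose fold tibble has one row per
#'   (subject, held-out session); `per_subject` accuracy summary attached.
#' @export
per_subject_cv <- function(d, spec = classifier("elm"), seed = 1) {
  stopifnot(inherits(d, "trial_dataset"))
  folds <- list()
  k <- 0L
  for (s in unique(d$subjects)) {
    rows <- which(d$subjects == s)
    sess <- unique(d$sessions[rows])
    if (length(sess) < 2) {
      rlang::warn(sprintf("subject %s has < 2 sessions; skipped", s))
      next
    }
    for (holdout in sess) {
      k <- k + 1L
      test_idx <- rows[d$sessions[rows] == holdout]
      train_idx <- rows[d$sessions[rows] != holdout]
      acc <- run_fold(spec, d$features[train_idx, , drop = FALSE],
                      d$labels[train_idx],
                      d$features[test_idx, , drop = FALSE],
                      d$labels[test_idx], seed = derive_seed(seed, k))
      folds[[k]] <- tibble::tibble(
        fold = k, subject = s, session = holdout,
        n_train = length(train_idx), n_test = length(test_idx),
        accuracy = acc)
    }
  }
  if (!k) stop_invalid("no subject has two or more sessions")
  res <- new_cv_result(dplyr::bind_rows(folds), "per-subject-session")
  res$per_subject <- res$folds %>%
    dplyr::group_by(.data$subject) %>%
    dplyr::summarise(accuracy = mean(.data$accuracy), .groups = "drop")
  res
}

#' Permutation-test chance level for a cross-validation protocol
#'
#' Re-runs the cross-validation with class labels permuted within subject
#' (respecting the grouping) `n_perm` times; the chance level is the mean
#' permuted accuracy, and the permuted accuracies form the null
#' distribution. For balanced three-class labels the chance level
#' concentrates near 1/3.
#'
#' For the ELM under LOSO the per-fold hidden activations and their
#' pseudoinverse are label-independent, so they are computed once and only
#' the least-squares output weights are refit per permutation — numerically
#' identical to a full refit with the fold's hidden layer held fixed, and
#' orders of magnitude faster on wide feature sets.
#'
#' @inheritParams loso_cv
#' @param n_perm number of permutations (default 200).
#' @param protocol `"loso"` or `"per_subject"`.
#' @return Object of class `null_distribution`: `accuracies`, `chance`
#'   (mean), `q95` (95th percentile), `n_perm`, `seed`.
#' @export
permutation_chance <- function(d, spec = classifier("elm"), n_perm = 200,
                               seed = 1, protocol = c("loso", "per_subject"),
                               feature_builder = NULL) {
  stopifnot(inherits(d, "trial_dataset"))
  protocol <- match.arg(protocol)
  if (n_perm < 1) stop_invalid("`n_perm` must be >= 1")
  subj_rows <- split(seq_along(d$subjects), d$subjects)
  if (protocol == "loso" && spec$method == "elm") {
    # precompute label-independent fold state: standardized hidden
    # activations and their pseudoinverse
    subjects <- unique(d$subjects)
    n_hidden <- spec$args$n_hidden %||% 200
    folds <- lapply(seq_along(subjects), function(i) {
      test_idx <- which(d$subjects == subjects[i])
      train_idx <- which(d$subjects != subjects[i])
      xs <- if (is.null(feature_builder)) {
        list(train = d$features[train_idx, , drop = FALSE],
             test = d$features[test_idx, , drop = FALSE])
      } else feature_builder(train_idx, test_idx)
      std <- standardizer(xs$train)
      xtr <- std$apply(xs$train); xte <- std$apply(xs$test)
      wb <- with_seed(derive_seed(seed, i), {
        list(w = matrix(runif(ncol(xtr) * n_hidden, -1, 1), ncol(xtr)),
             b = runif(n_hidden, -1, 1))
      })
      htr <- stats::plogis(xtr %*% wb$w +
                             matrix(wb$b, nrow(xtr), n_hidden, byrow = TRUE))
      hte <- stats::plogis(xte %*% wb$w +
                             matrix(wb$b, nrow(xte), n_hidden, byrow = TRUE))
      list(pinv = MASS::ginv(htr), hte = hte, train_idx = train_idx,
           test_idx = test_idx)
    })
    classes <- sort(unique(d$labels))
    accs <- with_seed(seed, vapply(seq_len(n_perm), function(b) {
      perm <- d$labels
      for (rows in subj_rows) perm[rows] <- sample(d$labels[rows])
      mean(vapply(folds, function(f) {
        target <- outer(perm[f$train_idx], classes, `==`) * 1
        beta <- f$pinv %*% target
        pred <- classes[max.col(f$hte %*% beta, ties.method = "first")]
        mean(pred == perm[f$test_idx])
      }, 0))
    }, 0))
  } else {
    # fold features do not depend on labels, so build them once
    cache <- NULL
    if (protocol == "loso" && !is.null(feature_builder)) {
      subjects <- unique(d$subjects)
      cache <- lapply(seq_along(subjects), function(i) {
        feature_builder(which(d$subjects != subjects[i]),
                        which(d$subjects == subjects[i]))
      })
      feature_builder_cached <- local({
        subjects <- subjects
        function(train_idx, test_idx) {
          i <- which(vapply(subjects, function(s)
            all(d$subjects[test_idx] == s), TRUE))[1]
          cache[[i]]
        }
      })
    }
    accs <- with_seed(seed, vapply(seq_len(n_perm), function(b) {
      dp <- d
      for (rows in subj_rows) dp$labels[rows] <- sample(d$labels[rows])
      res <- if (protocol == "loso") {
        loso_cv(dp, spec, seed = derive_seed(seed, b),
                feature_builder = if (is.null(cache)) NULL else
                  feature_builder_cached)
      } else {
        suppressWarnings(per_subject_cv(dp, spec, seed = derive_seed(seed, b)))
      }
      res$mean
    }, 0))
  }
  structure(
    list(accuracies = accs, chance = mean(accs),
         q95 = as.numeric(stats::quantile(accs, 0.95, type = 7)),
         n_perm = n_perm, seed = seed, protocol = protocol),
    class = "null_distribution"
  )
}

#' @export
print.null_distribution <- function(x, ...) {
  cat(sprintf(
    "<null_distribution> %s, %d permutations: chance %.3f (95th pct %.3f)\n",
    x$protocol, x$n_perm, x$chance, x$q95))
  invisible(x)
}
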