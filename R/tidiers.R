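# broom-style tidiers for the fitted/result objects.

#' Tidy a microstate model into template loadings
#'
#' @param x a `microstate_model`.
#' @param ... unused.
#' @return Long tibble: `template`, `channel`, `loading`.
#' @export
tidy.microstate_model <- function(x, ...) {
  tibble::tibble(
    template = rep(x$labels, each = ncol(x$templates)),
    channel = rep(seq_len(ncol(x$templates)), times = x$q),
    loading = as.numeric(t(x$templates))
  )
}

#' One-row summary of a microstate model
#'
#' @param x a `microstate_model`.
#' @param ... unused.
#' @return Tibble with `q`, `polarity`, `ev`, `cv_score`, `n_maps`.
#' @export
glance.microstate_model <- function(x, ...) {
  tibble::tibble(q = x$q, polarity = x$polarity, ev = x$ev,
                 cv_score = x$cv_score, n_maps = x$n_maps)
}

#' Tidy MVAR coefficients into long form
#'
#' @param x an `mvar_model`.
#' @param ... unused.
#' @return Tibble: `lag`, `to`, `from`, `coefficient`.
#' @export
tidy.mvar_model <- function(x, ...) {
  purrr::map_dfr(seq_along(x$coeffs), function(l) {
    co <- x$coeffs[[l]]
    tibble::tibble(lag = l,
                   to = rep(seq_len(nrow(co)), times = ncol(co)),
                   from = rep(seq_len(ncol(co)), each = nrow(co)),
                   coefficient = as.numeric(co))
  })
}

#' One-row summary of an MVAR fit
#'
#' @param x an `mvar_model`.
#' @param ... unused.
#' @return Tibble with `order`, `aic`, `spectral_radius`, `stable`.
#' @export
glance.mvar_model <- function(x, ...) {
  tibble::tibble(order = x$order, aic = as.numeric(x$aic),
                 spectral_radius = x$spectral_radius, stable = x$stable)
}

#' Tidy band connectivity into long form
#'
#' @param x a `band_connectivity`.
#' @param ... unused.
#' @return Tibble: `band`, `to`, `from`, `pdc`.
#' @export
tidy.band_connectivity <- function(x, ...) {
  purrr::map_dfr(names(x$matrices), function(b) {
    m <- x$matrices[[b]]
    tibble::tibble(band = b,
                   to = rep(seq_len(nrow(m)), times = ncol(m)),
                   from = rep(seq_len(ncol(m)), each = nrow(m)),
                   pdc = as.numeric(m))
  })
}

#' Tidy cross-validation folds
#'
#' @param x a `cv_result`.
#' @param ... unused.
#' @return The per-fold tibble.
#' @export
tidy.cv_result <- function(x, ...) x$folds

#' One-row cross-validation summary
#'
#' @param x a `cv_result`.
#' @param ... unused.
#' @return Tibble with `protocol`, `mean`, `std`, `n_folds`.
#' @export
glance.cv_result <- function(x, ...) {
  tibble::tibble(protocol = x$protocol, mean = x$mean, std = x$std,
                 n_folds = nrow(x$folds))
}

#' Tidy a permutation null distribution
#'
#' @param x a `null_distribution`.
#' @param ... unused.
#' @return Tibble: `permutation`, `accuracy`.
#' @export
tidy.null_distribution <- function(x, ...) {
  tibble::tibble(permutation = seq_along(x$accuracies),
                 accuracy = x$accuracies)
}

#' One-row summary of a permutation null
#'
#' @param x a `null_distribution`.
#' @param ... unused.
#' @return Tibble with `chance`, `q95`, `n_perm`, `protocol`.
#' @export
glance.null_distribution <- function(x, ...) {
  tibble::tibble(chance = x$chance, q95 = x$q95, n_perm = x$n_perm,
                 protocol = x$protocol)
}
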