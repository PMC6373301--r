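# Internal helpers shared across modules.

# Stop with a classed condition so callers/tests can distinguish user errors.
stop_invalid <- function(msg, ...) {
  rlang::abort(sprintf(msg, ...), class = "gripnet_invalid_input")
}

check_matrix <- function(x, what = "data") {
  if (!is.matrix(x) || !is.numeric(x)) {
    stop_invalid("`%s` must be a numeric matrix (channels x samples)", what)
  }
  invisible(x)
}

# Derive a child seed from a parent seed and a stream index; stays < 2^31.
derive_seed <- function(seed, stream) {
  (as.integer(seed) %% 100000L) * 19997L + as.integer(stream) * 7919L + 1L
}

# Evaluate `expr` under a local RNG state seeded with `seed`; NULL seed means
# use (and advance) the current RNG state.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(force(expr))
  withr::with_seed(as.integer(seed), expr)
}

# Encode a label vector into runs: tibble(label, start, length) (1-based).
label_runs <- function(labels) {
  r <- rle(labels)
  ends <- cumsum(r$lengths)
  tibble::tibble(
    label = r$values,
    start = ends - r$lengths + 1L,
    length = r$lengths
  )
}

# Column-standardize `x` by train statistics; constant columns get scale 1.
standardizer <- function(train) {
  mu <- colMeans(train)
  sigma <- apply(train, 2, stats::sd)
  sigma[!is.finite(sigma) | sigma < 1e-12] <- 1
  list(
    apply = function(x) sweep(sweep(x, 2, mu, "-"), 2, sigma, "/"),
    center = mu, scale = sigma
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
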