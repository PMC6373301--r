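#' Threshold a weighted connectivity matrix into a binary network
#'
#' Symmetrizes a directed weight matrix by the mean of the two directions,
#' zeroes the diagonal, and keeps the top `ceiling(density * N * (N - 1) / 2)`
#' undirected edges by weight. Ties are broken deterministically in favour of
#' the smaller node-index pair.
#'
#' @param w square numeric matrix of weights in `[0, 1]` (e.g. one band of a
#'   [band_average()] result).
#' @param density fraction of possible undirected edges to retain, in
#'   `(0, 1]` (default 0.3).
#' @param nodes optional node labels.
#' @return Object of class `eeg_network`: `weights` (symmetrized),
#'   `binary_adj` (symmetric 0/1, zero diagonal), `density`, `nodes`.
#' @export
#' @examples
#' net <- binarize(matrix(runif(81), 9), density = 0.3)
#' sum(net$binary_adj) / 2
binarize <- function(w, density = 0.3, nodes = NULL) {
  if (!is.matrix(w) || nrow(w) != ncol(w)) {
    stop_invalid("`w` must be a square matrix")
  }
  if (!(density > 0 && density <= 1)) stop_invalid("`density` must be in (0, 1]")
  N <- nrow(w)
  sym <- (w + t(w)) / 2
  diag(sym) <- 0
  pairs <- which(upper.tri(sym), arr.ind = TRUE)
  wts <- sym[pairs]
  n_keep <- ceiling(density * N * (N - 1) / 2)
  ord <- order(-wts, pairs[, 1], pairs[, 2])
  keep <- ord[seq_len(min(n_keep, length(ord)))]
  adj <- matrix(0L, N, N)
  adj[pairs[keep, , drop = FALSE]] <- 1L
  adj <- adj + t(adj)
  structure(
    list(weights = sym, binary_adj = adj, density = density,
         nodes = nodes %||% (if (N == 9) motor_montage() else
                               paste0("n", seq_len(N)))),
    class = "eeg_network"
  )
}

#' @export
print.eeg_network <- function(x, ...) {
  cat(sprintf("<eeg_network> %d nodes, %d edges (density %.2f)\n",
              nrow(x$binary_adj), sum(x$binary_adj) / 2, x$density))
  invisible(x)
}

# Accept an eeg_network or a plain binary adjacency matrix.
as_binary_adj <- function(net) {
  adj <- if (inherits(net, "eeg_network")) net$binary_adj else net
  if (!is.matrix(adj) || nrow(adj) != ncol(adj)) {
    stop_invalid("need a square binary adjacency matrix")
  }
  adj <- (adj != 0) * 1L
  diag(adj) <- 0L
  if (!isTRUE(all.equal(adj, t(adj)))) stop_invalid("adjacency must be symmetric")
  adj
}

#' Average clustering coefficient of a binary network
#'
#' Per node, `C_i = 2 e_i / (k_i (k_i - 1))` where `e_i` counts the edges
#' among node `i`'s neighbours and `k_i` is its degree; nodes with fewer than
#' two neighbours contribute `C_i = 0` (documented convention). The network
#' coefficient is the mean over all `N` nodes.
#'
#' @param net an [binarize()] network or a symmetric 0/1 matrix.
#' @return Scalar mean clustering coefficient.
#' @export
clustering_coefficient <- function(net) {
  adj <- as_binary_adj(net)
  k <- rowSums(adj)
  e <- diag(adj %*% adj %*% adj) / 2   # triangles through each node
  ci <- ifelse(k >= 2, 2 * e / (k * (k - 1)), 0)
  mean(ci)
}

#' Characteristic (shortest) path length of a binary network
#'
#' Hop-count shortest paths between all unordered node pairs (breadth-first
#' expansion of the adjacency); the path length is the mean over connected
#' pairs, with disconnected pairs excluded from the mean and counted.
#'
#' @param net an [binarize()] network or a symmetric 0/1 matrix.
#' @return List with `L` (mean shortest path over connected pairs) and
#'   `n_disconnected` (unordered pairs with no path).
#' @export
path_length <- function(net) {
  adj <- as_binary_adj(net)
  N <- nrow(adj)
  if (sum(adj) == 0) {
    rlang::abort("network has no edges: path length undefined",
                 class = "gripnet_invalid_input")
  }
  dist <- matrix(Inf, N, N)
  diag(dist) <- 0
  reach <- adj
  d <- 1
  while (any(reach > 0) && d < N) {
    newly <- reach > 0 & !is.finite(dist)
    dist[newly] <- d
    reach <- (reach %*% adj) * is.infinite(dist)
    d <- d + 1
  }
  newly <- reach > 0 & !is.finite(dist)
  dist[newly] <- d
  up <- dist[upper.tri(dist)]
  connected <- is.finite(up)
  list(L = mean(up[connected]), n_disconnected = sum(!connected))
}

#' Graph feature block: clustering and path length per band
#'
#' Binarizes each band's connectivity matrix at the given density and returns
#' the six network features in fixed order:
#' `C_theta, L_theta, C_alpha, L_alpha, C_beta, L_beta`.
#'
#' @param bc a [band_average()] result with theta, alpha and beta bands.
#' @param density binarization density (default 0.3).
#' @return Named numeric vector of length `2 * n_bands` (6 for the standard
#'   bands).
#' @export
network_features <- function(bc, density = 0.3) {
  stopifnot(inherits(bc, "band_connectivity"))
  out <- numeric(0)
  for (b in names(bc$matrices)) {
    net <- binarize(bc$matrices[[b]], density = density)
    cl <- clustering_coefficient(net)
    pl <- path_length(net)$L
    v <- c(cl, pl)
    names(v) <- paste0("net_", c("C_", "L_"), b)
    out <- c(out, v)
  }
  out
}

#' Export a network as an edge list
#'
#' @param net an [binarize()] network.
#' @param path output path for the tab-separated `node_a`, `node_b`,
#'   `weight` table (retained undirected edges only).
#' @return The edge tibble, invisibly.
#' @export
write_network_edges <- function(net, path) {
  stopifnot(inherits(net, "eeg_network"))
  idx <- which(upper.tri(net$binary_adj) & net$binary_adj > 0, arr.ind = TRUE)
  edges <- tibble::tibble(
    node_a = net$nodes[idx[, 1]],
    node_b = net$nodes[idx[, 2]],
    weight = net$weights[idx]
  )
  write.table(edges, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(edges)
}
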