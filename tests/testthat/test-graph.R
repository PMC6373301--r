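# Independent matrix-algebra oracles for the graph metrics.
oracle_clustering <- function(adj) {
  k <- rowSums(adj)
  tri <- diag(adj %*% adj %*% adj) / 2
  mean(ifelse(k >= 2, 2 * tri / (k * (k - 1)), 0))
}

oracle_path_igraph <- function(adj) {
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  d <- igraph::distances(g)
  up <- d[upper.tri(d)]
  list(L = mean(up[is.finite(up)]), n_disconnected = sum(!is.finite(up)))
}

test_that("binarization keeps the top edges with deterministic tie-breaks", {
  # all-equal weights at density 1: complete graph
  net <- binarize(matrix(0.5, 5, 5), density = 1)
  expect_equal(net$binary_adj, matrix(1L, 5, 5) - diag(5L))
  # a planted triangle at matching density is retained exactly
  w <- matrix(0.1, 9, 9)
  tri <- rbind(c(1, 2), c(2, 3), c(1, 3))
  w[tri] <- 0.9; w[tri[, 2:1]] <- 0.9
  net2 <- binarize(w, density = 3 / 36)
  expect_equal(sum(net2$binary_adj) / 2, 3)
  expect_true(all(net2$binary_adj[tri] == 1))
  # symmetrization by the mean of the two directions
  w3 <- matrix(0, 3, 3); w3[1, 2] <- 0.8  # one direction only
  net3 <- binarize(w3, density = 1 / 3)
  expect_equal(net3$weights[1, 2], 0.4)
  expect_equal(net3$weights[2, 1], 0.4)
  # deterministic tie-break on equal weights: smallest index pair first
  net4 <- binarize(matrix(0.5, 4, 4), density = 1 / 6)
  expect_equal(which(net4$binary_adj == 1, arr.ind = TRUE)[1, ], c(row = 2L, col = 1L))
  expect_error(binarize(matrix(1, 2, 3)), class = "gripnet_invalid_input")
  expect_error(binarize(matrix(1, 3, 3), density = 0), class = "gripnet_invalid_input")
})

test_that("clustering coefficient matches closed forms and hand evaluation", {
  k9 <- matrix(1L, 9, 9) - diag(9L)
  expect_equal(clustering_coefficient(k9), 1)
  star <- matrix(0L, 6, 6); star[1, 2:6] <- 1L; star <- star + t(star)
  expect_equal(clustering_coefficient(star), 0)
  # triangle A-B-C plus pendant D-A: (1/3 + 1 + 1 + 0) / 4 = 7/12
  adj <- matrix(0L, 4, 4)
  adj[rbind(c(1, 2), c(2, 3), c(1, 3), c(1, 4))] <- 1L
  adj <- adj + t(adj)
  expect_equal(clustering_coefficient(adj), 7 / 12)
})

test_that("path length matches closed forms and reports disconnection", {
  k5 <- matrix(1L, 5, 5) - diag(5L)
  expect_equal(path_length(k5)$L, 1)
  p3 <- matrix(0L, 3, 3); p3[1, 2] <- p3[2, 3] <- 1L; p3 <- p3 + t(p3)
  expect_equal(path_length(p3)$L, 4 / 3)
  # two disjoint edges on 4 nodes: connected pairs at distance 1, 4 pairs unreachable
  dis <- matrix(0L, 4, 4); dis[1, 2] <- dis[3, 4] <- 1L; dis <- dis + t(dis)
  res <- path_length(dis)
  expect_equal(res$L, 1)
  expect_equal(res$n_disconnected, 4L)
  expect_error(path_length(matrix(0L, 3, 3)), class = "gripnet_invalid_input")
})

test_that("metrics agree with igraph on random graphs up to 9 nodes", {
  skip_if_not_installed("igraph")
  for (i in 1:40) {
    n <- 3 + i %% 7
    adj <- withr::with_seed(i, {
      a <- matrix(rbinom(n * n, 1, 0.4), n)
      a[lower.tri(a, diag = TRUE)] <- 0
      a + t(a)
    })
    if (sum(adj) == 0) next
    g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
    ci <- igraph::transitivity(g, type = "localundirected", isolates = "zero")
    ci[is.nan(ci)] <- 0
    expect_equal(clustering_coefficient(adj), mean(ci), tolerance = 1e-12)
    ref <- oracle_path_igraph(adj)
    got <- path_length(adj)
    expect_equal(got$L, ref$L)
    expect_equal(got$n_disconnected, ref$n_disconnected)
  }
})

test_that("adding an edge never lengthens paths nor destroys triangles", {
  for (i in 1:15) {
    n <- 6
    adj <- withr::with_seed(100 + i, {
      a <- matrix(rbinom(n * n, 1, 0.35), n)
      a[lower.tri(a, diag = TRUE)] <- 0
      a + t(a)
    })
    if (sum(adj) == 0) next
    absent <- which(adj == 0 & upper.tri(adj), arr.ind = TRUE)
    if (!nrow(absent)) next
    pick <- absent[1 + (i %% nrow(absent)), ]
    adj2 <- adj
    adj2[pick[1], pick[2]] <- adj2[pick[2], pick[1]] <- 1L
    tri_before <- sum(diag(adj %*% adj %*% adj)) / 6
    tri_after <- sum(diag(adj2 %*% adj2 %*% adj2)) / 6
    expect_gte(tri_after, tri_before)
    # restrict to pairs connected before: their distance cannot grow
    g1 <- oracle_path_igraph(adj); g2 <- oracle_path_igraph(adj2)
    expect_lte(g2$n_disconnected, g1$n_disconnected)
  }
})

test_that("network feature block has fixed order and length 6", {
  mats <- list(theta = matrix(0.5, 9, 9), alpha = matrix(0.5, 9, 9),
               beta = matrix(0.5, 9, 9))
  bc <- structure(list(matrices = mats, bands = eeg_bands()),
                  class = "band_connectivity")
  nf <- network_features(bc, density = 1)
  expect_equal(names(nf), c("net_C_theta", "net_L_theta", "net_C_alpha",
                            "net_L_alpha", "net_C_beta", "net_L_beta"))
  expect_equal(unname(nf), rep(1, 6))
})
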