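test_that("Spearman correlation matrix is symmetric with unit diagonal and rank-invariant", {
  set.seed(2)
  x <- matrix(rnorm(30 * 6), 30, 6, dimnames = list(NULL, paste0("f", 1:6)))
  x[, 2] <- exp(x[, 1])            # strictly increasing transform of f1
  rho <- correlation_matrix(x)
  expect_equal(dim(rho), c(6L, 6L))
  expect_equal(rho, t(rho))
  expect_equal(unname(diag(rho)), rep(1, 6))
  expect_equal(rho["f1", "f2"], 1)
  x[, 3] <- 7
  expect_error(correlation_matrix(x), "f3")
})

test_that("edge thresholding keeps exactly the top fraction of |rho| pairs", {
  p <- 6
  rho <- diag(p)
  vals <- seq(0.05, 0.75, by = 0.05)[1:15]
  rho[upper.tri(rho)] <- vals
  rho <- rho + t(rho) - diag(p) * 0          # symmetric copy
  diag(rho) <- 1
  colnames(rho) <- rownames(rho) <- paste0("f", 1:p)
  net <- build_network(rho, top_fraction = 0.30)
  expect_equal(nrow(net$edges), 5L)          # ceiling(0.3 * 15)
  expect_setequal(net$edges$weight, sort(vals, decreasing = TRUE)[1:5])
  full <- build_network(rho, top_fraction = 1)
  expect_equal(nrow(full$edges), 15L)
  expect_true(all(full$adjacency[upper.tri(full$adjacency)] > 0))
})

test_that("modularity of the undivided network is zero and is sign-symmetric", {
  net <- random_weighted_network(8, seed = 3)
  expect_equal(modularity_bisection(net, rep(1, 8)), 0)
  set.seed(4)
  s <- sample(c(-1, 1), 8, replace = TRUE)
  expect_equal(modularity_bisection(net, s), modularity_bisection(net, -s))
})

test_that("two disconnected triangles have Q = 0.5 under the component split, the exhaustive maximum", {
  A <- matrix(0, 6, 6)
  for (e in list(c(1, 2), c(1, 3), c(2, 3), c(4, 5), c(4, 6), c(5, 6))) {
    A[e[1], e[2]] <- A[e[2], e[1]] <- 1
  }
  net <- network_from_adjacency(A)
  s <- c(1, 1, 1, -1, -1, -1)
  expect_equal(modularity_bisection(net, s), 0.5)
  expect_equal(exhaustive_best_bisection(net), 0.5)
  bi <- spectral_bisect(net)
  expect_true(bi$divisible)
  expect_equal(bi$dQ, 0.5)
  expect_true(all(bi$s[1:3] == bi$s[1]) && all(bi$s[4:6] == -bi$s[1]))
})

test_that("a complete graph is indivisible and clusters as a single group", {
  A <- matrix(1, 4, 4); diag(A) <- 0
  net <- network_from_adjacency(A)
  expect_false(spectral_bisect(net)$divisible)
  expect_lte(exhaustive_best_bisection(net), 0)
  part <- cluster_network(net)
  expect_equal(length(part$groups), 1L)
  expect_equal(part$Q, 0)
})

test_that("three bridged 4-cliques are recovered as three groups", {
  n <- 12
  A <- matrix(0, n, n)
  for (i in 1:3) { b <- ((i - 1) * 4 + 1):(i * 4); A[b, b] <- 1 }
  diag(A) <- 0
  A[4, 5] <- A[5, 4] <- 1; A[8, 9] <- A[9, 8] <- 1; A[12, 1] <- A[1, 12] <- 1
  net <- network_from_adjacency(A)
  part <- cluster_network(net)
  expect_equal(length(part$groups), 3L)
  truth <- rep(1:3, each = 4)
  expect_equal(length(unique(paste(part$labels, truth))), 3L)  # label bijection
  # accumulated split gains reproduce the final partition modularity
  expect_equal(part$Q, part$dQ_sum, tolerance = 1e-9)
  expect_gte(part$Q, 0); expect_lte(part$Q, 1)
  # independent Q oracle
  g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected")
  expect_equal(part$Q, igraph::modularity(g, part$labels), tolerance = 1e-9)
})

test_that("features from 3 latent factors cluster exactly into the factor blocks", {
  set.seed(6)
  n <- 200
  factors <- matrix(rnorm(n * 3), n, 3)
  load <- rep(1:3, each = 5)
  x <- sapply(seq_along(load), function(j) {
    0.9 * factors[, load[j]] + 0.1 * rnorm(n)
  })
  colnames(x) <- sprintf("v%02d", seq_along(load))
  net <- build_network(correlation_matrix(x), top_fraction = 0.30)
  part <- cluster_network(net)
  expect_equal(mclust::adjustedRandIndex(part$labels, load), 1)
})

test_that("relabeling under node permutation is an isomorphism", {
  set.seed(8)
  x <- matrix(rnorm(50 * 9), 50, 9, dimnames = list(NULL, paste0("f", 1:9)))
  x[, 1:3] <- x[, 1] + 0.1 * matrix(rnorm(50 * 3), 50, 3)
  x[, 4:6] <- x[, 4] + 0.1 * matrix(rnorm(50 * 3), 50, 3)
  rho <- correlation_matrix(x)
  perm <- sample(9)
  p1 <- cluster_network(build_network(rho, 0.3))
  p2 <- cluster_network(build_network(rho[perm, perm], 0.3))
  expect_equal(mclust::adjustedRandIndex(p1$labels[colnames(rho)[perm]],
                                         p2$labels), 1)
  expect_equal(p1$Q, p2$Q, tolerance = 1e-9)
})
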