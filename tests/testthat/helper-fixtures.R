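# Shared fixtures and independent oracles (kept deliberately naive: oracles
# must not share code paths with the implementation they check).

# Recording with an exactly piecewise-linear VCO2-vs-VO2 relation.
piecewise_recording <- function(vo2_from = 1000, vo2_to = 3000, by = 20,
                                break_vo2 = 2000, slope_lo = 0.85,
                                slope_hi = 1.20, noise_sd = 0) {
  vo2 <- seq(vo2_from, vo2_to, by = by)
  vco2 <- ifelse(vo2 <= break_vo2, slope_lo * vo2,
                 slope_lo * break_vo2 + slope_hi * (vo2 - break_vo2))
  if (noise_sd > 0) vco2 <- vco2 + rnorm(length(vco2), 0, noise_sd)
  data.frame(t_s = seq_along(vo2) * 2, vo2_ml_min = vo2, vco2_ml_min = vco2,
             ve_l_min = vco2 / 40, rf_per_min = rep(30, length(vo2)))
}

# Brute-force two-segment least-squares oracle via lm(), one fit per split.
brute_vat <- function(vo2, vco2, min_points = 5) {
  ord <- order(vo2)
  x <- vo2[ord]; y <- vco2[ord]
  n <- length(x)
  best_sse <- Inf; best_b <- NA
  for (b in min_points:(n - min_points)) {
    f1 <- lm(y[1:b] ~ x[1:b])
    f2 <- lm(y[(b + 1):n] ~ x[(b + 1):n])
    sse <- sum(resid(f1)^2) + sum(resid(f2)^2)
    if (sse < best_sse) { best_sse <- sse; best_b <- b }
  }
  list(vo2_at_vat = x[best_b], sse = best_sse)
}

# Exhaustive best subset of size k by direct lm() refits.
best_subset <- function(x, y, k = 2) {
  combs <- utils::combn(ncol(x), k)
  sse <- apply(combs, 2, function(cols) {
    sum(lm.fit(cbind(1, x[, cols, drop = FALSE]), y)$residuals^2)
  })
  sort(colnames(x)[combs[, which.min(sse)]])
}

# Feature network straight from an adjacency matrix (bypasses build_network).
network_from_adjacency <- function(A) {
  colnames(A) <- rownames(A) <- colnames(A) %||% paste0("f", seq_len(nrow(A)))
  structure(list(nodes = colnames(A), adjacency = A, strength = rowSums(A),
                 m = sum(A) / 2, edges = data.frame()),
            class = "feature_network")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Exhaustive best bisection of a network: all 2^(n-1) sign assignments,
# delta-Q at the root equals Q of the two-group division.
exhaustive_best_bisection <- function(net) {
  n <- length(net$nodes)
  best <- -Inf
  for (code in 0:(2^(n - 1) - 1)) {
    bits <- as.integer(intToBits(code))[1:(n - 1)]
    s <- c(1, ifelse(bits == 1, -1, 1))
    if (length(unique(s)) == 1) next
    q <- modularity_bisection(net, s)
    if (q > best) best <- q
  }
  best
}

# Seeded weighted Erdos-Renyi graph guaranteed to have at least one edge.
random_weighted_network <- function(n, p = 0.4, seed = 1) {
  set.seed(seed)
  repeat {
    A <- matrix(0, n, n)
    ut <- which(upper.tri(A))
    on_edge <- runif(length(ut)) < p
    A[ut[on_edge]] <- runif(sum(on_edge), 0.5, 1)
    A <- A + t(A)
    if (sum(A) > 0) break
  }
  network_from_adjacency(A)
}
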