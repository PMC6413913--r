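# Feature correlation network and Newman leading-eigenvector modularity
# clustering by iterative spectral bisection.

#' Spearman correlation matrix of a feature matrix
#'
#' @param features Numeric matrix (subjects x features), no missing values,
#'   at least 4 rows.
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
correlation_matrix <- function(features) {
  features <- as.matrix(features)
  if (nrow(features) < 4) stop("need at least 4 subjects")
  if (anyNA(features)) stop("missing values in feature matrix")
  sds <- apply(features, 2, stats::sd)
  if (any(!(sds > 0))) {
    stop("constant column(s), correlation undefined: ",
         paste(colnames(features)[!(sds > 0)], collapse = ", "))
  }
  rho <- stats::cor(features, method = "spearman")
  diag(rho) <- 1
  rho
}

#' Build the feature network from a correlation matrix
#'
#' Ranks the off-diagonal pairs by absolute Spearman correlation and keeps the
#' top `ceiling(top_fraction * choose(p, 2))` pairs as undirected edges with
#' weight `|rho|` (modularity assumes nonnegative weights).  All nodes are
#' retained, possibly isolated.  Ties at the cutoff are broken by the lexical
#' order of the feature-name pair, for determinism.
#'
#' @param corr Symmetric correlation matrix with named dimensions.
#' @param top_fraction Fraction of pairs kept as edges (default 0.30).
#' @return Object of class `feature_network`: `nodes`, `adjacency` (symmetric,
#'   zero diagonal), `strength` (weighted degree), `m` (total edge weight),
#'   `edges` (data.frame feature_a, feature_b, weight).
#' @export
build_network <- function(corr, top_fraction = 0.30) {
  stopifnot(is.matrix(corr), nrow(corr) == ncol(corr))
  if (!(top_fraction > 0 && top_fraction <= 1)) {
    stop("top_fraction must be in (0, 1]")
  }
  p <- nrow(corr)
  nodes <- colnames(corr) %||% paste0("f", seq_len(p))
  ut <- which(upper.tri(corr), arr.ind = TRUE)
  w <- abs(corr[ut])
  a_name <- nodes[ut[, 1]]; b_name <- nodes[ut[, 2]]
  ord <- order(-w, pmin(a_name, b_name), pmax(a_name, b_name), method = "radix")
  n_keep <- ceiling(top_fraction * nrow(ut))
  keep <- ord[seq_len(n_keep)]
  A <- matrix(0, p, p, dimnames = list(nodes, nodes))
  A[ut[keep, , drop = FALSE]] <- w[keep]
  A <- A + t(A)
  structure(list(nodes = nodes, adjacency = A, strength = rowSums(A),
                 m = sum(A) / 2,
                 edges = data.frame(feature_a = pmin(a_name[keep], b_name[keep]),
                                    feature_b = pmax(a_name[keep], b_name[keep]),
                                    weight = w[keep])),
            class = "feature_network")
}

#' @export
print.feature_network <- function(x, ...) {
  cat(sprintf("feature network: %d nodes, %d edges, total weight m = %.3f\n",
              length(x$nodes), nrow(x$edges), x$m))
  invisible(x)
}

modularity_matrix <- function(network) {
  k <- network$strength
  network$adjacency - outer(k, k) / (2 * network$m)
}

#' Modularity of a two-group (+-1) division
#'
#' `Q = (1/4m) * sum_ij (A_ij - k_i k_j / 2m) (S_i S_j + 1)` with strengths as
#' degrees and total edge weight as `m` for weighted graphs.
#'
#' @param network A [build_network()] object.
#' @param s Membership vector of +-1, one entry per node.
#' @return Modularity Q.
#' @export
modularity_bisection <- function(network, s) {
  stopifnot(length(s) == length(network$nodes), all(s %in% c(-1, 1)))
  if (network$m <= 0) stop("modularity undefined: network has no edges")
  B <- modularity_matrix(network)
  sum(B * (outer(s, s) + 1)) / (4 * network$m)
}

#' Modularity of an arbitrary partition
#'
#' @param network A [build_network()] object.
#' @param labels Group label per node.
#' @return Modularity Q.
#' @export
modularity_partition <- function(network, labels) {
  stopifnot(length(labels) == length(network$nodes))
  if (network$m <= 0) stop("modularity undefined: network has no edges")
  B <- modularity_matrix(network)
  same <- outer(labels, labels, "==")
  sum(B[same]) / (2 * network$m)
}

# Generalized modularity matrix of a subgroup: restricted B with the row sums
# of the restriction subtracted on the diagonal.
subgroup_B <- function(B, group) {
  Bg <- B[group, group, drop = FALSE]
  diag(Bg) <- diag(Bg) - rowSums(Bg)
  Bg
}

# One Kernighan-Lin-style fine-tuning pass repeated to convergence: each node
# is moved at most once per pass in best-gain order (even through downhill
# moves), and the pass keeps the best intermediate state.  Works on the
# quadratic form q(s) = s' Bg s; flipping node i changes it by
# -4 s_i (Bg s)_i + 4 Bg_ii.
refine_bisection <- function(Bg, s) {
  n <- length(s)
  q <- as.numeric(s %*% Bg %*% s)
  repeat {
    s_pass <- s
    v <- as.numeric(Bg %*% s_pass)
    q_pass <- q
    best_q <- q
    best_s <- s
    moved <- rep(FALSE, n)
    for (step in seq_len(n)) {
      delta <- -4 * s_pass * v + 4 * diag(Bg)
      delta[moved] <- -Inf
      i <- which.max(delta)
      q_pass <- q_pass + delta[i]
      v <- v - 2 * s_pass[i] * Bg[, i]
      s_pass[i] <- -s_pass[i]
      moved[i] <- TRUE
      if (q_pass > best_q + 1e-12) { best_q <- q_pass; best_s <- s_pass }
    }
    if (best_q <= q + 1e-12) break
    q <- best_q
    s <- best_s
  }
  list(s = s, q = q)
}

#' Spectral bisection of a network (or subgroup) by the leading eigenvector
#'
#' Computes the (generalized) modularity matrix of the group, takes the
#' eigenvector of its largest eigenvalue, and splits by sign (entries equal to
#' zero go to the +1 side).  Two deterministic refinements are then applied:
#' a sweep over the eigenvector ordering (every prefix split of the nodes
#' sorted by eigenvector entry), and the vertex-moving fine-tuning stage that
#' conventionally accompanies the leading-eigenvector method, which repeatedly
#' moves single nodes between the two halves while any move improves the
#' modularity gain.  The group is declared indivisible when the leading
#' eigenvalue is non-positive or no division achieves `dQ > tol`.
#'
#' @param network A [build_network()] object.
#' @param group Integer indices of the subgroup (default: all nodes).
#' @param tol Minimum modularity gain to accept (default 1e-10).
#' @return List with `s` (+-1 per group member), `dQ`, and `divisible`.
#' @export
spectral_bisect <- function(network, group = seq_along(network$nodes),
                            tol = 1e-10) {
  if (length(group) < 2) return(list(s = rep(1, length(group)), dQ = 0, divisible = FALSE))
  B <- modularity_matrix(network)
  Bg <- if (length(group) == length(network$nodes) &&
            all(group == seq_along(network$nodes))) B else subgroup_B(B, group)
  eig <- eigen((Bg + t(Bg)) / 2, symmetric = TRUE)
  if (eig$values[1] <= tol) {
    return(list(s = rep(1, length(group)), dQ = 0, divisible = FALSE))
  }
  u <- eig$vectors[, 1]
  dq_of <- function(s) as.numeric(s %*% Bg %*% s) / (4 * network$m)
  s_best <- ifelse(u >= 0, 1, -1)
  dq_best <- dq_of(s_best)
  # sweep over the eigenvector ordering
  ord <- order(u)
  for (cut in seq_len(length(group) - 1L)) {
    s <- rep(1, length(group))
    s[ord[seq_len(cut)]] <- -1
    dq <- dq_of(s)
    if (dq > dq_best) { dq_best <- dq; s_best <- s }
  }
  ref <- refine_bisection(Bg, s_best)
  if (ref$q / (4 * network$m) > dq_best && length(unique(ref$s)) > 1) {
    s_best <- ref$s
    dq_best <- ref$q / (4 * network$m)
  }
  if (dq_best <= tol || length(unique(s_best)) == 1) {
    return(list(s = rep(1, length(group)), dQ = 0, divisible = FALSE))
  }
  list(s = s_best, dQ = dq_best, divisible = TRUE)
}

#' Cluster a feature network by iterative spectral bisection
#'
#' Starting from the whole network, repeatedly applies [spectral_bisect()] to
#' each current group and accepts a split only when its modularity gain
#' exceeds `tol`; groups for which no positive-gain division exists are left
#' intact (indivisibility is a result, not an error).
#'
#' @param network A [build_network()] object.
#' @param tol Minimum accepted modularity gain (default 1e-10).
#' @return Object of class `network_partition`: `labels` (integer per node,
#'   named), `groups` (list of node-name vectors), `Q` (modularity of the
#'   final partition), `dQ_sum` (accumulated gains), `tree` (data.frame of
#'   accepted splits: group size and dQ).
#' @export
#' @examples
#' rho <- diag(6)
#' rho[1:3, 1:3] <- 0.9; rho[4:6, 4:6] <- 0.9; diag(rho) <- 1
#' colnames(rho) <- rownames(rho) <- paste0("f", 1:6)
#' cluster_network(build_network(rho, top_fraction = 0.4))
cluster_network <- function(network, tol = 1e-10) {
  n <- length(network$nodes)
  labels <- rep(1L, n)
  queue <- list(seq_len(n))
  next_label <- 2L
  dq_sum <- 0
  tree <- list()
  while (length(queue)) {
    g <- queue[[1]]; queue <- queue[-1]
    if (length(g) < 2) next
    bi <- spectral_bisect(network, g, tol = tol)
    if (!bi$divisible) next
    left <- g[bi$s > 0]; right <- g[bi$s < 0]
    labels[right] <- next_label
    next_label <- next_label + 1L
    dq_sum <- dq_sum + bi$dQ
    tree[[length(tree) + 1L]] <- data.frame(size = length(g), dQ = bi$dQ,
                                            left = length(left),
                                            right = length(right))
    queue <- c(queue, list(left), list(right))
  }
  labels <- stats::setNames(match(labels, unique(labels)), network$nodes)
  groups <- split(network$nodes, labels)
  structure(list(labels = labels, groups = unname(groups),
                 Q = if (network$m > 0) modularity_partition(network, labels) else 0,
                 dQ_sum = dq_sum,
                 tree = if (length(tree)) do.call(rbind, tree) else
                   data.frame(size = integer(0), dQ = numeric(0),
                              left = integer(0), right = integer(0))),
            class = "network_partition")
}

#' @export
print.network_partition <- function(x, ...) {
  cat(sprintf("partition: %d group(s), Q = %.4f\n", length(x$groups), x$Q))
  for (i in seq_along(x$groups)) {
    cat(sprintf("  group %d (%d): %s\n", i, length(x$groups[[i]]),
                paste(utils::head(x$groups[[i]], 8), collapse = ", ")))
  }
  invisible(x)
}
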