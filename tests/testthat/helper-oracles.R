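# Independent oracles used across the suite. These deliberately recompute
# quantities by brute force (per-pair path walks, dense multivariate-normal
# densities, explicit normal equations) so they share no code path with the
# package implementations they check.

# Parent map and root of an ape tree.
oracle_parents <- function(tree) {
  p <- rep(NA_integer_, ape::Ntip(tree) + tree$Nnode)
  bl <- rep(NA_real_, length(p))
  for (e in seq_len(nrow(tree$edge))) {
    p[tree$edge[e, 2]] <- tree$edge[e, 1]
    bl[tree$edge[e, 2]] <- tree$edge.length[e]
  }
  list(parent = p, bl = bl, root = which(is.na(p)))
}

# Node sequence from the root down to a node.
oracle_root_path <- function(pm, node) {
  path <- node
  while (!is.na(pm$parent[node])) {
    node <- pm$parent[node]
    path <- c(node, path)
  }
  path
}

# BM covariance by per-pair path walks: shared path length of each tip pair.
oracle_bm_cov <- function(tree) {
  n <- ape::Ntip(tree)
  pm <- oracle_parents(tree)
  paths <- lapply(seq_len(n), function(i) oracle_root_path(pm, i))
  C <- matrix(0, n, n, dimnames = list(tree$tip.label, tree$tip.label))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      shared <- intersect(paths[[i]], paths[[j]])
      C[i, j] <- sum(pm$bl[setdiff(shared, pm$root)])
    }
  }
  C
}

# Dense multivariate-normal log density.
oracle_mvn <- function(x, mean, V) {
  r <- x - mean
  -length(x) / 2 * log(2 * pi) -
    as.numeric(determinant(V, logarithm = TRUE)$modulus) / 2 -
    drop(crossprod(r, solve(V, r))) / 2
}

# Hansen expected tip values by segment-by-segment hand integration along each
# root-to-tip path.
oracle_hansen_mean <- function(tree, painting, alpha, theta) {
  n <- ape::Ntip(tree)
  pm <- oracle_parents(tree)
  depth <- numeric(length(pm$parent))
  for (node in order(sapply(seq_along(pm$parent), function(k)
    length(oracle_root_path(pm, k))))) {
    if (node != pm$root) depth[node] <- depth[pm$parent[node]] + pm$bl[node]
  }
  edge_of <- function(child) which(tree$edge[, 2] == child)
  mu <- numeric(n)
  for (i in seq_len(n)) {
    path <- oracle_root_path(pm, i)
    Ti <- depth[i]
    m <- theta[[attr(painting, "root_regime")]] * exp(-alpha * Ti)
    for (node in setdiff(path, pm$root)) {
      reg <- unclass(painting)[edge_of(node)]
      t0 <- depth[pm$parent[node]]; t1 <- depth[node]
      m <- m + theta[[reg]] * (exp(-alpha * (Ti - t1)) - exp(-alpha * (Ti - t0)))
    }
    mu[i] <- m
  }
  stats::setNames(mu, tree$tip.label)
}

# OU covariance from the closed form, built on the brute-force shared paths.
oracle_ou_cov <- function(tree, alpha, sigma2) {
  C <- oracle_bm_cov(tree)
  n <- nrow(C)
  Ti <- diag(C)
  V <- matrix(0, n, n, dimnames = dimnames(C))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      V[i, j] <- sigma2 / (2 * alpha) * exp(-alpha * (Ti[i] + Ti[j] - 2 * C[i, j])) *
        (1 - exp(-2 * alpha * C[i, j]))
    }
  }
  V
}

# A random non-ultrametric fixture tree with a random 2-regime painting.
random_fixture <- function(n, seed) {
  set.seed(seed)
  tree <- ape::rtree(n)
  tree$edge.length <- tree$edge.length + 0.1   # keep away from zero
  shift <- sample(seq_len(nrow(tree$edge)), 1)
  painting <- painting_from_shifts(tree, shift, "shifted")
  x <- stats::setNames(rnorm(n), tree$tip.label)
  list(tree = tree, painting = painting, x = x, shift = shift)
}
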