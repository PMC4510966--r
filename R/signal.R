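## Blomberg's K: phylogenetic signal measured against the Brownian-motion
## expectation, with its permutation test.

#' Blomberg's K statistic
#'
#' Compares the mean squared error of the tip data measured from the
#' phylogenetic (GLS) mean, `MSE0`, with the GLS mean squared error computed
#' through the tree's variance-covariance matrix, `MSE`; the observed ratio is
#' divided by its Brownian-motion expectation for the given tree,
#' `(tr(C) - n / sum(C^-1)) / (n - 1)`, giving `K`. `K` near 1 indicates
#' Brownian-like signal; `K < 1` variance concentrated within clades
#' (homoplasy-like); `K > 1` variance concentrated among clades. On a star
#' tree with equal branch lengths `K` is identically 1.
#'
#' @param tree A `"phylo"` object with at least 4 tips.
#' @param x Named, non-constant numeric vector of tip values.
#' @return An object of class `"blomberg_k"`: list with `K`, `observed_ratio`,
#'   `expected_ratio`, `MSE0`, `MSE`, `n`; `p_value`, `n_perm`, `tail` are
#'   filled in by [k_permutation_test()].
#' @export
blomberg_k <- function(tree, x) {
  prep <- k_prep(tree)
  x <- align_traits(tree, x)
  k_core(prep, x)
}

## Tree-dependent pieces of K, computed once per tree (the permutation test
## reuses them across shuffles).
k_prep <- function(tree) {
  validate_tree(tree)
  n <- ape::Ntip(tree)
  if (n < 4) stop("need at least 4 tips")
  C <- bm_covariance(tree)
  Ci <- solve(C)
  denom <- sum(Ci)
  list(n = n, Ci = Ci, denom = denom, colsums_Ci = colSums(Ci),
       expected = (sum(diag(C)) - n / denom) / (n - 1))
}

k_core <- function(prep, x) {
  if (stats::sd(x) == 0) stop("K undefined for a constant trait")
  n <- prep$n
  mu <- sum(prep$colsums_Ci * x) / prep$denom
  r <- x - mu
  MSE0 <- sum(r^2) / (n - 1)
  MSE <- drop(crossprod(r, prep$Ci %*% r)) / (n - 1)
  observed <- MSE0 / MSE
  out <- list(K = observed / prep$expected, observed_ratio = observed,
              expected_ratio = prep$expected, MSE0 = MSE0, MSE = MSE, n = n,
              p_value = NA_real_, n_perm = NA_integer_, tail = NA_character_)
  class(out) <- "blomberg_k"
  out
}

#' Permutation test for Blomberg's K
#'
#' Shuffles the tip values across the tips `n_perm` times and asks whether the
#' observed `K` exceeds the permutation distribution:
#' `p = (1 + #{K_perm >= K_obs}) / (1 + n_perm)` (add-one estimator, so the
#' smallest attainable value with 1000 permutations is 1/1001). Shuffled data
#' carry no signal and give small `K`, so a small `p` means phylogenetic
#' signal is present -- whether the observed `K` sits above 1 (variance among
#' clades) or below 1 (variance within clades, still exceeding the no-signal
#' baseline). The direction of departure of `K` from 1 is recorded in `tail`
#' for interpretation.
#'
#' @param tree A `"phylo"` object.
#' @param x Named numeric vector of tip values.
#' @param n_perm Number of permutations (default 1000; at least 99).
#' @param seed Integer seed; the test is deterministic given it.
#' @return A `"blomberg_k"` with `p_value`, `n_perm` and `tail` filled in.
#' @examples
#' tr <- sim_tree(16, total_height = 10, seed = 3)
#' x <- simulate_bm(tr, sigma2 = 1, root = 0, seed = 4)
#' k_permutation_test(tr, x, n_perm = 199, seed = 5)
#' @export
k_permutation_test <- function(tree, x, n_perm = 1000, seed) {
  if (n_perm < 99) stop("need at least 99 permutations")
  if (missing(seed)) stop("seed is required for a reproducible test")
  prep <- k_prep(tree)
  x <- align_traits(tree, x)
  obs <- k_core(prep, x)
  set.seed(seed)
  kperm <- numeric(n_perm)
  xu <- unname(x)
  for (i in seq_len(n_perm)) {
    kperm[i] <- k_core(prep, sample(xu))$K
  }
  obs$p_value <- (1 + sum(kperm >= obs$K)) / (1 + n_perm)
  obs$n_perm <- as.integer(n_perm)
  obs$tail <- if (obs$K >= 1) "K>1 (among clades)" else "K<1 (within clades)"
  obs
}

#' @export
print.blomberg_k <- function(x, ...) {
  cat(sprintf("Blomberg's K = %.4f (n = %d tips)\n", x$K, x$n))
  cat(sprintf("  observed MSE0/MSE = %.4f, BM expectation = %.4f\n",
              x$observed_ratio, x$expected_ratio))
  if (!is.na(x$p_value)) {
    cat(sprintf("  permutation test for signal: p = %.4g (%d permutations, %s)\n",
                x$p_value, x$n_perm, x$tail))
  }
  invisible(x)
}
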