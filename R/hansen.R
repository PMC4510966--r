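## Multi-regime Ornstein-Uhlenbeck (Hansen) model. A trait evolves along each
## branch as dX = alpha (theta_r - X) dt + sigma dB, with the optimum theta_r
## set by the regime painted on that branch. The root state is fixed at the
## root regime's optimum, the standard Hansen convention that removes the one
## unidentifiable parameter on ultrametric trees. The expected tip values are
## W %*% theta, where the weight matrix W integrates the exponentially
## discounted time each root-to-tip path spends in each regime; the tip
## covariance has the closed form valid for non-ultrametric trees with a fixed
## root state.

#' Hansen regime weight matrix
#'
#' `W[i, r]` is the exponentially discounted fraction of the root-to-tip path
#' of tip `i` spent in regime `r`:
#' sum over path segments in `r` of `exp(-alpha (T_i - t_end)) -
#' exp(-alpha (T_i - t_start))`, with the residual root weight
#' `exp(-alpha T_i)` assigned to the root regime. Rows sum to one; the
#' expected tip values under the model are `W %*% theta`.
#'
#' @param tree A `"phylo"` object.
#' @param painting A `"regime_painting"` for `tree`.
#' @param alpha Pull strength (per Myr), positive.
#' @param cache Internal; precomputed tree structures.
#' @return A tips x regimes matrix with regime labels as column names.
#' @export
hansen_weights <- function(tree, painting, alpha, cache = tree_cache(tree)) {
  if (alpha <= 0) stop("alpha must be positive")
  regimes <- attr(painting, "regimes")
  k <- length(regimes)
  n <- cache$n
  w <- exp(-alpha * (cache$seg_T - cache$seg_end)) -
       exp(-alpha * (cache$seg_T - cache$seg_start))
  reg_idx <- match(unclass(painting)[cache$seg_edge], regimes)
  W <- matrix(0, n, k, dimnames = list(cache$tree$tip.label, regimes))
  acc <- rowsum(w, group = (reg_idx - 1L) * n + cache$seg_tip)
  W[as.integer(rownames(acc))] <- acc
  r0 <- match(attr(painting, "root_regime"), regimes)
  W[, r0] <- W[, r0] + exp(-alpha * cache$Ti)
  W
}

#' Ornstein-Uhlenbeck tip covariance
#'
#' `V[i, j] = sigma2 / (2 alpha) * exp(-alpha (T_i + T_j - 2 t_ij)) *
#' (1 - exp(-2 alpha t_ij))`, with `t_ij` the shared root-to-MRCA path length;
#' valid for non-ultrametric trees with the root state held fixed. Below
#' `alpha = 1e-8 / tree height` the `(1 - exp(-2 alpha t)) / (2 alpha)` factor
#' is evaluated by its second-order series for numerical continuity with the
#' Brownian limit `sigma2 * C`.
#'
#' @param tree A `"phylo"` object.
#' @param alpha Pull strength (per Myr), positive.
#' @param sigma2 Stochastic rate, positive.
#' @param cache Internal; precomputed tree structures.
#' @return A symmetric positive semi-definite tips x tips matrix.
#' @export
ou_covariance <- function(tree, alpha, sigma2, cache = tree_cache(tree)) {
  if (alpha <= 0) stop("alpha must be positive")
  if (sigma2 <= 0) stop("sigma2 must be positive")
  t <- cache$tij; d <- cache$D
  if (alpha < 1e-8 / cache$height) {
    ## series: (1 - exp(-2 a t)) / (2 a) = t (1 - a t + (2/3) a^2 t^2 - ...)
    base <- t * (1 - alpha * t + (2 / 3) * alpha^2 * t^2)
    V <- sigma2 * exp(-alpha * d) * base
  } else {
    V <- sigma2 / (2 * alpha) * exp(-alpha * d) * (1 - exp(-2 * alpha * t))
  }
  dimnames(V) <- dimnames(t)
  V
}

#' Hansen model log-likelihood
#'
#' Multivariate-normal log density of the tip data with mean
#' `hansen_weights() %*% theta` and covariance [ou_covariance()].
#'
#' @param tree A `"phylo"` object.
#' @param painting A `"regime_painting"`.
#' @param x Named numeric vector of tip values.
#' @param alpha,sigma2 OU parameters, positive.
#' @param theta Named numeric vector of optima, one per regime label of the
#'   painting (order-matched by name when named, by the painting's regime
#'   order otherwise).
#' @return Log-likelihood (scalar).
#' @export
hansen_loglik <- function(tree, painting, x, alpha, sigma2, theta) {
  cache <- tree_cache(tree)
  x <- align_traits(cache$tree, x)
  regimes <- attr(painting, "regimes")
  if (!is.null(names(theta))) {
    miss <- setdiff(regimes, names(theta))
    if (length(miss)) stop("theta missing for regime: ", paste(miss, collapse = ", "))
    theta <- theta[regimes]
  } else if (length(theta) != length(regimes)) {
    stop("need one theta per regime")
  }
  W <- hansen_weights(cache$tree, painting, alpha, cache)
  V <- ou_covariance(cache$tree, alpha, sigma2, cache)
  R <- tryCatch(chol(V), error = function(e)
    stop("OU covariance not positive definite: ", conditionMessage(e)))
  z <- backsolve(R, x - drop(W %*% theta), transpose = TRUE)
  -cache$n / 2 * log(2 * pi) - sum(log(diag(R))) - sum(z^2) / 2
}

## Profile likelihood machinery shared by fit_hansen() and the regime search.
## For a fixed alpha, V is computed with sigma2 = 1; theta is the GLS estimate
## and sigma2 the scaled residual quadratic form / n. Returns NULL when the
## candidate is numerically unusable (caller decides whether to error or skip).
hansen_profile <- function(cache, painting, x, alpha) {
  W <- hansen_weights(cache$tree, painting, alpha, cache)
  bad <- colSums(abs(W)) < 1e-12
  if (any(bad)) {
    return(list(error = paste("unreachable regime:",
                              paste(colnames(W)[bad], collapse = ", "))))
  }
  V1 <- ou_covariance(cache$tree, alpha, 1, cache)
  R <- tryCatch(chol(V1), error = function(e) NULL)
  if (is.null(R)) return(NULL)
  Wt <- backsolve(R, W, transpose = TRUE)
  xt <- backsolve(R, x, transpose = TRUE)
  qrW <- qr(Wt)
  if (qrW$rank < ncol(W)) {
    return(list(error = "regime weight matrix is rank deficient"))
  }
  theta <- qr.coef(qrW, xt)
  res <- xt - drop(Wt %*% theta)
  Q <- sum(res^2)
  n <- cache$n
  sigma2 <- Q / n
  if (!is.finite(sigma2) || sigma2 <= 0) return(NULL)
  ll <- -n / 2 * (log(2 * pi * sigma2) + 1) - sum(log(diag(R)))
  list(logLik = ll, theta = stats::setNames(theta, colnames(W)), sigma2 = sigma2)
}

## 1-D bounded search over log(alpha); ties resolved toward smaller alpha.
hansen_optimize <- function(cache, painting, x) {
  lo <- log(1e-8 / cache$height); hi <- log(1e3 / cache$height)
  neg <- function(la) {
    pr <- hansen_profile(cache, painting, x, exp(la))
    if (is.null(pr) || !is.null(pr$error)) return(Inf)
    -pr$logLik
  }
  ## optimize() warns whenever the objective is Inf (candidates rejected on
  ## purpose, e.g. unreachable regimes at extreme alpha); that is expected
  opt <- suppressWarnings(stats::optimize(neg, lower = lo, upper = hi, tol = 1e-8))
  cand <- c(lo, opt$minimum, hi)
  vals <- c(neg(lo), opt$objective, neg(hi))
  if (all(!is.finite(vals))) return(NULL)
  best <- min(vals[is.finite(vals)])
  pick <- which(is.finite(vals) & vals <= best + 1e-9)[1L]   # smallest alpha wins ties
  list(log_alpha = cand[pick], at_lower = pick == 1L)
}

#' Fit a multi-regime Ornstein-Uhlenbeck (Hansen) model to a trait
#'
#' Maximum likelihood over `(alpha, sigma2, theta)` for a fixed regime
#' painting. The optimization is one-dimensional over `log(alpha)` on
#' `[1e-8 / height, 1e3 / height]`: at each `alpha` the optima `theta` are the
#' generalized-least-squares estimates and `sigma2` is profiled analytically
#' from the residual quadratic form. Parameter count is
#' `2 + (number of regimes)`. Fits whose `alpha` sticks to the lower boundary
#' are flagged `bm_like`: the process is indistinguishable from Brownian
#' motion on this tree.
#'
#' @param tree A `"phylo"` object.
#' @param painting A `"regime_painting"`.
#' @param x Named numeric vector of tip values.
#' @return An object of class `c("hansen_fit", "evo_fit")` with components
#'   `alpha`, `sigma2`, `theta` (named by regime), `logLik`, `p`, `n`, `aicc`,
#'   `painting`, `bm_like`.
#' @examples
#' tr <- sim_tree(24, total_height = 10, seed = 1)
#' pp <- paint_clades(tr, list(list(label = "high", tips = tr$tip.label[1:8])))
#' x <- simulate_ou(tr, pp, alpha = 1, sigma2 = 0.5,
#'                  theta = c(root = 0, high = 3), seed = 2)
#' fit_hansen(tr, pp, x)
#' @export
fit_hansen <- function(tree, painting, x) {
  fit_hansen_cached(tree_cache(tree), painting, x)
}

#' @export
print.hansen_fit <- function(x, ...) {
  cat("Multi-regime OU (Hansen) fit (", x$n, " tips, ",
      length(x$theta), " regimes)\n", sep = "")
  cat(sprintf("  alpha  = %.6g /Myr (phylogenetic half-life %.3g Myr)\n",
              x$alpha, log(2) / x$alpha))
  cat(sprintf("  sigma2 = %.6g\n", x$sigma2))
  cat("  optima:\n")
  for (r in names(x$theta)) cat(sprintf("    %-12s %.6g\n", r, x$theta[[r]]))
  cat(sprintf("  logLik = %.4f, p = %d, AICc = %.4f\n", x$logLik, x$p, x$aicc))
  if (isTRUE(x$bm_like)) {
    cat("  [alpha at lower search bound: indistinguishable from Brownian motion]\n")
  }
  invisible(x)
}

#' @export
coef.hansen_fit <- function(object, ...) {
  c(alpha = object$alpha, sigma2 = object$sigma2,
    stats::setNames(object$theta, paste0("theta.", names(object$theta))))
}
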