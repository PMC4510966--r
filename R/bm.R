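## Brownian motion on a tree. The likelihood is computed by Felsenstein's
## pruning (independent-contrasts) algorithm rather than by forming the dense
## tip covariance matrix; the dense route is reserved for test oracles.

#' Brownian-motion covariance of the tips
#'
#' Returns the phylogenetic covariance structure `C`: `C[i, j]` is the length
#' of the shared root-to-MRCA path of tips `i` and `j`, and `C[i, i]` the
#' root-to-tip path length. Under Brownian motion with rate `sigma2` the tip
#' values are multivariate normal with covariance `sigma2 * C`.
#'
#' @param tree A `"phylo"` object.
#' @return A symmetric positive semi-definite matrix with tip labels as
#'   dimnames.
#' @export
bm_covariance <- function(tree) {
  tree_cache(tree)$tij
}

## One pruning pass; everything downstream (likelihood at any (sigma2, mu),
## the GLS mean, the profiled rate) is assembled from these pieces.
## Returns contrasts c_k with variances V_k (branch-length units), the root
## estimate (= GLS phylogenetic mean) and its residual variance v_root, and
## log det C = sum(log V_k) + log(v_root).
bm_prune <- function(tree, x) {
  x <- align_traits(tree, x)
  po <- ape::reorder.phylo(tree, "postorder")
  n <- ape::Ntip(po)
  nn <- n + po$Nnode
  mu <- numeric(nn); vext <- numeric(nn)
  mu[seq_len(n)] <- x
  bl <- numeric(nn)
  bl[po$edge[, 2L]] <- po$edge.length
  has <- logical(nn); has[seq_len(n)] <- TRUE
  contrasts <- numeric(0); cvars <- numeric(0)
  for (e in seq_len(nrow(po$edge))) {
    p <- po$edge[e, 1L]; ch <- po$edge[e, 2L]
    v_ch <- vext[ch] + bl[ch]
    if (!has[p]) {
      mu[p] <- mu[ch]; vext[p] <- v_ch; has[p] <- TRUE
    } else {
      v1 <- vext[p]; v2 <- v_ch
      contrasts <- c(contrasts, mu[p] - mu[ch])
      cvars <- c(cvars, v1 + v2)
      mu[p] <- (mu[p] * v2 + mu[ch] * v1) / (v1 + v2)
      vext[p] <- v1 * v2 / (v1 + v2)
    }
  }
  root <- po$edge[nrow(po$edge), 1L]
  list(contrasts = contrasts, cvars = cvars,
       mu_root = mu[root], v_root = vext[root],
       logdetC = sum(log(cvars)) + log(vext[root]), n = n)
}

#' Brownian-motion log-likelihood
#'
#' Log density of tip data under Brownian motion with rate `sigma2` and root
#' state `mu`: multivariate normal with mean `mu` and covariance
#' `sigma2 * C` (see [bm_covariance()]), evaluated by the pruning algorithm.
#'
#' @param tree A `"phylo"` object.
#' @param x Named numeric vector of tip values.
#' @param sigma2 Brownian rate (trait units squared per Myr), positive.
#' @param mu Root state (trait units).
#' @return Log-likelihood (scalar).
#' @export
bm_loglik <- function(tree, x, sigma2, mu) {
  if (sigma2 <= 0) stop("sigma2 must be positive")
  pr <- bm_prune(tree, x)
  Q <- sum(pr$contrasts^2 / pr$cvars) + (pr$mu_root - mu)^2 / pr$v_root
  -pr$n / 2 * log(2 * pi * sigma2) - pr$logdetC / 2 - Q / (2 * sigma2)
}

#' Fit Brownian motion to a trait by maximum likelihood
#'
#' The root state estimate is the generalized-least-squares phylogenetic mean
#' and the rate is the ML estimate (GLS residual quadratic form divided by the
#' number of tips). A constant trait gives a boundary fit (`sigma2` = 0),
#' flagged as degenerate.
#'
#' @param tree A `"phylo"` object with at least 3 tips.
#' @param x Named numeric vector of tip values.
#' @return An object of class `c("bm_fit", "evo_fit")` with components `mu`,
#'   `sigma2`, `logLik`, `p` (= 2), `n`, `aicc` and `degenerate`.
#' @examples
#' tr <- read_newick("((A:1,B:1):1,C:2);")
#' fit_bm(tr, c(A = 0.1, B = 0.3, C = 0.9))
#' @export
fit_bm <- function(tree, x) {
  if (ape::Ntip(tree) < 3) stop("need at least 3 tips")
  pr <- bm_prune(tree, x)
  mu <- pr$mu_root
  Q <- sum(pr$contrasts^2 / pr$cvars)
  sigma2 <- Q / pr$n
  degenerate <- sigma2 <= 0 || !is.finite(sigma2)
  ll <- if (degenerate) Inf else
    -pr$n / 2 * (log(2 * pi * sigma2) + 1) - pr$logdetC / 2
  p <- 2L
  out <- list(model = "BM", mu = mu, sigma2 = sigma2, logLik = ll, p = p,
              n = pr$n,
              aicc = if (degenerate) -Inf else aicc_or_na(ll, p, pr$n),
              tips = tree$tip.label, degenerate = degenerate)
  class(out) <- c("bm_fit", "evo_fit")
  out
}

#' @export
print.bm_fit <- function(x, ...) {
  cat("Brownian-motion fit (", x$n, " tips)\n", sep = "")
  cat(sprintf("  root state mu = %.6g\n  rate sigma2   = %.6g\n", x$mu, x$sigma2))
  cat(sprintf("  logLik = %.4f, p = %d, AICc = %.4f\n", x$logLik, x$p, x$aicc))
  if (x$degenerate) cat("  [degenerate: zero rate, constant trait]\n")
  invisible(x)
}

#' @export
logLik.evo_fit <- function(object, ...) {
  structure(object$logLik, df = object$p, nobs = object$n, class = "logLik")
}

#' @export
coef.bm_fit <- function(object, ...) c(mu = object$mu, sigma2 = object$sigma2)
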