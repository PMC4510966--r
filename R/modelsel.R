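## Model scoring and hypothesis comparison: finite-sample AIC, Akaike weights,
## and the shared-painting multivariate fit used for hypothesis testing and by
## the stepwise regime search. Traits are treated as independent given the
## painting, so the joint log-likelihood is the sum of per-trait fits and the
## joint AICc uses total logLik, total parameter count and n = tips x traits.

#' Finite-sample Akaike information criterion
#'
#' `AICc = -2 logL + 2 p + 2 p (p + 1) / (n - p - 1)`; requires
#' `n - p - 1 > 0`.
#'
#' @param logL Log-likelihood.
#' @param p Number of estimated parameters.
#' @param n Sample size.
#' @return AICc (scalar).
#' @export
aicc <- function(logL, p, n) {
  if (n - p - 1 <= 0) stop("n must exceed p + 1 (model too rich for the data)")
  -2 * logL + 2 * p + 2 * p * (p + 1) / (n - p - 1)
}

## NA instead of an error when the sample is too small to score; fit objects
## still report their estimates.
aicc_or_na <- function(logL, p, n) {
  if (n - p - 1 <= 0) return(NA_real_)
  aicc(logL, p, n)
}

#' Compare evolutionary model fits by AICc and Akaike weights
#'
#' All fits must be on the same tip set (and hence the same `n`). Weights are
#' `exp(-delta_i / 2)` normalized over the set; the best model has
#' `delta AICc = 0` by construction.
#'
#' @param fits A named list of `"evo_fit"` or `"multi_fit"` objects.
#' @return An object of class `"model_comparison"`: a data frame with columns
#'   `model`, `logLik`, `p`, `n`, `AICc`, `delta_AICc`, `weight`, sorted by
#'   AICc.
#' @export
compare_models <- function(fits) {
  if (length(fits) < 2) stop("need at least two fits to compare")
  if (is.null(names(fits)) || any(!nzchar(names(fits)))) {
    names(fits) <- paste0("model", seq_along(fits))
  }
  tipsets <- lapply(fits, function(f) sort(f$tips))
  for (i in seq_along(fits)[-1]) {
    if (!identical(tipsets[[i]], tipsets[[1]])) {
      stop("fits are on mismatched tip sets: ", names(fits)[i])
    }
  }
  ns <- vapply(fits, function(f) f$n, numeric(1))
  if (length(unique(ns)) != 1L) stop("fits have different sample sizes n")
  out <- data.frame(
    model = names(fits),
    logLik = vapply(fits, function(f) f$logLik, numeric(1)),
    p = vapply(fits, function(f) f$p, numeric(1)),
    n = ns,
    AICc = vapply(fits, function(f) f$aicc, numeric(1)),
    row.names = NULL
  )
  out$delta_AICc <- out$AICc - min(out$AICc)
  w <- exp(-out$delta_AICc / 2)
  out$weight <- w / sum(w)
  out <- out[order(out$AICc), ]
  rownames(out) <- NULL
  class(out) <- c("model_comparison", "data.frame")
  out
}

#' @export
print.model_comparison <- function(x, digits = 4, ...) {
  cat("Model comparison (AICc):\n")
  y <- x; class(y) <- "data.frame"
  y$logLik <- round(y$logLik, digits); y$AICc <- round(y$AICc, digits)
  y$delta_AICc <- round(y$delta_AICc, digits); y$weight <- round(y$weight, digits)
  print(y, row.names = FALSE)
  invisible(x)
}

#' Multivariate model fit with a shared regime painting
#'
#' Fits each trait column independently under the shared painting (Hansen
#' model) or under Brownian motion, and combines them: total log-likelihood is
#' the sum over traits, total parameter count the sum of per-trait counts, and
#' the joint AICc uses `n = tips * traits`. This is the unit of comparison for
#' multivariate evolutionary hypotheses and the objective of the stepwise
#' regime search.
#'
#' @param tree A `"phylo"` object.
#' @param painting A `"regime_painting"`; ignored for `model = "bm"`.
#' @param X Numeric matrix or data frame, taxa x traits, row names matching
#'   the tree tips.
#' @param model `"hansen"` (default) or `"bm"`.
#' @param cache Internal; precomputed tree structures.
#' @return An object of class `"multi_fit"` with per-trait `fits` and joint
#'   `logLik`, `p`, `n`, `aicc`.
#' @export
fit_multi <- function(tree, painting = NULL, X, model = c("hansen", "bm"),
                      cache = NULL) {
  model <- match.arg(model)
  if (is.null(cache)) cache <- tree_cache(tree)
  X <- align_traits(cache$tree, X)
  if (ncol(X) < 1) stop("need at least one trait")
  if (is.null(colnames(X))) colnames(X) <- paste0("trait", seq_len(ncol(X)))
  fits <- vector("list", ncol(X)); names(fits) <- colnames(X)
  for (j in seq_len(ncol(X))) {
    fits[[j]] <- if (model == "bm") {
      fit_bm(cache$tree, X[, j])
    } else {
      fit_hansen_cached(cache, painting, X[, j])
    }
  }
  logLik <- sum(vapply(fits, function(f) f$logLik, numeric(1)))
  p <- sum(vapply(fits, function(f) f$p, numeric(1)))
  n <- cache$n * ncol(X)
  out <- list(model = model, fits = fits, logLik = logLik, p = p, n = n,
              aicc = aicc(logLik, p, n), painting = painting,
              tips = cache$tree$tip.label, n_traits = ncol(X))
  class(out) <- "multi_fit"
  out
}

## fit_hansen with an externally supplied cache (hot path of the search).
fit_hansen_cached <- function(cache, painting, x) {
  k <- length(attr(painting, "regimes"))
  if (cache$n < k + 3) stop("need at least (regimes + 3) tips")
  x <- align_traits(cache$tree, x)
  opt <- hansen_optimize(cache, painting, x)
  if (is.null(opt)) {
    probe <- hansen_profile(cache, painting, x, 1 / cache$height)
    if (!is.null(probe$error)) stop("Hansen fit failed: ", probe$error)
    stop("Hansen fit failed: no usable alpha in the search interval")
  }
  alpha <- exp(opt$log_alpha)
  pr <- hansen_profile(cache, painting, x, alpha)
  if (!is.null(pr$error)) stop("Hansen fit failed: ", pr$error)
  p <- 2L + k
  out <- list(model = "OU", alpha = alpha, sigma2 = pr$sigma2, theta = pr$theta,
              logLik = pr$logLik, p = p, n = cache$n,
              aicc = aicc_or_na(pr$logLik, p, cache$n),
              painting = painting, tips = cache$tree$tip.label,
              bm_like = opt$at_lower)
  class(out) <- c("hansen_fit", "evo_fit")
  out
}

#' @export
print.multi_fit <- function(x, ...) {
  cat("Multivariate ", if (x$model == "bm") "Brownian-motion" else "Hansen",
      " fit: ", x$n_traits, " traits, ", length(x$tips), " tips\n", sep = "")
  cat(sprintf("  joint logLik = %.4f, p = %d, n = %d, AICc = %.4f\n",
              x$logLik, x$p, x$n, x$aicc))
  invisible(x)
}

#' @export
logLik.multi_fit <- function(object, ...) {
  structure(object$logLik, df = object$p, nobs = object$n, class = "logLik")
}

#' Serialize a model fit to JSON
#'
#' Writes the painting, per-trait parameters, and the fit scores in a plain
#' JSON form suitable for the pipeline manifest.
#'
#' @param fit A `"multi_fit"`, `"hansen_fit"` or `"bm_fit"`.
#' @param path Output file; if `NULL` the JSON string is returned.
#' @return The JSON string, invisibly when written to a file.
#' @export
fit_to_json <- function(fit, path = NULL) {
  as_params <- function(f) {
    if (inherits(f, "hansen_fit")) {
      list(alpha = f$alpha, sigma2 = f$sigma2, theta = as.list(f$theta))
    } else {
      list(mu = f$mu, sigma2 = f$sigma2)
    }
  }
  obj <- list(model_name = fit$model,
              painting = if (!is.null(fit$painting))
                list(root_regime = attr(fit$painting, "root_regime"),
                     edge_regimes = unclass(fit$painting)) else NULL,
              traits = if (inherits(fit, "multi_fit"))
                lapply(fit$fits, as_params) else as_params(fit),
              logL = fit$logLik, p = fit$p, n = fit$n, AICc = fit$aicc)
  s <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, null = "null")
  if (is.null(path)) return(s)
  writeLines(s, path)
  invisible(s)
}
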