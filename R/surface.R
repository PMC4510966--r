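## Stepwise, data-driven detection of adaptive-regime shifts, in the style of
## the surface algorithm: a forward phase adds one regime shift at a time on
## the branch that most improves the joint AICc of the shared-painting
## multivariate Hansen fit, and a backward phase then collapses regime pairs
## to a shared label when doing so improves AICc further -- the signature of
## convergent evolution. Everything is deterministic: ties among equal-AICc
## candidates go to the branch with the older parent node, then to the
## lexicographically smallest subtended tip set.

## Tie-break key for a candidate edge (larger age first, then tip-set string).
edge_tiebreak <- function(cache, e) {
  ages <- max(cache$Ti) - cache$depths
  tips <- sort(cache$tree$tip.label[cache$tips_under[[cache$tree$edge[e, 2L]]]])
  list(parent_age = ages[cache$tree$edge[e, 1L]],
       key = paste(tips, collapse = "|"))
}

## Evaluate fit_multi, returning NULL (and a log message) on numerical failure
## instead of aborting the search.
try_fit <- function(cache, painting, X, log_env, what) {
  f <- tryCatch(fit_multi(cache$tree, painting, X, cache = cache),
                error = function(e) conditionMessage(e))
  if (is.character(f) || !is.finite(f$aicc)) {
    log_env$skipped <- c(log_env$skipped,
                         paste0(what, ": ", if (is.character(f)) f else "non-finite AICc"))
    return(NULL)
  }
  f
}

#' Forward phase: stepwise addition of regime shifts by AICc
#'
#' Starts from a single-regime Ornstein-Uhlenbeck model (all branches
#' attracted to one peak) and repeatedly evaluates placing one new regime
#' shift on every branch not already carrying one; a shift relabels the branch
#' and all descendant branches not downstream of another shift. The best
#' candidate is accepted when it improves the joint AICc by more than
#' `min_improvement`; the phase stops otherwise. The root regime is the
#' baseline and the root itself carries no shift.
#'
#' @param tree A `"phylo"` object.
#' @param X Taxa x traits matrix (row names = tip labels).
#' @param min_improvement AICc units a candidate must improve by to be
#'   accepted (default 0: any improvement).
#' @param max_shifts Safety cap on the number of accepted shifts.
#' @return A list with `painting` (final `"regime_painting"`), `trace` (data
#'   frame of accepted steps with AICc before/after), `shift_edges`,
#'   `fit` (final `"multi_fit"`), and `skipped` (log of candidates dropped for
#'   numerical failure).
#' @export
forward_phase <- function(tree, X, min_improvement = 0,
                          max_shifts = ape::Ntip(tree)) {
  cache <- tree_cache(tree)
  X <- align_traits(cache$tree, X)
  log_env <- new.env(); log_env$skipped <- character(0)
  shifts <- integer(0); labels <- character(0)
  painting <- painting_from_shifts(cache$tree, shifts, labels)
  fit <- fit_multi(cache$tree, painting, X, cache = cache)
  trace <- list()
  step <- 0L
  while (length(shifts) < max_shifts && is.finite(min_improvement)) {
    cand_edges <- setdiff(seq_len(nrow(cache$tree$edge)), shifts)
    new_label <- paste0("r", length(shifts) + 1L)
    best <- NULL
    for (e in cand_edges) {
      pp <- painting_from_shifts(cache$tree, c(shifts, e), c(labels, new_label))
      f <- try_fit(cache, pp, X, log_env, paste("shift on edge", e))
      if (is.null(f)) next
      tb <- edge_tiebreak(cache, e)
      ## wide tie window: equivalent partitions (e.g. a root-child branch and
      ## its complement) agree in AICc only to float noise, and must fall
      ## through to the deterministic tie-break
      if (is.null(best) || f$aicc < best$aicc - 1e-7 ||
          (abs(f$aicc - best$aicc) <= 1e-7 &&
           (tb$parent_age > best$tb$parent_age + 1e-12 ||
            (abs(tb$parent_age - best$tb$parent_age) <= 1e-12 &&
             tb$key < best$tb$key)))) {
        best <- list(edge = e, fit = f, painting = pp, aicc = f$aicc, tb = tb)
      }
    }
    if (is.null(best) || !(fit$aicc - best$aicc > min_improvement)) break
    step <- step + 1L
    trace[[step]] <- data.frame(
      step = step, phase = "forward",
      detail = paste0("shift@edge", best$edge, "->", new_label),
      aicc_before = fit$aicc, aicc_after = best$aicc)
    shifts <- c(shifts, best$edge); labels <- c(labels, new_label)
    painting <- best$painting; fit <- best$fit
  }
  list(painting = painting, trace = do.call(rbind, trace),
       shift_edges = stats::setNames(shifts, labels), fit = fit,
       skipped = log_env$skipped)
}

#' Backward phase: collapse regimes to detect convergence
#'
#' Iteratively evaluates merging every unordered pair of non-root regime
#' labels (all branches of both take one shared label) and accepts the merge
#' that most improves the joint AICc, until no merge improves it by more than
#' `min_improvement`. A retained merged label records its member lineages: two
#' clades sharing one regime despite separate shifts is the model's signature
#' of convergent evolution.
#'
#' @param tree A `"phylo"` object.
#' @param X Taxa x traits matrix.
#' @param painting Starting `"regime_painting"`, typically from
#'   [forward_phase()].
#' @param min_improvement AICc units required to accept a merge.
#' @return A list with `painting`, `trace`, `fit`, `merges` (list of character
#'   vectors: the original labels pooled into each retained label), and
#'   `skipped`.
#' @export
backward_phase <- function(tree, X, painting, min_improvement = 0) {
  cache <- tree_cache(tree)
  X <- align_traits(cache$tree, X)
  log_env <- new.env(); log_env$skipped <- character(0)
  fit <- fit_multi(cache$tree, painting, X, cache = cache)
  root <- attr(painting, "root_regime")
  members <- stats::setNames(as.list(attr(painting, "regimes")),
                             attr(painting, "regimes"))
  trace <- list(); step <- 0L
  repeat {
    labs <- setdiff(attr(painting, "regimes"), root)
    if (length(labs) < 2) break
    best <- NULL
    pairs <- utils::combn(sort(labs), 2)
    for (j in seq_len(ncol(pairs))) {
      a <- pairs[1, j]; b <- pairs[2, j]
      er <- unclass(painting)
      er[er == b] <- a
      pp <- regime_painting(cache$tree, er, root)
      f <- try_fit(cache, pp, X, log_env, paste("merge", a, "+", b))
      if (is.null(f)) next
      if (is.null(best) || f$aicc < best$aicc - 1e-9) {
        best <- list(a = a, b = b, fit = f, painting = pp, aicc = f$aicc)
      }
    }
    if (is.null(best) || !(fit$aicc - best$aicc > min_improvement)) break
    step <- step + 1L
    trace[[step]] <- data.frame(
      step = step, phase = "backward",
      detail = paste0("merge:", best$a, "+", best$b),
      aicc_before = fit$aicc, aicc_after = best$aicc)
    members[[best$a]] <- c(members[[best$a]], members[[best$b]])
    members[[best$b]] <- NULL
    painting <- best$painting; fit <- best$fit
  }
  list(painting = painting, trace = do.call(rbind, trace), fit = fit,
       merges = members, skipped = log_env$skipped)
}

#' Data-driven regime search (forward shift addition, backward collapse)
#'
#' Runs [forward_phase()] then [backward_phase()] and returns the final
#' painting, the concatenated search trace, and the final multivariate fit.
#' The search is deterministic given its inputs.
#'
#' @inheritParams forward_phase
#' @return An object of class `"surface_fit"` with components `painting`,
#'   `trace`, `fit`, `forward`, `backward`, `n_regimes`, `convergent`
#'   (merged labels whose pooled membership spans more than one forward
#'   shift).
#' @examples
#' tr <- sim_tree(32, total_height = 10, seed = 7)
#' pp <- paint_clades(tr, list(list(label = "up", tips = tr$tip.label[1:10])))
#' x <- simulate_ou(tr, pp, alpha = 1.5, sigma2 = 0.4,
#'                  theta = c(root = 0, up = 4), seed = 8)
#' sf <- surface_search(tr, cbind(x = x))
#' sf$n_regimes
#' @export
surface_search <- function(tree, X, min_improvement = 0,
                           max_shifts = ape::Ntip(tree)) {
  if (is.null(dim(X))) X <- cbind(trait = X)
  fw <- forward_phase(tree, X, min_improvement, max_shifts)
  bw <- backward_phase(tree, X, fw$painting, min_improvement)
  trace <- rbind(fw$trace, bw$trace)
  if (!is.null(trace)) trace$step <- seq_len(nrow(trace))
  convergent <- Filter(function(m) length(m) > 1, bw$merges)
  out <- list(painting = bw$painting, trace = trace, fit = bw$fit,
              forward = fw, backward = bw,
              n_regimes = length(attr(bw$painting, "regimes")),
              convergent = convergent)
  class(out) <- "surface_fit"
  out
}

#' @export
print.surface_fit <- function(x, ...) {
  cat("Stepwise regime search\n")
  nf <- if (is.null(x$forward$trace)) 0L else nrow(x$forward$trace)
  nb <- if (is.null(x$backward$trace)) 0L else nrow(x$backward$trace)
  cat("  forward shifts accepted: ", nf, "\n", sep = "")
  cat("  backward merges accepted: ", nb, "\n", sep = "")
  cat("  final regimes: ", x$n_regimes, "\n", sep = "")
  if (length(x$convergent)) {
    for (lab in names(x$convergent)) {
      cat("  convergent regime ", lab, " pools: ",
          paste(x$convergent[[lab]], collapse = ", "), "\n", sep = "")
    }
  }
  cat(sprintf("  final joint AICc: %.4f\n", x$fit$aicc))
  invisible(x)
}

#' Export a search trace as JSON lines
#'
#' One accepted step per line, with the phase, the mutated unit and the AICc
#' before and after.
#'
#' @param x A `"surface_fit"` (or a trace data frame).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
trace_to_jsonl <- function(x, path) {
  trace <- if (inherits(x, "surface_fit")) x$trace else x
  con <- file(path, "w"); on.exit(close(con))
  if (!is.null(trace)) {
    for (i in seq_len(nrow(trace))) {
      writeLines(jsonlite::toJSON(as.list(trace[i, ]), auto_unbox = TRUE,
                                  digits = NA), con)
    }
  }
  invisible(path)
}

#' Export a painting as a branch table
#'
#' One row per branch keyed by child-node id, with the regime label.
#'
#' @param tree The tree the painting belongs to.
#' @param painting A `"regime_painting"`.
#' @return A data frame with columns `parent`, `child`, `regime`.
#' @export
painting_table <- function(tree, painting) {
  data.frame(parent = tree$edge[, 1L], child = tree$edge[, 2L],
             regime = unclass(painting))
}
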