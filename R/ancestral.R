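## Maximum-likelihood ancestral states under Brownian motion, with estimate
## variances and 95% confidence intervals, and the phylomorphospace scaffold
## (node coordinates in PC space plus the tree's edge list).
##
## The ML point estimates solve the branch-length-weighted harmonic system:
## each internal state is the 1/branch-length-weighted average of its
## neighbours, equivalently the minimizer of sum (delta x)^2 / branch length
## (squared-change parsimony accounting for branch length). Variances are the
## conditional (GLS) variances of the internal states given the tips, with the
## ML Brownian rate from fit_bm() plugged in.

## Graph Laplacian of the tree with edge weights 1 / branch length,
## partitioned into internal-internal and internal-tip blocks.
tree_laplacian <- function(tree) {
  n <- ape::Ntip(tree); m <- tree$Nnode; N <- n + m
  w <- 1 / tree$edge.length
  L <- matrix(0, N, N)
  for (e in seq_len(nrow(tree$edge))) {
    p <- tree$edge[e, 1L]; ch <- tree$edge[e, 2L]
    L[p, p] <- L[p, p] + w[e]; L[ch, ch] <- L[ch, ch] + w[e]
    L[p, ch] <- L[p, ch] - w[e]; L[ch, p] <- L[ch, p] - w[e]
  }
  list(LII = L[(n + 1):N, (n + 1):N, drop = FALSE],
       LIT = L[(n + 1):N, 1:n, drop = FALSE], n = n, m = m)
}

#' Maximum-likelihood ancestral states under Brownian motion
#'
#' Estimates the trait value at every internal node by maximizing the joint
#' Brownian-motion likelihood over internal states, which reduces to a sparse
#' linear solve of the branch-length-weighted harmonic system; the estimates
#' are identical to squared-change parsimony weighted by branch length.
#' Variances are the conditional variances of internal states given the tip
#' data, scaled by the ML rate estimate, and 95% confidence intervals are
#' `estimate +/- 1.96 * sqrt(variance)`. Tips are reported with their observed
#' values and zero variance. Fossil (non-contemporaneous) tips participate as
#' ordinary tips.
#'
#' @param tree A `"phylo"` object with at least 2 tips.
#' @param x Named numeric vector of tip values.
#' @return An object of class `"ancestral_recon"`: a data frame with one row
#'   per node (`node`, `is_tip`, `label`, `estimate`, `variance`, `ci_lower`,
#'   `ci_upper`) and attributes `sigma2` and `tree`.
#' @examples
#' tr <- read_newick("((A:1,B:1):1,C:2);")
#' ml_ancestral_states(tr, c(A = 0, B = 2, C = 1))
#' @export
ml_ancestral_states <- function(tree, x) {
  validate_tree(tree)
  if (ape::Ntip(tree) < 2) stop("need at least 2 tips")
  x <- align_traits(tree, x)
  lap <- tree_laplacian(tree)
  est <- tryCatch(solve(lap$LII, -lap$LIT %*% x),
                  error = function(e) stop("singular reconstruction system: ",
                                           conditionMessage(e)))
  pr <- bm_prune(tree, x)
  sigma2 <- sum(pr$contrasts^2 / pr$cvars) / pr$n
  vars <- sigma2 * diag(solve(lap$LII))
  n <- lap$n; m <- lap$m
  out <- data.frame(
    node = seq_len(n + m),
    is_tip = c(rep(TRUE, n), rep(FALSE, m)),
    label = c(tree$tip.label, rep(NA_character_, m)),
    estimate = c(unname(x), drop(est)),
    variance = c(rep(0, n), pmax(vars, 0))
  )
  out <- add_ci(out)
  attr(out, "sigma2") <- sigma2
  attr(out, "tree") <- tree
  class(out) <- c("ancestral_recon", "data.frame")
  out
}

add_ci <- function(recon, level = 0.95) {
  if (any(recon$variance < 0)) stop("negative reconstruction variance")
  z <- stats::qnorm(1 - (1 - level) / 2)
  recon$ci_lower <- recon$estimate - z * sqrt(recon$variance)
  recon$ci_upper <- recon$estimate + z * sqrt(recon$variance)
  recon
}

#' Recompute confidence bounds on an ancestral reconstruction
#'
#' @param recon An `"ancestral_recon"`.
#' @param level Confidence level (default 0.95, i.e. estimate +/- 1.96 sd).
#' @return The reconstruction with updated `ci_lower` / `ci_upper`.
#' @export
ancestral_ci <- function(recon, level = 0.95) {
  add_ci(recon, level)
}

#' @export
print.ancestral_recon <- function(x, ...) {
  cat("ML ancestral reconstruction:", sum(x$is_tip), "tips,",
      sum(!x$is_tip), "internal nodes",
      sprintf("(sigma2 = %.6g)\n", attr(x, "sigma2")))
  print.data.frame(utils::head(x[!x$is_tip, ], 10), row.names = FALSE)
  if (sum(!x$is_tip) > 10) cat("  ...\n")
  invisible(x)
}

#' Build a phylomorphospace
#'
#' Places every node of the tree in the plane of the first two principal
#' components: tips at their observed scores, internal nodes at the ML
#' ancestral reconstruction of each PC axis (reconstruction is linear, so
#' reconstructing scores directly is equivalent to reconstructing traits and
#' projecting). Edges mirror the tree's branches, so the phylogeny can be
#' drawn through the morphospace.
#'
#' @param tree A `"phylo"` object.
#' @param scores Taxa x >=2 matrix of PC scores (row names = tip labels);
#'   the first two columns are used.
#' @return An object of class `"phylomorphospace"`: list with `nodes` (per
#'   node: coordinates, variances, CI bounds per axis) and `edges`
#'   (`parent`, `child`).
#' @export
build_phylomorphospace <- function(tree, scores) {
  scores <- align_traits(tree, scores)
  if (ncol(scores) < 2) stop("need at least two score axes")
  ax <- colnames(scores)[1:2]
  r1 <- ml_ancestral_states(tree, scores[, 1])
  r2 <- ml_ancestral_states(tree, scores[, 2])
  nodes <- data.frame(
    node = r1$node, is_tip = r1$is_tip, label = r1$label,
    x = r1$estimate, y = r2$estimate,
    x_var = r1$variance, y_var = r2$variance,
    x_ci_lower = r1$ci_lower, x_ci_upper = r1$ci_upper,
    y_ci_lower = r2$ci_lower, y_ci_upper = r2$ci_upper
  )
  out <- list(nodes = nodes,
              edges = data.frame(parent = tree$edge[, 1L],
                                 child = tree$edge[, 2L]),
              axes = ax, tree = tree)
  class(out) <- "phylomorphospace"
  out
}

#' @export
print.phylomorphospace <- function(x, ...) {
  cat("Phylomorphospace on axes", paste(x$axes, collapse = ", "), "\n")
  cat(" ", sum(x$nodes$is_tip), "tips,", sum(!x$nodes$is_tip),
      "internal nodes,", nrow(x$edges), "edges\n")
  invisible(x)
}

#' Coordinates (with CIs) of the last common ancestor of two tips
#'
#' Retrieves the phylomorphospace row of the most recent common ancestor of a
#' tip pair -- e.g. the chimpanzee-human LCA whose position and 95% CI the
#' phylomorphospace is built to display.
#'
#' @param pms A `"phylomorphospace"`.
#' @param tip1,tip2 Tip labels.
#' @return The one-row `nodes` data frame for the LCA.
#' @export
lca_coordinates <- function(pms, tip1, tip2) {
  node <- resolve_node(pms$tree, c(tip1, tip2))
  pms$nodes[pms$nodes$node == node, , drop = FALSE]
}

#' Export a phylomorphospace as CSV tables
#'
#' @param pms A `"phylomorphospace"`.
#' @param nodes_path,edges_path Output CSV paths.
#' @return Invisibly, the two paths.
#' @export
phylomorphospace_to_csv <- function(pms, nodes_path, edges_path) {
  utils::write.csv(pms$nodes, nodes_path, row.names = FALSE)
  utils::write.csv(pms$edges, edges_path, row.names = FALSE)
  invisible(c(nodes_path, edges_path))
}
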