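## Internal per-tree cache of the quantities every likelihood evaluation needs:
## node depths, tip depths, the matrix of shared root-to-MRCA path lengths, and
## the root-to-tip path segments (edge, start depth, end depth) that the Hansen
## regime-weight matrix integrates over. Computed once per tree and passed down
## by the fitting and search routines, which evaluate thousands of candidate
## models on a fixed tree.

tree_cache <- function(tree) {
  validate_tree(tree)
  tree <- ape::reorder.phylo(tree, "cladewise")
  n <- ape::Ntip(tree)
  depths <- node_depths(tree)
  Ti <- depths[seq_len(n)]

  ## tips under each node and shared-path-length (MRCA depth) matrix
  po <- ape::reorder.phylo(tree, "postorder")
  tips_under <- vector("list", n + tree$Nnode)
  for (i in seq_len(n)) tips_under[[i]] <- i
  tij <- matrix(0, n, n)
  for (e in seq_len(nrow(po$edge))) {
    p <- po$edge[e, 1L]; ch <- po$edge[e, 2L]
    if (!is.null(tips_under[[p]])) {
      a <- tips_under[[p]]; b <- tips_under[[ch]]
      tij[a, b] <- depths[p]; tij[b, a] <- depths[p]
    }
    tips_under[[p]] <- c(tips_under[[p]], tips_under[[ch]])
  }
  diag(tij) <- Ti
  dimnames(tij) <- list(tree$tip.label, tree$tip.label)

  ## root-to-tip path segments, one row per (tip, edge-on-its-path)
  nseg <- 0L
  for (e in seq_len(nrow(tree$edge))) {
    nseg <- nseg + length(tips_under[[tree$edge[e, 2L]]])
  }
  seg_tip <- integer(nseg); seg_edge <- integer(nseg)
  k <- 0L
  for (e in seq_len(nrow(tree$edge))) {
    tt <- tips_under[[tree$edge[e, 2L]]]
    idx <- k + seq_along(tt)
    seg_tip[idx] <- tt; seg_edge[idx] <- e
    k <- k + length(tt)
  }
  list(tree = tree, n = n, depths = depths, Ti = Ti, tij = tij,
       D = outer(Ti, Ti, "+") - 2 * tij, height = max(Ti),
       seg_tip = seg_tip, seg_edge = seg_edge,
       seg_start = depths[tree$edge[seg_edge, 1L]],
       seg_end = depths[tree$edge[seg_edge, 2L]],
       seg_T = Ti[seg_tip],
       tips_under = tips_under)
}

## Order a named trait vector (or matrix rows) by the tree's tips.
align_traits <- function(tree, x) {
  labs <- tree$tip.label
  if (is.matrix(x) || is.data.frame(x)) {
    x <- as.matrix(x)
    if (is.null(rownames(x))) stop("trait matrix must have taxa as row names")
    miss <- setdiff(labs, rownames(x))
    if (length(miss)) stop("traits missing for tips: ", paste(miss, collapse = ", "))
    return(x[labs, , drop = FALSE])
  }
  if (is.null(names(x))) stop("trait vector must be named by taxa")
  miss <- setdiff(labs, names(x))
  if (length(miss)) stop("traits missing for tips: ", paste(miss, collapse = ", "))
  x[labs]
}
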