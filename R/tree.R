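## Rooted, time-calibrated trees. We use ape's "phylo" representation throughout;
## the helpers here add the validation, age bookkeeping and fossil-grafting
## conventions the comparative analyses rely on. Ages are measured backward from
## the present: extant tips sit at age 0, fossil tips at positive age, and the
## root at age = tree height (Myr).

#' Read a rooted time-calibrated tree from Newick
#'
#' Parses a Newick string (or a file containing one) into an [ape::read.tree()]
#' `"phylo"` object and validates it for comparative analysis: the tree must be
#' rooted and strictly bifurcating, every non-root branch must carry a strictly
#' positive length, and tip labels must be unique and non-empty. Zero-length
#' branches are rejected because downstream Ornstein-Uhlenbeck weight
#' computations divide by path segments.
#'
#' @param text A Newick string, or the path of a file whose contents are one.
#' @return An object of class `"phylo"`.
#' @seealso [write_newick()], [validate_tree()]
#' @examples
#' tr <- read_newick("((A:1,B:1):1,C:2);")
#' is_ultrametric(tr)
#' @export
read_newick <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  if (!grepl("(", text, fixed = TRUE)) {
    if (!file.exists(text)) stop("not a Newick string and no such file: ", text)
    text <- paste(readLines(text, warn = FALSE), collapse = "")
  }
  tree <- tryCatch(ape::read.tree(text = text),
                   error = function(e) stop("Newick parse error: ", conditionMessage(e)))
  if (is.null(tree)) stop("Newick parse error: string could not be parsed: ", text)
  validate_tree(tree)
  if (!ape::is.binary(tree)) {
    stop("tree is not strictly bifurcating; resolve polytomies before analysis")
  }
  tree
}

#' Write a tree to Newick
#'
#' @param tree A `"phylo"` object.
#' @param file Optional path; if `NULL` the Newick string is returned.
#' @return The Newick string, invisibly when written to a file.
#' @export
write_newick <- function(tree, file = NULL) {
  validate_tree(tree)
  s <- ape::write.tree(tree, digits = 12)
  if (is.null(file)) return(s)
  writeLines(s, file)
  invisible(s)
}

#' Validate a phylogeny for comparative analysis
#'
#' Checks the invariants assumed everywhere in the package: rooted binary
#' topology, unique non-empty tip labels, and strictly positive branch lengths.
#'
#' @param tree A `"phylo"` object.
#' @return `tree`, invisibly.
#' @export
validate_tree <- function(tree) {
  if (!inherits(tree, "phylo")) stop("not a \"phylo\" object")
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  if (anyNA(tree$edge.length)) stop("tree has missing branch lengths")
  if (any(tree$edge.length <= 0)) {
    bad <- which(tree$edge.length <= 0)[1L]
    stop("non-positive branch length on edge above node ", tree$edge[bad, 2L])
  }
  labs <- tree$tip.label
  if (any(!nzchar(labs))) stop("empty tip label")
  if (anyDuplicated(labs)) {
    stop("duplicate tip label: ", labs[duplicated(labs)][1L])
  }
  ## exactly one root: one node that is a parent but never a child
  ## (ape::is.rooted would reject star trees, which the analyses support)
  roots <- setdiff(unique(tree$edge[, 1L]), tree$edge[, 2L])
  if (length(roots) != 1L) stop("tree is not rooted (found ", length(roots), " roots)")
  if (anyDuplicated(tree$edge[, 2L])) stop("node with more than one parent")
  invisible(tree)
}

#' Node depths, ages and tree height
#'
#' `node_depths()` returns the root-to-node path length for every node (tips
#' first, then internal nodes, in ape numbering). `node_ages()` converts depths
#' to ages measured backward from the present, with the present defined by the
#' deepest tip (extant tips at age 0, fossil tips positive). `tree_height()` is
#' the root age.
#'
#' @param tree A `"phylo"` object.
#' @return A numeric vector over nodes (`node_depths`, `node_ages`) or a single
#'   number (`tree_height`).
#' @export
node_depths <- function(tree) {
  ape::node.depth.edgelength(tree)
}

#' @rdname node_depths
#' @export
node_ages <- function(tree) {
  d <- node_depths(tree)
  max(d[seq_len(ape::Ntip(tree))]) - d
}

#' @rdname node_depths
#' @export
tree_height <- function(tree) {
  max(node_depths(tree)[seq_len(ape::Ntip(tree))])
}

#' Is a tree ultrametric?
#'
#' All tips equidistant from the root, up to a relative tolerance. Trees with
#' grafted fossil tips are expected to fail this predicate; none of the model
#' machinery assumes ultrametricity.
#'
#' @param tree A `"phylo"` object.
#' @param tol Relative tolerance on root-to-tip path spread.
#' @return Logical scalar.
#' @export
is_ultrametric <- function(tree, tol = 1e-8) {
  d <- node_depths(tree)[seq_len(ape::Ntip(tree))]
  diff(range(d)) <= tol * max(d)
}

## Resolve a lineage specifier to a node id. A specifier is either a single tip
## label (the tip itself) or a character vector of >= 2 tip labels (their MRCA).
resolve_node <- function(tree, spec) {
  if (!is.character(spec) || length(spec) < 1L) {
    stop("lineage specifier must be a character vector of tip labels")
  }
  miss <- setdiff(spec, tree$tip.label)
  if (length(miss)) stop("unknown tip label in specifier: ", paste(miss, collapse = ", "))
  if (length(spec) == 1L) return(match(spec, tree$tip.label))
  ape::getMRCA(tree, spec)
}

## Edge index of the branch subtending (rootward of) a node; NA for the root.
stem_edge <- function(tree, node) {
  e <- which(tree$edge[, 2L] == node)
  if (!length(e)) NA_integer_ else e
}

#' Graft a fossil tip onto a lineage with a ghost lineage
#'
#' Attaches a new tip of age `fossil_age` to the branch subtending the host
#' lineage. By convention the attachment node sits `ghost` Myr (default 1)
#' above the fossil's age, so the fossil hangs from a 1-Myr ghost lineage; an
#' explicit `attach_age` overrides this when the host branch does not span
#' `fossil_age + ghost` (for instance, a 9.6-Myr fossil attached to a
#' great-ape stem that is everywhere older). All pre-existing path lengths are
#' preserved.
#'
#' @param tree A `"phylo"` object.
#' @param fossil_name Tip label for the fossil.
#' @param fossil_age Age of the fossil tip (Myr before present).
#' @param host A lineage specifier: one tip label (attach along its stem) or a
#'   vector of tip labels (attach along the stem of their MRCA).
#' @param ghost Ghost-lineage length in Myr used to place the default
#'   attachment node at `fossil_age + ghost`.
#' @param attach_age Optional explicit attachment-node age (Myr); must lie
#'   strictly within the age span of the host branch and above `fossil_age`.
#' @return A `"phylo"` object with one extra tip.
#' @examples
#' tr <- read_newick("((A:2,B:2):5,C:7);")
#' g <- graft_fossil(tr, "foss", fossil_age = 3, host = c("A", "B"))
#' node_ages(g)[match("foss", g$tip.label)]
#' @export
graft_fossil <- function(tree, fossil_name, fossil_age, host,
                         ghost = 1, attach_age = NULL) {
  validate_tree(tree)
  if (fossil_name %in% tree$tip.label) stop("tip label already present: ", fossil_name)
  if (fossil_age < 0) stop("fossil age must be non-negative")
  node <- resolve_node(tree, host)
  e <- stem_edge(tree, node)
  if (is.na(e)) stop("cannot attach along the root: host lineage has no stem branch")
  ages <- node_ages(tree)
  lo <- ages[tree$edge[e, 2L]]   # younger end of host branch
  hi <- ages[tree$edge[e, 1L]]   # older end
  if (is.null(attach_age)) attach_age <- fossil_age + ghost
  if (attach_age <= fossil_age) stop("attachment age must exceed the fossil age")
  if (attach_age <= lo || attach_age >= hi) {
    stop(sprintf(paste0("attachment age %.6g Myr outside the host branch span ",
                        "(%.6g, %.6g) for fossil '%s'"),
                 attach_age, lo, hi, fossil_name))
  }
  tip <- list(edge = matrix(c(2L, 1L), 1L, 2L), tip.label = fossil_name,
              edge.length = attach_age - fossil_age, Nnode = 1L)
  class(tip) <- "phylo"
  out <- ape::bind.tree(tree, tip, where = node, position = attach_age - lo)
  out <- ape::reorder.phylo(out, "cladewise")
  validate_tree(out)
  out
}

#' Three alternative placements of a 9.6-Myr great-ape fossil
#'
#' The late-Miocene ape of the study has a contested phylogenetic position, so
#' the analyses are repeated on three trees: the fossil as a stem great ape, a
#' stem pongine, or a stem hominine. The pongine and hominine variants attach
#' the tip at `fossil_age + 1` Myr; the stem-great-ape variant attaches 1 Myr
#' above the crown great-ape node, because that stem branch is everywhere older
#' than `fossil_age + 1` on any standard anthropoid chronogram (the ghost
#' lineage is correspondingly longer).
#'
#' @param tree A `"phylo"` object containing the great-ape clade.
#' @param fossil_name Tip label (default `"Hispanopithecus_laietanus"`).
#' @param fossil_age Age of the tip in Myr (default 9.6).
#' @param pongo,homo,gorilla Tip labels (or specifier vectors) locating the
#'   orangutan, human and gorilla lineages; defaults match
#'   [packaged_anthropoid_tree()].
#' @return A named list of three `"phylo"` objects:
#'   `stem_great_ape`, `stem_pongine`, `stem_hominine`.
#' @export
make_hispanopithecus_trees <- function(tree,
                                       fossil_name = "Hispanopithecus_laietanus",
                                       fossil_age = 9.6,
                                       pongo = c("Pongo_abelii", "Pongo_pygmaeus"),
                                       homo = "Homo_sapiens",
                                       gorilla = c("Gorilla_gorilla", "Gorilla_beringei")) {
  pongo <- intersect(pongo, tree$tip.label)
  gorilla <- intersect(gorilla, tree$tip.label)
  if (!length(pongo) || !length(gorilla) || !all(homo %in% tree$tip.label)) {
    stop("required lineages absent: need orangutan, gorilla and human tips")
  }
  great_apes <- c(pongo, gorilla, homo)
  ages <- node_ages(tree)
  crown_hominid <- ages[ape::getMRCA(tree, great_apes)]
  list(
    stem_great_ape = graft_fossil(tree, fossil_name, fossil_age, great_apes,
                                  attach_age = crown_hominid + 1),
    stem_pongine = graft_fossil(tree, fossil_name, fossil_age, pongo),
    stem_hominine = graft_fossil(tree, fossil_name, fossil_age,
                                 c(gorilla, homo))
  )
}

## ---------------------------------------------------------------------------
## Regime paintings

#' Regime paintings
#'
#' A regime painting assigns every branch of a tree to an adaptive regime; it
#' is the unit the stepwise regime search mutates and the parameterization the
#' multi-regime Ornstein-Uhlenbeck model reads its optima from. Internally a
#' painting is a character vector over the rows of `tree$edge`, plus the regime
#' of the root.
#'
#' `regime_painting()` constructs a painting from an explicit per-edge label
#' vector; [paint_clades()] and [painting_from_shifts()] are the usual ways to
#' build one.
#'
#' @param tree A `"phylo"` object.
#' @param edge_regimes Character vector of regime labels, one per row of
#'   `tree$edge`.
#' @param root_regime Regime label of the root.
#' @return An object of class `"regime_painting"`: the per-edge label vector
#'   with attributes `root_regime` and `regimes` (ordered unique label set).
#' @export
regime_painting <- function(tree, edge_regimes, root_regime) {
  validate_tree(tree)
  if (length(edge_regimes) != nrow(tree$edge)) {
    stop("painting must assign exactly one regime to every branch")
  }
  edge_regimes <- as.character(edge_regimes)
  if (anyNA(edge_regimes) || any(!nzchar(edge_regimes))) stop("empty regime label")
  regimes <- unique(c(root_regime, edge_regimes))
  structure(edge_regimes, root_regime = as.character(root_regime),
            regimes = regimes, class = "regime_painting")
}

#' @export
print.regime_painting <- function(x, ...) {
  cat("Regime painting:", length(x), "branches,",
      length(attr(x, "regimes")), "regimes\n")
  cat("  root regime:", attr(x, "root_regime"), "\n")
  tab <- table(factor(unclass(x), levels = attr(x, "regimes")))
  for (r in names(tab)) cat(sprintf("  %-12s %d branches\n", r, tab[[r]]))
  invisible(x)
}

#' Paint a tree from regime shifts on branches
#'
#' A shift on branch *b* relabels *b* and every descendant branch that is not
#' downstream of another shift ("sticky" inheritance); branches above all
#' shifts keep the root regime.
#'
#' @param tree A `"phylo"` object.
#' @param shift_edges Integer indices into the rows of `tree$edge`.
#' @param shift_labels Regime labels, one per shift.
#' @param root_regime Label of the baseline (root) regime.
#' @return A `"regime_painting"`.
#' @export
painting_from_shifts <- function(tree, shift_edges, shift_labels,
                                 root_regime = "root") {
  validate_tree(tree)
  stopifnot(length(shift_edges) == length(shift_labels))
  if (anyDuplicated(shift_edges)) stop("two shifts on one branch")
  tree <- ape::reorder.phylo(tree, "cladewise")   # parents before children
  nn <- ape::Ntip(tree) + tree$Nnode
  node_reg <- rep(NA_character_, nn)
  root <- ape::Ntip(tree) + 1L
  node_reg[root] <- root_regime
  edge_reg <- character(nrow(tree$edge))
  shift_at <- rep(NA_character_, nrow(tree$edge))
  shift_at[shift_edges] <- as.character(shift_labels)
  for (e in seq_len(nrow(tree$edge))) {
    p <- tree$edge[e, 1L]; ch <- tree$edge[e, 2L]
    edge_reg[e] <- if (!is.na(shift_at[e])) shift_at[e] else node_reg[p]
    node_reg[ch] <- edge_reg[e]
  }
  regime_painting(tree, edge_reg, root_regime)
}

#' Paint clades with named regimes
#'
#' Each specification assigns a regime label to a lineage (its stem branch and
#' all descendant branches). Nested specifications follow an innermost-wins
#' rule; branches outside every specified clade keep the root regime. A
#' specification whose tips cover the whole tree relabels the root regime
#' itself, yielding a uniform painting.
#'
#' @param tree A `"phylo"` object.
#' @param clade_specs A list of `list(label = , tips = )` entries: `tips` is a
#'   lineage specifier as in [graft_fossil()]. Several entries may share one
#'   label (a convergent regime painted on disjoint clades).
#' @param root_regime Baseline regime label.
#' @return A `"regime_painting"`.
#' @examples
#' tr <- read_newick("(((A:1,B:1):1,C:2):1,D:3);")
#' paint_clades(tr, list(list(label = "fast", tips = c("A", "B"))))
#' @export
paint_clades <- function(tree, clade_specs, root_regime = "root") {
  validate_tree(tree)
  root <- ape::Ntip(tree) + 1L
  edges <- integer(0); labels <- character(0)
  for (spec in clade_specs) {
    if (is.null(spec$label) || is.null(spec$tips)) {
      stop("each clade spec needs $label and $tips")
    }
    node <- resolve_node(tree, spec$tips)
    if (node == root) { root_regime <- spec$label; next }
    edges <- c(edges, stem_edge(tree, node))
    labels <- c(labels, spec$label)
  }
  ## innermost-wins is automatic: painting_from_shifts propagates rootward-
  ## to-tipward, so a shift nested inside another overrides it downstream
  painting_from_shifts(tree, edges, labels, root_regime = root_regime)
}

#' Read clade/regime specifications from a JSON config
#'
#' The JSON file holds a list of `{"label": ..., "tips": [...]}` objects, the
#' external form of the `clade_specs` argument of [paint_clades()].
#'
#' @param path JSON file path.
#' @return A list suitable for [paint_clades()].
#' @export
read_clade_specs <- function(path) {
  specs <- jsonlite::read_json(path, simplifyVector = FALSE)
  lapply(specs, function(s) list(label = as.character(s$label),
                                 tips = vapply(s$tips, as.character, character(1))))
}
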