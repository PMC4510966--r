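## Generators for trees and trait data with the statistical structure the
## comparative analyses assume: clade-structured multi-regime OU evolution of
## taxon-mean log shape ratios, specimen-level multiplicative (lognormal)
## measurement scatter, and body mass linked to lengths by cube-root scaling.
## They replace the museum specimen measurements the real study rests on, so
## every generator is bit-reproducible given its seed.

#' Simulate a pure-birth tree rescaled to a fixed height
#'
#' @param n_tips Number of tips (>= 3).
#' @param total_height Tree height in Myr.
#' @param seed Integer seed; the tree is deterministic given it.
#' @return An ultrametric `"phylo"` object with tips `t1..tn`.
#' @export
sim_tree <- function(n_tips, total_height = 1, seed) {
  if (n_tips < 3) stop("need at least 3 tips")
  if (missing(seed)) stop("seed is required")
  set.seed(seed)
  tree <- ape::rphylo(n_tips, birth = 1, death = 0)
  tree$edge.length <- tree$edge.length * (total_height / tree_height(tree))
  validate_tree(tree)
  tree
}

#' The packaged synthetic anthropoid chronogram
#'
#' A fixed 16-taxon anthropoid tree (hominoids to species, monkeys to genus,
#' hylobatids pooled as one tip), with node ages rounded from
#' literature-standard divergence dates; see the header of
#' `extdata/anthropoid_tree.nwk` for the constants. With `fossils = TRUE`
#' four fossil tips are grafted with 1-Myr ghost lineages:
#' *Ardipithecus ramidus* (4.4 Myr, hominin stem),
#' *Australopithecus sediba* (2 Myr, hominin stem below the previous),
#' *Proconsul heseloni* (18 Myr, hominoid stem) and
#' *Hispanopithecus laietanus* (9.6 Myr, orangutan stem by default; see
#' [make_hispanopithecus_trees()] for the alternative placements).
#'
#' @param fossils Graft the four fossil tips (default `TRUE`).
#' @return A `"phylo"` object.
#' @export
packaged_anthropoid_tree <- function(fossils = TRUE) {
  path <- system.file("extdata", "anthropoid_tree.nwk", package = "handevo")
  lines <- readLines(path, warn = FALSE)
  tree <- read_newick(paste(lines[!startsWith(lines, "#")], collapse = ""))
  if (!fossils) return(tree)
  hominoids <- c("Hylobatidae", "Pongo_abelii", "Pongo_pygmaeus",
                 "Gorilla_gorilla", "Gorilla_beringei", "Homo_sapiens",
                 "Pan_troglodytes", "Pan_paniscus")
  tree <- graft_fossil(tree, "Proconsul_heseloni", 18, hominoids)
  tree <- graft_fossil(tree, "Hispanopithecus_laietanus", 9.6,
                       c("Pongo_abelii", "Pongo_pygmaeus"))
  tree <- graft_fossil(tree, "Ardipithecus_ramidus", 4.4, "Homo_sapiens")
  tree <- graft_fossil(tree, "Australopithecus_sediba", 2, "Homo_sapiens")
  tree
}

#' Simulate Brownian motion on a tree
#'
#' Recursive simulation from the root: each child value is its parent value
#' plus a normal increment with variance `sigma2 * branch length`.
#'
#' @param tree A `"phylo"` object.
#' @param sigma2 Brownian rate (>= 0; 0 gives the root state everywhere).
#' @param root Root state.
#' @param seed Integer seed.
#' @return Named numeric vector of tip values.
#' @export
simulate_bm <- function(tree, sigma2, root = 0, seed) {
  if (missing(seed)) stop("seed is required")
  if (sigma2 < 0) stop("sigma2 must be non-negative")
  validate_tree(tree)
  set.seed(seed)
  tree <- ape::reorder.phylo(tree, "cladewise")
  n <- ape::Ntip(tree)
  val <- numeric(n + tree$Nnode)
  val[n + 1L] <- root
  eps <- stats::rnorm(nrow(tree$edge), 0, sqrt(sigma2 * tree$edge.length))
  for (e in seq_len(nrow(tree$edge))) {
    val[tree$edge[e, 2L]] <- val[tree$edge[e, 1L]] + eps[e]
  }
  stats::setNames(val[seq_len(n)], tree$tip.label)
}

#' Simulate a multi-regime Ornstein-Uhlenbeck process on a tree
#'
#' Exact transition sampling along each branch within its regime: the child
#' value is `theta_r + (parent - theta_r) * exp(-alpha t)` plus normal noise
#' with variance `sigma2 / (2 alpha) * (1 - exp(-2 alpha t))`. The root starts
#' at the root regime's optimum.
#'
#' @param tree A `"phylo"` object.
#' @param painting A `"regime_painting"`.
#' @param alpha Pull strength (> 0).
#' @param sigma2 Stochastic rate (>= 0; 0 gives deterministic decay to the
#'   optima).
#' @param theta Named numeric vector of optima per regime label.
#' @param seed Integer seed.
#' @return Named numeric vector of tip values.
#' @export
simulate_ou <- function(tree, painting, alpha, sigma2, theta, seed) {
  if (missing(seed)) stop("seed is required")
  if (alpha <= 0) stop("alpha must be positive")
  if (sigma2 < 0) stop("sigma2 must be non-negative")
  validate_tree(tree)
  regimes <- attr(painting, "regimes")
  if (is.null(names(theta))) {
    if (length(theta) != length(regimes)) stop("need one theta per regime")
    names(theta) <- regimes
  }
  miss <- setdiff(regimes, names(theta))
  if (length(miss)) stop("theta missing for regime: ", paste(miss, collapse = ", "))
  set.seed(seed)
  tree2 <- ape::reorder.phylo(tree, "cladewise")
  n <- ape::Ntip(tree2)
  val <- numeric(n + tree2$Nnode)
  val[n + 1L] <- theta[[attr(painting, "root_regime")]]
  t <- tree2$edge.length
  sdv <- sqrt(sigma2 / (2 * alpha) * (1 - exp(-2 * alpha * t)))
  eps <- stats::rnorm(nrow(tree2$edge), 0, sdv)
  th <- theta[unclass(painting)]
  decay <- exp(-alpha * t)
  for (e in seq_len(nrow(tree2$edge))) {
    val[tree2$edge[e, 2L]] <- th[[e]] + (val[tree2$edge[e, 1L]] - th[[e]]) * decay[e] + eps[e]
  }
  stats::setNames(val[seq_len(n)], tree2$tip.label)
}

#' Default study specification for the synthetic anthropoid dataset
#'
#' Encodes the study conditions the generator emulates: the packaged
#' anthropoid tree with four fossil tips, per-taxon specimen counts matching
#' the study's extant samples (e.g. *Homo sapiens* n = 40, *Pan troglodytes*
#' n = 34, *Papio* n = 50; fossils n = 1), taxon body-mass means on realistic
#' scales, a five-regime adaptive painting (background; convergent
#' Cebus + Alouatta; Papio + Theropithecus; hylobatids; convergent
#' Pan + Pongo), and per-trait optima for the six log shape ratios with
#' digital elongation in the suspensory regimes. OU parameters default to
#' `alpha` = 0.1 /Myr (phylogenetic half-life about 7 Myr) and `sigma2` =
#' 0.001 /Myr on log ratios (stationary SD about 0.07, so the painted regime
#' contrasts span roughly 2-7 stationary SDs); within-taxon coefficients of
#' variation default to 0.05 for shape and 0.15 for body mass.
#'
#' @param tree Optional replacement tree.
#' @param seed Seed stored in the spec (mandatory at simulation time).
#' @return A list of class `"study_spec"` understood by [simulate_study()].
#' @export
study_spec <- function(tree = packaged_anthropoid_tree(), seed = 1L) {
  counts <- c(Homo_sapiens = 40, Pan_troglodytes = 34, Pan_paniscus = 12,
              Gorilla_beringei = 21, Gorilla_gorilla = 13, Pongo_abelii = 8,
              Pongo_pygmaeus = 19, Hylobatidae = 14, Theropithecus = 5,
              Papio = 50, Mandrillus = 3, Macaca = 18, Nasalis = 14,
              Cebus = 11, Alouatta = 8, Ateles = 8,
              Proconsul_heseloni = 1, Hispanopithecus_laietanus = 1,
              Ardipithecus_ramidus = 1, Australopithecus_sediba = 1)
  bm_mean <- c(Homo_sapiens = 60, Pan_troglodytes = 45, Pan_paniscus = 35,
               Gorilla_beringei = 140, Gorilla_gorilla = 120, Pongo_abelii = 50,
               Pongo_pygmaeus = 55, Hylobatidae = 6, Theropithecus = 15,
               Papio = 20, Mandrillus = 25, Macaca = 8, Nasalis = 15,
               Cebus = 3, Alouatta = 6, Ateles = 8,
               Proconsul_heseloni = 10.5, Hispanopithecus_laietanus = 37.25,
               Ardipithecus_ramidus = 50.8, Australopithecus_sediba = 32.5)
  regimes <- list(
    list(label = "cebus_alouatta", tips = "Cebus"),
    list(label = "cebus_alouatta", tips = "Alouatta"),
    list(label = "papionin", tips = c("Papio", "Theropithecus")),
    list(label = "hylobatid", tips = "Hylobatidae"),
    list(label = "pan_pongo", tips = c("Pan_troglodytes", "Pan_paniscus")),
    list(label = "pan_pongo", tips = c("Pongo_abelii", "Pongo_pygmaeus"))
  )
  ## optima for log shape ratios, log(mm kg^-1/3); rows = regimes
  base <- c(mc1 = 2.5, pp1 = 2.3, dp1 = 1.9, mc4 = 3.0, pp4 = 2.8, ip4 = 2.5)
  off <- function(thumb = 0, digits = 0) {
    base + c(rep(thumb, 3), rep(digits, 3))
  }
  theta <- rbind(background = off(),
                 cebus_alouatta = off(thumb = 0.15, digits = -0.05),
                 papionin = off(digits = -0.2),
                 hylobatid = off(thumb = 0.3, digits = 0.5),
                 pan_pongo = off(thumb = -0.05, digits = 0.25))
  keep <- intersect(names(counts), tree$tip.label)
  structure(list(tree = tree, counts = counts[keep], bm_mean = bm_mean[keep],
                 regimes = regimes, root_regime = "background", theta = theta,
                 alpha = 0.1, sigma2 = 0.001,
                 cv_shape = 0.05, cv_bm = 0.15,
                 mass_allometry = c(intercept = -2.0, slope = 2.5),
                 missing_rate = 0, seed = as.integer(seed)),
            class = "study_spec")
}

#' Simulate a specimen-level comparative study
#'
#' Taxon-mean log shape ratios for the six hand elements evolve under the
#' spec's painted multi-regime OU model; each specimen draws a lognormal body
#' mass around its taxon mean (CV `cv_bm`) and element lengths
#' `exp(taxon log ratio + N(0, cv_shape)) * BM^(1/3)`, so recovering shape
#' ratios from the output cancels the mass draw exactly. Femoral head
#' diameters consistent with a log-log mass allometry (slope 2.5, intercept
#' -2) are attached so the mass-estimation workflow can be exercised. An
#' optional uniform missing-at-random mask blanks measured masses.
#'
#' @param spec A `"study_spec"`.
#' @param seed Optional override of `spec$seed`.
#' @return A list with `tree`, `specimens` (data frame in the
#'   [read_specimens()] dialect), `painting`, and `truth` (generating
#'   parameters and taxon-mean log ratios).
#' @examples
#' sim <- simulate_study(study_spec(seed = 42))
#' head(sim$specimens)
#' @export
simulate_study <- function(spec, seed = spec$seed) {
  stopifnot(inherits(spec, "study_spec"))
  if (is.null(seed)) stop("seed is required")
  tree <- spec$tree
  miss <- setdiff(tree$tip.label, names(spec$counts))
  if (length(miss)) stop("no specimen counts for tips: ", paste(miss, collapse = ", "))
  painting <- paint_clades(tree, spec$regimes, root_regime = spec$root_regime)
  used <- attr(painting, "regimes")
  bad <- setdiff(vapply(spec$regimes, `[[`, "", "label"), used)
  if (length(bad)) stop("regime referenced by no branch: ", paste(bad, collapse = ", "))
  set.seed(seed)
  trait_seeds <- sample.int(2^30, ncol(spec$theta))
  noise_seed <- sample.int(2^30, 1)
  logmeans <- sapply(seq_len(ncol(spec$theta)), function(j) {
    simulate_ou(tree, painting, spec$alpha, spec$sigma2,
                spec$theta[, j], seed = trait_seeds[j])
  })
  colnames(logmeans) <- colnames(spec$theta)
  set.seed(noise_seed)
  rows <- vector("list", length(tree$tip.label))
  for (i in seq_along(tree$tip.label)) {
    taxon <- tree$tip.label[i]
    k <- spec$counts[[taxon]]
    bm <- spec$bm_mean[[taxon]] * exp(stats::rnorm(k, 0, spec$cv_bm))
    shape <- exp(sweep(matrix(stats::rnorm(k * 6, 0, spec$cv_shape), k, 6),
                       2, logmeans[taxon, ], "+"))
    lengths <- shape * bm^(1 / 3)
    colnames(lengths) <- colnames(spec$theta)
    fhd <- 10^((log10(bm) - spec$mass_allometry[["intercept"]]) /
                 spec$mass_allometry[["slope"]] + stats::rnorm(k, 0, 0.01))
    rows[[i]] <- data.frame(taxon = taxon,
                            specimen_id = sprintf("%s_%02d", taxon, seq_len(k)),
                            lengths, bm_kg = bm, fhd_mm = fhd)
  }
  specimens <- do.call(rbind, rows)
  rownames(specimens) <- NULL
  if (spec$missing_rate > 0) {
    mask <- stats::runif(nrow(specimens)) < spec$missing_rate
    specimens$bm_kg[mask] <- NA_real_
  }
  list(tree = tree, specimens = specimens, painting = painting,
       truth = list(alpha = spec$alpha, sigma2 = spec$sigma2,
                    theta = spec$theta, logmeans = logmeans,
                    painting = unclass(painting),
                    root_regime = attr(painting, "root_regime"),
                    counts = spec$counts, seed = seed))
}

#' Write a simulated study to disk
#'
#' Specimen CSV (the [read_specimens()] dialect), tree Newick, and ground
#' truth JSON.
#'
#' @param sim Output of [simulate_study()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(sim$specimens, file.path(dir, "specimens.csv"),
                   row.names = FALSE)
  write_newick(sim$tree, file.path(dir, "tree.nwk"))
  truth <- sim$truth
  truth$theta <- as.data.frame(truth$theta)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
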