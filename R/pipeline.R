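## Config-driven orchestration of the full analysis: specimen loading, IHP
## group tests, EHP standardization, species means, covariance PCA, the
## stepwise regime search on the leading PC axes, hypothesis comparison by
## AICc, phylomorphospace with LCA confidence intervals, and Blomberg's K --
## writing plain CSV/JSON outputs plus a manifest sufficient to rerun any
## stage. All randomness flows from the single config seed, so reruns with
## the same config produce byte-identical outputs.

#' Assemble a pipeline configuration
#'
#' @param specimens Specimen CSV path or data frame ([read_specimens()]
#'   dialect).
#' @param tree Newick path or `"phylo"` object.
#' @param out_dir Output directory.
#' @param analyses Stages to run, a subset of `"ihp"`, `"ehp"`, `"pca"`,
#'   `"surface"`, `"hypotheses"`, `"phylomorphospace"`, `"signal"`.
#' @param n_axes Number of leading species-mean PC axes fed to the regime
#'   search and hypothesis fits (default 2, the study convention).
#' @param ray4_only Use only the three fourth-ray elements (for datasets with
#'   taxa lacking thumbs).
#' @param body_mass `"measured"` (use recorded `bm_kg`) or `"fhd"` (fill
#'   missing masses from per-taxon FHD regressions).
#' @param dual_mass Optional `list(taxon =, masses = c(high, low))`: rerun all
#'   mass-dependent stages once per mass for that taxon (sensitivity to an
#'   uncertain fossil body mass); results land in subdirectories.
#' @param drop_taxa Taxa to exclude before analysis (leave-taxa-out
#'   sensitivity reruns).
#' @param hypotheses Named list of clade-spec lists (see [paint_clades()])
#'   fitted as alternative multi-regime OU hypotheses next to the built-in
#'   Brownian-motion and single-regime OU models and the regime-search result.
#' @param lca_tips Tip pair whose LCA coordinates and CIs are reported from
#'   the phylomorphospace.
#' @param n_perm Permutations for the K test.
#' @param seed Integer seed for every stochastic step.
#' @return A list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(specimens, tree, out_dir,
                            analyses = c("ihp", "ehp", "pca", "surface",
                                         "hypotheses", "phylomorphospace",
                                         "signal"),
                            n_axes = 2, ray4_only = FALSE,
                            body_mass = c("measured", "fhd"),
                            dual_mass = NULL, drop_taxa = character(0),
                            hypotheses = list(), lca_tips = NULL,
                            n_perm = 1000, seed = 1L) {
  structure(list(specimens = specimens, tree = tree, out_dir = out_dir,
                 analyses = analyses, n_axes = n_axes, ray4_only = ray4_only,
                 body_mass = match.arg(body_mass), dual_mass = dual_mass,
                 drop_taxa = drop_taxa, hypotheses = hypotheses,
                 lca_tips = lca_tips, n_perm = n_perm, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from JSON
#'
#' @param path JSON file with the fields of [pipeline_config()].
#' @return A `"pipeline_config"`.
#' @export
read_pipeline_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg$hypotheses <- lapply(cfg$hypotheses, function(h) {
    lapply(h, function(s) list(label = s$label, tips = unlist(s$tips)))
  })
  do.call(pipeline_config, cfg)
}

stage <- function(name, out_dir, expr) {
  tryCatch(expr, error = function(e) {
    writeLines(paste0("FAILED at stage ", name, ": ", conditionMessage(e)),
               file.path(out_dir, "FAILED"))
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run the full comparative analysis pipeline
#'
#' Executes the configured stages in order (load/validate, IHP + ANOVA, EHP,
#' species means, PCA, regime search on the leading PC axes, hypothesis
#' comparison, phylomorphospace with LCA CIs, Blomberg's K per axis), writes
#' CSV/JSON outputs under `config$out_dir`, and returns (and writes) a
#' manifest listing every output with the seed and a config hash. With
#' `dual_mass` set, mass-dependent stages run once per mass variant in
#' subdirectories (`mass_high`, `mass_low`); IHP is mass-free and computed
#' once at the top level.
#'
#' @param config A `"pipeline_config"`.
#' @return The manifest, invisibly.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  out_dir <- config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  unlink(file.path(out_dir, "FAILED"))

  specimens <- stage("load", out_dir, {
    if (is.character(config$specimens)) read_specimens(config$specimens)
    else config$specimens
  })
  tree <- stage("load", out_dir, {
    tr <- if (is.character(config$tree)) read_newick(config$tree) else config$tree
    validate_tree(tr)
    tr
  })
  if (length(config$drop_taxa)) {
    specimens <- specimens[!specimens$taxon %in% config$drop_taxa, , drop = FALSE]
    tree <- ape::drop.tip(tree, intersect(config$drop_taxa, tree$tip.label))
  }
  if (config$body_mass == "fhd") {
    specimens <- stage("body_mass", out_dir, fill_mass_from_fhd(specimens))
  }

  outputs <- character(0)
  emit <- function(obj, file, dir = out_dir) {
    path <- file.path(dir, file)
    if (is.data.frame(obj) || is.matrix(obj)) {
      utils::write.csv(obj, path, row.names = FALSE)
    } else {
      jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                           pretty = TRUE, null = "null")
    }
    outputs <<- c(outputs, path)
    path
  }

  if ("ihp" %in% config$analyses) {
    stage("ihp", out_dir, {
      ok <- stats::complete.cases(specimens[, hand_elements])
      ihp <- data.frame(taxon = specimens$taxon[ok],
                        specimen_id = specimens$specimen_id[ok],
                        ihp = compute_ihp(specimens[ok, ]))
      emit(ihp, "ihp_specimens.csv")
      grp <- ihp$taxon[ihp$taxon %in% names(which(table(ihp$taxon) >= 2))]
      gc_res <- group_compare(ihp$ihp[ihp$taxon %in% grp], ihp$taxon[ihp$taxon %in% grp])
      emit(list(F = gc_res$F, df = gc_res$df, p = gc_res$p), "ihp_anova.json")
      emit(gc_res$pairwise, "ihp_pairwise.csv")
    })
  }

  variants <- list(default = specimens)
  if (!is.null(config$dual_mass)) {
    tx <- config$dual_mass$taxon
    hi <- specimens; hi$bm_kg[hi$taxon == tx] <- config$dual_mass$masses[1]
    lo <- specimens; lo$bm_kg[lo$taxon == tx] <- config$dual_mass$masses[2]
    variants <- list(mass_high = hi, mass_low = lo)
  }

  results <- list()
  for (vn in names(variants)) {
    vdir <- if (length(variants) == 1) out_dir else file.path(out_dir, vn)
    dir.create(vdir, showWarnings = FALSE)
    results[[vn]] <- run_mass_dependent(variants[[vn]], tree, config, vdir, emit)
  }

  manifest <- list(
    seed = config$seed,
    config = unclass(config[setdiff(names(config),
                                    c("specimens", "tree", "out_dir"))]),
    config_hash = unname(config_hash(config)),
    outputs = basename(outputs),
    variants = names(variants)
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(list(manifest = manifest, results = results))
}

## Hash of the analysis-relevant configuration (input objects and output paths
## excluded, so reruns into different directories hash identically).
config_hash <- function(config) {
  s <- jsonlite::toJSON(unclass(config[setdiff(names(config),
                                               c("specimens", "tree", "out_dir"))]),
                        auto_unbox = TRUE, digits = NA, null = "null",
                        force = TRUE)
  f <- tempfile(); on.exit(unlink(f))
  writeLines(as.character(s), f)
  as.character(tools::md5sum(f))
}

## Fit per-taxon mass~FHD regressions on specimens with both, and estimate
## masses for specimens with FHD only. Taxa with too few training pairs fall
## back to the pooled regression.
fill_mass_from_fhd <- function(specimens) {
  if (is.null(specimens$fhd_mm)) stop("body_mass = 'fhd' needs an fhd_mm column")
  train <- !is.na(specimens$bm_kg) & !is.na(specimens$fhd_mm)
  if (sum(train) < 3) stop("too few (FHD, BM) pairs to train any regression")
  pooled <- fit_mass_regression(specimens$fhd_mm[train], specimens$bm_kg[train])
  out <- specimens
  out$bm_estimated <- FALSE
  for (tx in unique(specimens$taxon)) {
    sel <- specimens$taxon == tx
    need <- sel & is.na(specimens$bm_kg) & !is.na(specimens$fhd_mm)
    if (!any(need)) next
    tr_sel <- sel & train
    reg <- if (sum(tr_sel) >= 3) {
      fit_mass_regression(specimens$fhd_mm[tr_sel], specimens$bm_kg[tr_sel])
    } else pooled
    out$bm_kg[need] <- predict(reg, specimens$fhd_mm[need])
    out$bm_estimated[need] <- TRUE
  }
  out
}

run_mass_dependent <- function(specimens, tree, config, vdir, emit) {
  res <- list()
  trait <- if (config$ray4_only) "ray4" else "ehp"

  means <- stage("species_means", vdir, {
    m <- species_means(specimens, trait)
    m <- m[intersect(rownames(m), tree$tip.label), , drop = FALSE]
    emit(data.frame(taxon = rownames(m), m), "species_means.csv", vdir)
    m
  })
  tree_used <- ape::drop.tip(tree, setdiff(tree$tip.label, rownames(means)))
  res$means <- means

  if (!any(c("pca", "surface", "hypotheses", "phylomorphospace", "signal")
           %in% config$analyses)) return(res)

  pca <- stage("pca", vdir, {
    ok <- stats::complete.cases(specimens[, if (config$ray4_only)
      ray4_elements else hand_elements]) & !is.na(specimens$bm_kg)
    ind <- compute_ehp(specimens[ok, ])
    if (config$ray4_only) ind <- ind[, ray4_elements, drop = FALSE]
    p_ind <- pca_covariance(ind)
    p_sp <- pca_covariance(means)
    emit(data.frame(taxon = specimens$taxon[ok], p_ind$scores),
         "pca_individual_scores.csv", vdir)
    emit(data.frame(taxon = rownames(p_sp$scores), p_sp$scores),
         "pca_species_scores.csv", vdir)
    emit(data.frame(variable = rownames(p_sp$eigenvectors), p_sp$eigenvectors),
         "pca_species_loadings.csv", vdir)
    emit(summary(p_sp), "pca_species_variance.csv", vdir)
    p_sp
  })
  res$pca <- pca
  n_axes <- min(config$n_axes, ncol(pca$scores))
  scores <- pca$scores[, seq_len(n_axes), drop = FALSE]

  sf <- NULL
  if ("surface" %in% config$analyses) {
    sf <- stage("surface", vdir, {
      s <- surface_search(tree_used, scores)
      emit(painting_table(tree_cache(tree_used)$tree, s$painting),
           "surface_painting.csv", vdir)
      trace_to_jsonl(s, file.path(vdir, "surface_trace.jsonl"))
      s
    })
    res$surface <- sf
  }

  if ("hypotheses" %in% config$analyses) {
    res$comparison <- stage("hypotheses", vdir, {
      cache <- tree_cache(tree_used)
      fits <- list(
        BM = fit_multi(tree_used, NULL, scores, model = "bm", cache = cache),
        OU1 = fit_multi(tree_used,
                        painting_from_shifts(cache$tree, integer(0), character(0)),
                        scores, cache = cache)
      )
      for (hn in names(config$hypotheses)) {
        pp <- paint_clades(cache$tree, config$hypotheses[[hn]])
        fits[[hn]] <- fit_multi(tree_used, pp, scores, cache = cache)
      }
      if (!is.null(sf)) fits$surface <- sf$fit
      cmp <- compare_models(fits)
      emit(as.data.frame(cmp), "model_comparison.csv", vdir)
      cmp
    })
  }

  if ("phylomorphospace" %in% config$analyses && ncol(scores) >= 2) {
    res$pms <- stage("phylomorphospace", vdir, {
      pms <- build_phylomorphospace(tree_used, scores)
      phylomorphospace_to_csv(pms, file.path(vdir, "phylomorphospace_nodes.csv"),
                              file.path(vdir, "phylomorphospace_edges.csv"))
      lca <- config$lca_tips
      if (is.null(lca)) {
        cand <- intersect(c("Pan_troglodytes", "Homo_sapiens"), tree_used$tip.label)
        if (length(cand) == 2) lca <- cand
      }
      if (!is.null(lca) && all(lca %in% tree_used$tip.label)) {
        emit(lca_coordinates(pms, lca[1], lca[2]), "lca_coordinates.csv", vdir)
      }
      pms
    })
  }

  if ("signal" %in% config$analyses) {
    res$signal <- stage("signal", vdir, {
      rows <- lapply(seq_len(ncol(scores)), function(j) {
        k <- k_permutation_test(tree_used, scores[, j], n_perm = config$n_perm,
                                seed = config$seed + j)
        data.frame(trait = colnames(scores)[j], K = k$K,
                   expected_ratio = k$expected_ratio, p = k$p_value,
                   n_perm = k$n_perm, tail = k$tail,
                   scores = "species_mean")
      })
      tab <- do.call(rbind, rows)
      emit(tab, "phylogenetic_signal.csv", vdir)
      tab
    })
  }
  res
}
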