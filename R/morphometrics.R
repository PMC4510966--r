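## Specimen-level morphometrics: intrinsic and extrinsic hand proportions,
## body-mass estimation from femoral head diameter, species means, covariance
## PCA and simple group tests.
##
## The specimen table dialect has columns: taxon, specimen_id, mc1, pp1, dp1
## (thumb metacarpal, proximal and distal phalanx), mc4, pp4, ip4 (fourth-ray
## metacarpal, proximal and intermediate phalanx), all lengths in mm, plus
## bm_kg (body mass) and fhd_mm (femoral head diameter); empty cells are
## missing values.

hand_elements <- c("mc1", "pp1", "dp1", "mc4", "pp4", "ip4")
thumb_elements <- c("mc1", "pp1", "dp1")
ray4_elements <- c("mc4", "pp4", "ip4")

#' Read a specimen measurement table
#'
#' @param path CSV path with columns `taxon, specimen_id, mc1, pp1, dp1, mc4,
#'   pp4, ip4, bm_kg, fhd_mm` (the last two optional); empty cells are
#'   missing.
#' @return A data frame of specimens; positive-value sanity checks applied.
#' @export
read_specimens <- function(path) {
  if (!file.exists(path)) stop("specimen table not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("taxon", "specimen_id", hand_elements)
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("specimen table missing columns: ", paste(miss, collapse = ", "))
  for (col in c(hand_elements, intersect(c("bm_kg", "fhd_mm"), names(df)))) {
    v <- df[[col]]
    if (any(!is.na(v) & v <= 0)) stop("non-positive value in column ", col)
  }
  df
}

#' Intrinsic hand proportions (thumb-to-digit ratio)
#'
#' The dimensionless ratio of summed thumb long-bone lengths to summed
#' fourth-ray lengths, `(mc1 + pp1 + dp1) / (mc4 + pp4 + ip4)`; the fourth-ray
#' distal phalanx is deliberately excluded (it is rarely preserved in
#' associated fossil hands). A proxy for thumb opposability.
#'
#' @param rec A specimen data frame (one or more rows) with the six element
#'   columns.
#' @return Numeric vector of ratios, one per row.
#' @examples
#' compute_ihp(data.frame(mc1 = 40, pp1 = 30, dp1 = 20,
#'                        mc4 = 50, pp4 = 35, ip4 = 25))
#' @export
compute_ihp <- function(rec) {
  for (el in hand_elements) {
    if (is.null(rec[[el]]) || anyNA(rec[[el]])) {
      stop("missing element required for intrinsic proportions: ", el)
    }
  }
  (rec$mc1 + rec$pp1 + rec$dp1) / (rec$mc4 + rec$pp4 + rec$ip4)
}

#' Extrinsic hand proportions (body-size-standardized lengths)
#'
#' Each of the six element lengths (mm) divided by the cube root of body mass
#' (kg), giving shape ratios in mm kg^(-1/3); the cube root of mass is the
#' standard proxy for linear body size.
#'
#' @param rec A specimen data frame with the six element columns and `bm_kg`.
#' @return A matrix (rows = specimens) of the six standardized ratios.
#' @export
compute_ehp <- function(rec) {
  if (is.null(rec$bm_kg) || anyNA(rec$bm_kg)) {
    stop("body mass required to standardize lengths (bm_kg missing; ",
         "estimate it from fhd_mm first)")
  }
  for (el in hand_elements) {
    if (is.null(rec[[el]]) || anyNA(rec[[el]])) {
      stop("missing element required for extrinsic proportions: ", el)
    }
  }
  size <- rec$bm_kg^(1 / 3)
  out <- sapply(hand_elements, function(el) rec[[el]] / size)
  if (is.null(dim(out))) out <- matrix(out, nrow = 1,
                                       dimnames = list(NULL, hand_elements))
  out
}

#' Allometric body-mass regression on femoral head diameter
#'
#' Least-squares fit of `log10(BM)` on `log10(FHD)`, the allometric convention
#' that guarantees positive mass predictions. Fitted per reference group
#' (typically per genus) by the caller.
#'
#' @param fhd Femoral head diameters (mm), positive.
#' @param bm Body masses (kg), positive; same length, at least 3 pairs.
#' @return An object of class `"mass_reg"`: list with `slope`, `intercept`
#'   (log10-log10 space), `r_squared`, `n`, and the underlying `lm` fit.
#' @export
fit_mass_regression <- function(fhd, bm) {
  ok <- stats::complete.cases(fhd, bm)
  fhd <- fhd[ok]; bm <- bm[ok]
  if (length(fhd) < 3) stop("need at least 3 (FHD, BM) pairs")
  if (any(fhd <= 0) || any(bm <= 0)) stop("FHD and BM must be positive")
  fit <- stats::lm(log10(bm) ~ log10(fhd))
  out <- list(slope = unname(stats::coef(fit)[2]),
              intercept = unname(stats::coef(fit)[1]),
              r_squared = suppressWarnings(summary(fit)$r.squared),
              n = length(fhd), lm = fit)
  class(out) <- "mass_reg"
  out
}

#' @export
print.mass_reg <- function(x, ...) {
  cat(sprintf("Mass ~ FHD allometry: log10(BM) = %.4f + %.4f log10(FHD)  (n = %d, R^2 = %.3f)\n",
              x$intercept, x$slope, x$n, x$r_squared))
  invisible(x)
}

#' @export
predict.mass_reg <- function(object, fhd, ...) {
  if (any(fhd <= 0)) stop("FHD must be positive")
  10^(object$intercept + object$slope * log10(fhd))
}

#' @export
coef.mass_reg <- function(object, ...) {
  c(intercept = object$intercept, slope = object$slope)
}

#' Estimate body mass from femoral head diameter
#'
#' Predicts body mass for specimens lacking a recorded mass, from their FHD
#' and a fitted [fit_mass_regression()] for the matching taxon group. Several
#' regressions may be supplied (e.g. a quadrupedal and a bipedal reference
#' sample for a fossil of uncertain locomotion), in which case the estimates
#' are averaged. The returned records carry a `bm_estimated` flag.
#'
#' @param rec Specimen data frame with an `fhd_mm` column.
#' @param reg A `"mass_reg"`, or a list of them to average.
#' @param overwrite Replace already-present `bm_kg` values (default: only fill
#'   missing ones).
#' @return `rec` with `bm_kg` filled in and a logical `bm_estimated` column.
#' @export
estimate_body_mass <- function(rec, reg, overwrite = FALSE) {
  if (is.null(rec$fhd_mm)) stop("no femoral head diameter (fhd_mm) to predict from")
  regs <- if (inherits(reg, "mass_reg")) list(reg) else reg
  if (!all(vapply(regs, inherits, logical(1), "mass_reg"))) {
    stop("reg must be a mass_reg or a list of them")
  }
  if (is.null(rec$bm_estimated)) rec$bm_estimated <- FALSE
  if (is.null(rec$bm_kg)) rec$bm_kg <- NA_real_
  target <- if (overwrite) !is.na(rec$fhd_mm) else is.na(rec$bm_kg) & !is.na(rec$fhd_mm)
  if (!any(target)) return(rec)
  preds <- sapply(regs, function(r) predict(r, rec$fhd_mm[target]))
  if (is.null(dim(preds))) preds <- matrix(preds, nrow = sum(target))
  rec$bm_kg[target] <- rowMeans(preds)
  rec$bm_estimated[target] <- TRUE
  rec
}

#' Per-taxon trait means (ratios first, then mean)
#'
#' Computes the requested per-specimen ratios and averages them within taxa:
#' the mean of per-specimen ratios, not the ratio of means. Taxa with no
#' complete specimen for the requested ratio set are dropped with a warning.
#'
#' @param records Specimen data frame.
#' @param trait `"ehp"` (six standardized ratios), `"ihp"` (thumb-to-digit
#'   ratio) or `"ray4"` (the three fourth-ray standardized ratios only, for
#'   taxa without preserved thumbs).
#' @param log Return means of log-ratios (default `FALSE`).
#' @return A taxa x traits matrix (taxa as row names); single-column for
#'   `"ihp"`.
#' @export
species_means <- function(records, trait = c("ehp", "ihp", "ray4"), log = FALSE) {
  trait <- match.arg(trait)
  cols <- switch(trait, ehp = hand_elements, ray4 = ray4_elements,
                 ihp = hand_elements)
  need_bm <- trait %in% c("ehp", "ray4")
  ok <- stats::complete.cases(records[, cols, drop = FALSE])
  if (need_bm) ok <- ok & !is.na(records$bm_kg)
  dropped <- setdiff(unique(records$taxon), unique(records$taxon[ok]))
  if (length(dropped)) {
    warning("taxa dropped (no complete specimen): ", paste(dropped, collapse = ", "))
  }
  rec <- records[ok, , drop = FALSE]
  ratios <- switch(trait,
    ihp = matrix(compute_ihp(rec), ncol = 1, dimnames = list(NULL, "ihp")),
    ehp = compute_ehp(rec),
    ray4 = compute_ehp(rec)[, ray4_elements, drop = FALSE])
  if (log) ratios <- base::log(ratios)
  out <- rowsum(ratios, rec$taxon) / as.vector(table(rec$taxon)[sort(unique(rec$taxon))])
  out[order(rownames(out)), , drop = FALSE]
}

#' Principal components of the trait covariance matrix
#'
#' Eigen-decomposition of the sample covariance matrix (divisor `n - 1`);
#' scores are the centered data projected on the eigenvectors. The sign of
#' each eigenvector is fixed so its largest-magnitude loading is positive,
#' making results deterministic across linear-algebra backends. Constant
#' columns are valid (zero eigenvalue).
#'
#' @param data Observations x variables matrix or data frame (>= 2 of each),
#'   no missing values.
#' @return An object of class `"pca_cov"`: list with `mean`, `eigenvalues`
#'   (descending), `eigenvectors` (orthonormal columns), `scores`,
#'   `proportion` (variance proportions summing to 1).
#' @export
pca_covariance <- function(data) {
  X <- as.matrix(data)
  if (nrow(X) < 2) stop("need at least 2 observations")
  if (ncol(X) < 2) stop("need at least 2 variables")
  if (anyNA(X)) stop("missing values in PCA input")
  ctr <- colMeans(X)
  Xc <- sweep(X, 2, ctr)
  eg <- eigen(stats::cov(X), symmetric = TRUE)
  vals <- pmax(eg$values, 0)
  vecs <- eg$vectors
  for (j in seq_len(ncol(vecs))) {
    i <- which.max(abs(vecs[, j]))
    if (vecs[i, j] < 0) vecs[, j] <- -vecs[, j]
  }
  dimnames(vecs) <- list(colnames(X), paste0("PC", seq_len(ncol(vecs))))
  scores <- Xc %*% vecs
  rownames(scores) <- rownames(X)
  out <- list(mean = ctr, eigenvalues = vals, eigenvectors = vecs,
              scores = scores, proportion = vals / sum(vals))
  class(out) <- "pca_cov"
  out
}

#' @export
print.pca_cov <- function(x, n_axes = min(4, length(x$eigenvalues)), ...) {
  cat("Covariance-matrix PCA:", nrow(x$scores), "observations,",
      length(x$eigenvalues), "variables\n")
  for (j in seq_len(n_axes)) {
    cat(sprintf("  PC%d: eigenvalue %.5g (%.1f%% of variance)\n",
                j, x$eigenvalues[j], 100 * x$proportion[j]))
  }
  invisible(x)
}

#' @export
summary.pca_cov <- function(object, ...) {
  data.frame(axis = paste0("PC", seq_along(object$eigenvalues)),
             eigenvalue = object$eigenvalues,
             proportion = object$proportion,
             cumulative = cumsum(object$proportion))
}

#' One-way ANOVA with Bonferroni-corrected pairwise comparisons
#'
#' Classical one-way ANOVA of a per-specimen scalar across taxon groups,
#' followed by pairwise two-sample t tests whose p-values are multiplied by
#' the number of pairs (capped at 1).
#'
#' @param values Numeric vector (e.g. per-specimen intrinsic proportions).
#' @param groups Group labels, same length; every group needs >= 2
#'   observations.
#' @param pool_sd Use a common within-group variance in the pairwise tests
#'   (default `FALSE`: Welch tests).
#' @return An object of class `"group_comparison"`: list with `F`, `df`, `p`,
#'   and `pairwise` (data frame of pair, raw and Bonferroni-corrected p).
#' @export
group_compare <- function(values, groups, pool_sd = FALSE) {
  groups <- factor(groups)
  sizes <- table(groups)
  if (nlevels(groups) < 2) stop("need at least 2 groups")
  if (any(sizes < 2)) {
    stop("groups with fewer than 2 observations: ",
         paste(names(sizes)[sizes < 2], collapse = ", "))
  }
  fit <- stats::aov(values ~ groups)
  tab <- summary(fit)[[1]]
  lev <- levels(groups)
  prs <- utils::combn(lev, 2)
  m <- ncol(prs)
  raw <- numeric(m)
  for (j in seq_len(m)) {
    raw[j] <- stats::t.test(values[groups == prs[1, j]],
                            values[groups == prs[2, j]],
                            var.equal = pool_sd)$p.value
  }
  out <- list(F = tab[["F value"]][1], df = tab[["Df"]],
              p = tab[["Pr(>F)"]][1],
              pairwise = data.frame(group1 = prs[1, ], group2 = prs[2, ],
                                    p_raw = raw,
                                    p_bonferroni = pmin(raw * m, 1)))
  class(out) <- "group_comparison"
  out
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("One-way ANOVA: F(%d, %d) = %.4f, p = %.4g\n",
              x$df[1], x$df[2], x$F, x$p))
  sig <- x$pairwise[x$pairwise$p_bonferroni < 0.05, , drop = FALSE]
  cat("  Bonferroni pairwise comparisons:", nrow(x$pairwise), "pairs,",
      nrow(sig), "significant at 0.05\n")
  invisible(x)
}
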