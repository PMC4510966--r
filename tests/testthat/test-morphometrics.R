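one_rec <- function(mc1 = 40, pp1 = 30, dp1 = 20, mc4 = 50, pp4 = 35, ip4 = 25,
                    bm_kg = NA, ...) {
  data.frame(mc1 = mc1, pp1 = pp1, dp1 = dp1, mc4 = mc4, pp4 = pp4, ip4 = ip4,
             bm_kg = bm_kg, ...)
}

test_that("intrinsic proportions are the thumb / fourth-ray length ratio", {
  expect_equal(compute_ihp(one_rec()), 90 / 110)
  expect_equal(compute_ihp(one_rec(mc4 = 40, pp4 = 30, ip4 = 20)), 1)
  expect_error(compute_ihp(one_rec(dp1 = NA)), "dp1")
})

test_that("extrinsic proportions standardize lengths by the cube root of mass", {
  r <- one_rec(mc1 = 54, bm_kg = 8)
  expect_equal(unname(compute_ehp(r)[1, "mc1"]), 27)
  r2 <- one_rec(bm_kg = 1)
  expect_equal(unname(compute_ehp(r2)[1, ]),
               c(40, 30, 20, 50, 35, 25))
  expect_equal(unname(compute_ehp(one_rec(mc1 = 81, bm_kg = 27))[1, "mc1"]), 27)
  expect_error(compute_ehp(one_rec()), "bm_kg")
})

test_that("proportions are scale-consistent", {
  r <- one_rec(bm_kg = 10)
  for (c_scale in c(0.5, 2, 7)) {
    rs <- r
    for (el in c("mc1", "pp1", "dp1", "mc4", "pp4", "ip4")) rs[[el]] <- r[[el]] * c_scale
    expect_equal(compute_ihp(rs), compute_ihp(r))
    expect_equal(compute_ehp(rs), compute_ehp(r) * c_scale)
  }
})

test_that("mass regression recovers exact and noisy power laws", {
  fhd <- seq(10, 40, length.out = 8)
  bm <- 10^(-2.0 + 2.5 * log10(fhd))
  reg <- fit_mass_regression(fhd, bm)
  expect_equal(reg$slope, 2.5, tolerance = 1e-10)
  expect_equal(reg$intercept, -2.0, tolerance = 1e-10)
  ## cube scaling: slope 3 means doubling FHD gives 8x the mass
  reg3 <- fit_mass_regression(fhd, 10^(0.5 + 3 * log10(fhd)))
  expect_equal(predict(reg3, 20) / predict(reg3, 10), 8, tolerance = 1e-8)
  ## noisy fit against the explicit normal-equations oracle
  set.seed(11)
  fhd <- runif(50, 15, 45)
  lbm <- -1.5 + 2.2 * log10(fhd) + rnorm(50, 0, 0.05)
  reg <- fit_mass_regression(fhd, 10^lbm)
  X <- cbind(1, log10(fhd))
  beta <- solve(t(X) %*% X, t(X) %*% lbm)
  expect_equal(reg$intercept, beta[1], tolerance = 1e-10)
  expect_equal(reg$slope, beta[2], tolerance = 1e-10)
  expect_error(fit_mass_regression(c(10, 20), c(5, 10)), "at least 3")
  expect_error(fit_mass_regression(c(10, 20, -3), c(5, 10, 2)), "positive")
})

test_that("body-mass estimation inverts its regression and can average references", {
  fhd <- seq(10, 40, length.out = 8)
  bm <- 10^(-2.0 + 2.5 * log10(fhd))
  reg <- fit_mass_regression(fhd, bm)
  rec <- data.frame(taxon = "x", fhd_mm = fhd, bm_kg = NA_real_)
  out <- estimate_body_mass(rec, reg)
  expect_equal(out$bm_kg, bm, tolerance = 1e-10)
  expect_true(all(out$bm_estimated))
  ## averaging a quadrupedal and a bipedal reference regression
  regB <- fit_mass_regression(fhd, 10^(-2.3 + 2.5 * log10(fhd)))
  out2 <- estimate_body_mass(data.frame(fhd_mm = 25, bm_kg = NA_real_),
                             list(reg, regB))
  expect_equal(out2$bm_kg,
               mean(c(predict(reg, 25), predict(regB, 25))), tolerance = 1e-12)
  expect_error(estimate_body_mass(data.frame(bm_kg = NA_real_), reg), "fhd_mm")
})

test_that("species means average per-specimen ratios, not ratios of means", {
  rec <- rbind(one_rec(bm_kg = 8), one_rec(mc1 = 60, mc4 = 40, bm_kg = 8))
  rec$taxon <- "A"; rec$specimen_id <- c("a1", "a2")
  m <- species_means(rec, "ihp")
  ratio1 <- (40 + 30 + 20) / (50 + 35 + 25)
  ratio2 <- (60 + 30 + 20) / (40 + 35 + 25)
  mean_of_ratios <- mean(c(ratio1, ratio2))
  ratio_of_means <- (50 + 30 + 20) / (45 + 35 + 25)
  expect_false(isTRUE(all.equal(mean_of_ratios, ratio_of_means)))
  expect_equal(unname(m["A", "ihp"]), mean_of_ratios)
  ## simple numerics
  rec2 <- data.frame(taxon = c("A", "A"), specimen_id = c("1", "2"),
                     mc1 = c(8, 9), pp1 = c(0.1, 0.1), dp1 = c(0.1, 0.1),
                     mc4 = c(10, 10), pp4 = c(0.1, 0.1), ip4 = c(0.1, 0.1),
                     bm_kg = 1)
  expect_equal(unname(species_means(rec2, "ihp")[1, 1]),
               mean(c(8.2 / 10.2, 9.2 / 10.2)))
  ## incomplete taxa are dropped with a warning, not silently
  rec3 <- rbind(rec, data.frame(taxon = "B", specimen_id = "b1",
                                one_rec(dp1 = NA, bm_kg = 5)))
  expect_warning(m3 <- species_means(rec3, "ihp"), "B")
  expect_equal(rownames(m3), "A")
})

test_that("covariance PCA matches an independent decomposition and its invariants", {
  set.seed(21)
  X <- matrix(rnorm(24), 6, 4)
  p <- pca_covariance(X)
  o <- prcomp(X, center = TRUE, scale. = FALSE)       # svd route, independent
  expect_equal(p$eigenvalues, unname(o$sdev^2), tolerance = 1e-8)
  expect_equal(sum(p$proportion), 1, tolerance = 1e-9)
  ## scores: zero means, variances equal eigenvalues, reproduce centered data
  expect_true(all(abs(colMeans(p$scores)) < 1e-9))
  expect_equal(unname(apply(p$scores, 2, var)), p$eigenvalues, tolerance = 1e-8)
  Xc <- sweep(X, 2, colMeans(X))
  expect_equal(p$scores %*% t(p$eigenvectors), Xc, tolerance = 1e-8,
               ignore_attr = TRUE)
  ## orthonormal eigenvectors, deterministic sign
  expect_equal(t(p$eigenvectors) %*% p$eigenvectors, diag(4),
               tolerance = 1e-10, ignore_attr = TRUE)
  for (j in 1:4) expect_gt(max(p$eigenvectors[, j]), 0)
})

test_that("PCA handles rank deficiency and degenerate inputs", {
  x <- rnorm(10)
  p <- pca_covariance(cbind(x, 2 * x))
  expect_equal(p$proportion[1], 1, tolerance = 1e-9)
  expect_equal(p$eigenvalues[2], 0, tolerance = 1e-9)
  pc <- pca_covariance(cbind(rnorm(10), rep(1, 10)))   # constant column is fine
  expect_equal(pc$eigenvalues[2], 0, tolerance = 1e-12)
  expect_error(pca_covariance(matrix(1:4, 1)), "observations")
})

test_that("group comparison matches the sum-of-squares oracle and Bonferroni rule", {
  set.seed(31)
  g <- rep(c("a", "b"), each = 6)
  y <- c(rnorm(6, 0), rnorm(6, 1.5))
  res <- group_compare(y, g)
  ## hand-computed one-way ANOVA decomposition
  gm <- mean(y); ms <- tapply(y, g, mean); ns <- table(g)
  ssb <- sum(ns * (ms - gm)^2); ssw <- sum((y - ms[g])^2)
  Fo <- (ssb / 1) / (ssw / (length(y) - 2))
  expect_equal(res$F, Fo, tolerance = 1e-10)
  expect_equal(res$p, pf(Fo, 1, 10, lower.tail = FALSE), tolerance = 1e-10)
  ## identical group means, positive within-group variance -> F ~ 0
  y0 <- c(-1, 0, 1, -1, 0, 1)
  res0 <- group_compare(y0, rep(c("a", "b"), each = 3))
  expect_equal(res0$F, 0, tolerance = 1e-12)
  expect_equal(res0$p, 1, tolerance = 1e-12)
  ## Bonferroni: raw p times number of pairs, capped at 1
  y3 <- rnorm(30); g3 <- rep(c("a", "b", "c"), each = 10)
  res3 <- group_compare(y3, g3)
  expect_equal(res3$pairwise$p_bonferroni,
               pmin(res3$pairwise$p_raw * 3, 1), tolerance = 1e-12)
  expect_error(group_compare(c(1, 2, 3), c("a", "a", "b")), "fewer than 2")
})
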