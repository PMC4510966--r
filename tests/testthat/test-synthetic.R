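test_that("pure-birth tree simulation is ultrametric, scaled and seeded", {
  tr <- sim_tree(3, total_height = 5, seed = 1)
  expect_equal(tr$Nnode, 2L)
  tr2 <- sim_tree(24, total_height = 7, seed = 2)
  depths <- node_depths(tr2)[1:24]
  expect_true(all(abs(depths - 7) < 1e-9))
  expect_identical(write_newick(sim_tree(10, 1, seed = 3)),
                   write_newick(sim_tree(10, 1, seed = 3)))
  expect_false(identical(write_newick(sim_tree(10, 1, seed = 3)),
                         write_newick(sim_tree(10, 1, seed = 4))))
})

test_that("the packaged anthropoid tree carries the four dated fossil tips", {
  tr <- packaged_anthropoid_tree()
  validate_tree(tr)
  ages <- node_ages(tr)
  a <- function(t) ages[match(t, tr$tip.label)]
  expect_equal(a("Ardipithecus_ramidus"), 4.4)
  expect_equal(a("Australopithecus_sediba"), 2)
  expect_equal(a("Proconsul_heseloni"), 18)
  expect_equal(a("Hispanopithecus_laietanus"), 9.6)
  ## extant tips at the present
  extant <- setdiff(tr$tip.label, c("Ardipithecus_ramidus", "Australopithecus_sediba",
                                    "Proconsul_heseloni", "Hispanopithecus_laietanus"))
  expect_true(all(abs(ages[match(extant, tr$tip.label)]) < 1e-9))
  expect_true(is_ultrametric(packaged_anthropoid_tree(fossils = FALSE)))
})

test_that("Brownian simulation matches its covariance and is reproducible", {
  tr <- read_newick("((A:1,B:1):1,(C:1.5,D:1.5):0.5);")
  expect_equal(unname(simulate_bm(tr, sigma2 = 0, root = 3, seed = 5)),
               rep(3, 4))
  expect_identical(simulate_bm(tr, 1, 0, seed = 6), simulate_bm(tr, 1, 0, seed = 6))
  ## Monte-Carlo tip covariance against sigma2 * C within 3 standard errors
  reps <- 2000
  X <- t(vapply(seq_len(reps), function(i) simulate_bm(tr, 1.3, 0, seed = 1e5 + i),
                numeric(4)))
  S <- cov(X)
  C <- 1.3 * bm_covariance(tr)[colnames(X), colnames(X)]
  se <- sqrt((C^2 + outer(diag(C), diag(C))) / reps)   # var of a sample covariance
  expect_true(all(abs(S - C) < 3.5 * se))
})

test_that("OU simulation decays to optima and reaches stationary variance", {
  tr <- read_newick("((A:1,B:1):1,C:2);")
  pp <- painting_from_shifts(tr, integer(0), character(0))
  ## noise-free: deterministic exponential decay toward theta
  x0 <- simulate_ou(tr, pp, alpha = 0.7, sigma2 = 0, theta = c(root = 2), seed = 7)
  expect_equal(unname(x0), rep(2, 3))  # root starts at the optimum and stays
  ## a shifted regime pulls the subtree toward its optimum, noise-free
  p1 <- painting_from_shifts(tr, 1L, "up")
  x1 <- simulate_ou(tr, p1, alpha = 1, sigma2 = 0,
                    theta = c(root = 0, up = 4), seed = 8)
  expect_true(all(x1[c("A", "B")] > 0.5))
  expect_equal(unname(x1["C"]), 0)
  ## alpha large: tips sit at their terminal-branch optimum
  xl <- simulate_ou(tr, p1, alpha = 200, sigma2 = 1e-6,
                    theta = c(root = -1, up = 4), seed = 9)
  expect_equal(unname(xl[c("A", "B")]), c(4, 4), tolerance = 1e-2)
  expect_equal(unname(xl["C"]), -1, tolerance = 1e-2)
  ## stationary variance sigma2 / (2 alpha) on a long branch
  long <- read_newick("(A:30,B:30);")
  plong <- painting_from_shifts(long, integer(0), character(0))
  tips <- vapply(seq_len(5000), function(i)
    simulate_ou(long, plong, 1.5, 2, c(root = 0), seed = 2e5 + i)[["A"]],
    numeric(1))
  v <- var(tips); v_true <- 2 / (2 * 1.5)
  se <- v_true * sqrt(2 / (5000 - 1))
  expect_lt(abs(v - v_true), 3 * se)
})

test_that("the OU simulator converges to the Brownian simulator as alpha vanishes", {
  tr <- sim_tree(8, total_height = 2, seed = 10)
  pp <- painting_from_shifts(tr, integer(0), character(0))
  n <- 1000
  v_ou <- vapply(seq_len(n), function(i)
    var(simulate_ou(tr, pp, 1e-8, 1, c(root = 0), seed = 3e5 + i)), numeric(1))
  v_bm <- vapply(seq_len(n), function(i)
    var(simulate_bm(tr, 1, 0, seed = 4e5 + i)), numeric(1))
  expect_gt(stats::ks.test(v_ou, v_bm)$p.value, 0.01)
})

test_that("the study generator respects counts and recovers its taxon means", {
  spec <- study_spec(seed = 12)
  sim <- simulate_study(spec)
  counts <- table(sim$specimens$taxon)
  for (tx in names(spec$counts)) {
    expect_equal(unname(counts[tx]), unname(spec$counts[tx]), ignore_attr = TRUE)
  }
  expect_equal(unname(spec$counts["Homo_sapiens"]), 40)
  expect_equal(unname(spec$counts["Pan_troglodytes"]), 34)
  expect_equal(unname(spec$counts["Papio"]), 50)
  ## bit-reproducible
  sim2 <- simulate_study(spec)
  expect_identical(sim$specimens, sim2$specimens)
  ## shape ratios recovered from specimens match simulated taxon means:
  ## the body-mass draw cancels exactly, leaving the CV-scale specimen noise
  m <- species_means(sim$specimens, "ehp", log = TRUE)
  for (tx in rownames(m)) {
    n_tx <- spec$counts[[tx]]
    tol <- 3 * spec$cv_shape / sqrt(n_tx)
    expect_true(all(abs(m[tx, ] - sim$truth$logmeans[tx, colnames(m)]) < tol),
                label = paste("taxon mean recovery for", tx))
  }
})

test_that("simulated studies round-trip through disk and the painting is usable", {
  sim <- simulate_study(study_spec(seed = 13))
  d <- withr::local_tempdir()
  write_study(sim, d)
  spp <- read_specimens(file.path(d, "specimens.csv"))
  expect_equal(nrow(spp), nrow(sim$specimens))
  tr <- read_newick(file.path(d, "tree.nwk"))
  expect_setequal(tr$tip.label, sim$tree$tip.label)
  truth <- jsonlite::read_json(file.path(d, "truth.json"), simplifyVector = TRUE)
  expect_equal(truth$alpha, 0.1)
  ## painting invariants
  expect_equal(length(unclass(sim$painting)), nrow(sim$tree$edge))
  expect_setequal(attr(sim$painting, "regimes"),
                  c("background", "cebus_alouatta", "papionin", "hylobatid",
                    "pan_pongo"))
})
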