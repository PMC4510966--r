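test_that("BM covariance equals shared path lengths (brute-force oracle)", {
  tr <- read_newick("((A:1,B:1):1,C:2);")
  C <- bm_covariance(tr)
  expect_equal(C["A", "B"], 1)
  expect_equal(C["A", "A"], 2)
  expect_equal(C["A", "C"], 0)
  ## star tree: no shared paths
  star <- ape::stree(5, "star")
  star$edge.length <- rep(3, 5)
  expect_equal(bm_covariance(star), diag(3, 5), ignore_attr = TRUE)
  ## random non-ultrametric trees against the per-pair path walk
  for (seed in 1:3) {
    fx <- random_fixture(8, seed)
    expect_equal(bm_covariance(fx$tree), oracle_bm_cov(fx$tree),
                 tolerance = 1e-12)
  }
})

test_that("BM log-likelihood equals the dense multivariate-normal density", {
  ## single tip at its mean
  one <- structure(list(edge = matrix(c(2L, 1L), 1), tip.label = "A",
                        edge.length = 1.7, Nnode = 1L), class = "phylo")
  expect_equal(bm_loglik(one, c(A = 0.5), sigma2 = 2, mu = 0.5),
               -0.5 * log(2 * pi * 2 * 1.7), tolerance = 1e-12)
  for (seed in 4:6) {
    fx <- random_fixture(8, seed)
    C <- oracle_bm_cov(fx$tree)
    for (s2 in c(0.5, 2)) {
      expect_equal(bm_loglik(fx$tree, fx$x, s2, mu = 0.3),
                   oracle_mvn(fx$x[rownames(C)], rep(0.3, 8), s2 * C),
                   tolerance = 1e-8)
    }
  }
  ## invariant to consistent permutation of tip order
  fx <- random_fixture(8, 7)
  xp <- fx$x[sample(names(fx$x))]
  expect_equal(bm_loglik(fx$tree, xp, 1, 0), bm_loglik(fx$tree, fx$x, 1, 0))
})

test_that("BM fitting maximizes the likelihood and reduces to iid on a star tree", {
  star <- ape::stree(3, "star")
  star$edge.length <- rep(1, 3)
  star$tip.label <- c("a", "b", "c")
  f <- fit_bm(star, c(a = 1, b = 2, c = 3))
  expect_equal(f$mu, 2)
  expect_equal(f$sigma2, 2 / 3)
  ## constant trait: degenerate boundary flagged
  fc <- fit_bm(star, c(a = 1, b = 1, c = 1))
  expect_true(fc$degenerate)
  ## against a dense numerical optimization oracle
  fx <- random_fixture(10, 8)
  f <- fit_bm(fx$tree, fx$x)
  C <- oracle_bm_cov(fx$tree)
  obj <- function(par) -oracle_mvn(fx$x[rownames(C)], rep(par[1], 10),
                                   exp(par[2]) * C)
  o <- optim(c(mean(fx$x), 0), obj, method = "Nelder-Mead",
             control = list(reltol = 1e-14, maxit = 5000))
  expect_equal(f$mu, o$par[1], tolerance = 1e-5)
  expect_equal(f$sigma2, exp(o$par[2]), tolerance = 1e-5)
  expect_gte(f$logLik + 1e-8, -o$value)
})

test_that("Hansen weights integrate regime occupancy and sum to one", {
  ## uniform painting: a single column of ones
  tr <- read_newick("((A:1,B:1):1,C:2);")
  p0 <- painting_from_shifts(tr, integer(0), character(0))
  W <- hansen_weights(tr, p0, alpha = 1.3)
  expect_equal(dim(W), c(3L, 1L))
  expect_equal(unname(W[, 1]), rep(1, 3), tolerance = 1e-12)
  ## 3-tip painted fixture against segment-by-segment hand integration
  p1 <- painting_from_shifts(tr, 1L, "up")   # first cladewise edge
  W1 <- hansen_weights(tr, p1, alpha = 1)
  th <- c(root = 0.7, up = -1.2)
  m_oracle <- oracle_hansen_mean(tr, p1, 1, th)
  m_pkg <- drop(W1 %*% th[colnames(W1)])
  expect_equal(m_pkg[names(m_oracle)], m_oracle, tolerance = 1e-10)
  ## alpha large: weight concentrates on the terminal branch's regime
  fx <- random_fixture(8, 9)
  Wb <- hansen_weights(fx$tree, fx$painting, alpha = 500)
  tree_cw <- ape::reorder.phylo(fx$tree, "cladewise")
  term_reg <- unclass(fx$painting)[match(seq_len(8), tree_cw$edge[, 2])]
  for (i in 1:8) {
    expect_gt(Wb[i, term_reg[i]], 0.999)
  }
  ## rows sum to 1 across alpha and random paintings
  for (seed in 10:12) {
    fx <- random_fixture(8, seed)
    for (a in c(1e-6, 1e-2, 1, 1e3)) {
      W <- hansen_weights(fx$tree, fx$painting, a)
      expect_equal(unname(rowSums(W)), rep(1, 8), tolerance = 1e-10)
    }
  }
  expect_error(hansen_weights(tr, p0, alpha = 0), "positive")
})

test_that("OU covariance matches its closed form, PSD, and the BM limit", {
  tr <- read_newick("((A:1,B:1):1,C:2);")
  V <- ou_covariance(tr, alpha = 0.8, sigma2 = 2)
  expect_equal(V["A", "C"], 0)                         # no shared path
  expect_equal(V["A", "A"], 2 / (2 * 0.8) * (1 - exp(-2 * 0.8 * 2)))
  ## stationary variance limit on a deep tree
  deep <- read_newick("((A:500,B:500):1,C:501);")
  expect_equal(diag(ou_covariance(deep, 1, 3))[["A"]], 3 / 2, tolerance = 1e-8)
  ## oracle equivalence and symmetry/PSD on random trees
  for (seed in 13:15) {
    fx <- random_fixture(8, seed)
    for (a in c(0.05, 1, 20)) {
      V <- ou_covariance(fx$tree, a, 1.5)
      expect_equal(V, oracle_ou_cov(fx$tree, a, 1.5), tolerance = 1e-10)
      expect_equal(V, t(V), tolerance = 1e-12)
      expect_gte(min(eigen(V, symmetric = TRUE, only.values = TRUE)$values),
                 -1e-9 * sum(diag(V)))
    }
  }
  ## alpha below the numerical floor: series evaluation close to sigma2 * C
  fx <- random_fixture(8, 16)
  Vs <- ou_covariance(fx$tree, 1e-10, 1)
  expect_equal(Vs, oracle_bm_cov(fx$tree)[rownames(Vs), colnames(Vs)],
               tolerance = 1e-4)
})

test_that("Hansen log-likelihood equals the dense mean/covariance density", {
  tr <- read_newick("((A:1,B:1):1,C:2);")
  p0 <- painting_from_shifts(tr, integer(0), character(0))
  ## all tips at the optimum: only the normalization term survives
  th0 <- c(root = 1.4)
  V <- ou_covariance(tr, 2, 1)
  ll <- hansen_loglik(tr, p0, c(A = 1.4, B = 1.4, C = 1.4), 2, 1, th0)
  expect_equal(ll, -3 / 2 * log(2 * pi) -
                 as.numeric(determinant(V)$modulus) / 2, tolerance = 1e-10)
  ## random painted fixtures against the oracle
  for (seed in 17:19) {
    fx <- random_fixture(8, seed)
    th <- c(root = 0.5, shifted = -2)
    ll <- hansen_loglik(fx$tree, fx$painting, fx$x, 1.2, 0.7, th)
    mo <- oracle_hansen_mean(fx$tree, fx$painting, 1.2, th)
    Vo <- oracle_ou_cov(fx$tree, 1.2, 0.7)
    expect_equal(ll, oracle_mvn(fx$x[names(mo)], mo, Vo), tolerance = 1e-8)
  }
  ## BM limit: alpha -> 0 with theta_root = mu
  fx <- random_fixture(8, 20)
  mu <- fit_bm(fx$tree, fx$x)$mu
  ll_ou <- hansen_loglik(fx$tree, painting_from_shifts(fx$tree, integer(0), character(0)),
                         fx$x, 1e-8, 1, c(root = mu))
  expect_equal(ll_ou, bm_loglik(fx$tree, fx$x, 1, mu), tolerance = 1e-4)
})

test_that("Hansen fitting profiles parameters and beats any alpha grid", {
  fx <- random_fixture(16, 21)
  x <- simulate_ou(fx$tree, fx$painting, alpha = 2, sigma2 = 1,
                   theta = c(root = 0, shifted = 3), seed = 22)
  f <- fit_hansen(fx$tree, fx$painting, x)
  expect_s3_class(f, "hansen_fit")
  expect_equal(f$p, 2 + 2)
  ## optimum at least as good as a fixed 25-point alpha grid (same profiling)
  H <- tree_height(fx$tree)
  cache <- handevo:::tree_cache(fx$tree)
  grid <- exp(seq(log(1e-8 / H), log(1e3 / H), length.out = 25))
  for (a in grid) {
    pr <- handevo:::hansen_profile(cache, fx$painting, x, a)
    if (!is.null(pr) && is.null(pr$error)) expect_gte(f$logLik + 1e-6, pr$logLik)
  }
  ## uniform painting: theta-hat is the OU-GLS mean
  p0 <- painting_from_shifts(fx$tree, integer(0), character(0))
  f0 <- fit_hansen(fx$tree, p0, x)
  W <- hansen_weights(fx$tree, p0, f0$alpha)
  V <- ou_covariance(fx$tree, f0$alpha, 1)
  gls <- solve(t(W) %*% solve(V, W), t(W) %*% solve(V, x[rownames(V)]))
  expect_equal(unname(f0$theta), unname(drop(gls)), tolerance = 1e-6)
  ## unreachable regime is named in the error
  bad <- regime_painting(fx$tree, rep("root", nrow(fx$tree$edge)), "root")
  attr(bad, "regimes") <- c("root", "ghostregime")
  expect_error(fit_hansen(fx$tree, bad, x), "ghostregime")
})

test_that("AICc follows the finite-sample formula and its limits", {
  expect_equal(aicc(0, 1, 10), 2.5)
  expect_equal(aicc(-5, 2, 10), 10 + 4 + 12 / 7)
  expect_lt(abs(aicc(-5, 2, 1e9) - (10 + 4)), 1e-6)    # AICc -> AIC
  expect_error(aicc(0, 5, 6), "n must exceed")
})

test_that("model comparison computes deltas and Akaike weights", {
  mk <- function(ll, p, n = 50) {
    structure(list(logLik = ll, p = p, n = n, aicc = aicc(ll, p, n),
                   tips = paste0("t", 1:10)), class = "evo_fit")
  }
  cmp <- compare_models(list(a = mk(-10, 2), b = mk(-10, 2)))
  expect_equal(cmp$weight, c(0.5, 0.5))
  ## delta of 20 AICc units
  two <- compare_models(list(good = mk(-10, 2), bad = mk(-20, 2)))
  expect_equal(two$delta_AICc, c(0, 20))
  expect_equal(two$weight, c(1, exp(-10)) / (1 + exp(-10)), tolerance = 1e-12)
  expect_equal(sum(two$weight), 1, tolerance = 1e-12)
  ## mismatched tip sets rejected
  other <- mk(-5, 2); other$tips <- paste0("u", 1:10)
  expect_error(compare_models(list(a = mk(-1, 2), b = other)), "mismatched")
})

test_that("multivariate fits sum per-trait likelihoods under a shared painting", {
  fx <- random_fixture(16, 23)
  X <- cbind(t1 = simulate_ou(fx$tree, fx$painting, 1, 0.5,
                              c(root = 0, shifted = 2), seed = 24),
             t2 = simulate_ou(fx$tree, fx$painting, 1, 0.5,
                              c(root = 1, shifted = -1), seed = 25))
  mf <- fit_multi(fx$tree, fx$painting, X)
  f1 <- fit_hansen(fx$tree, fx$painting, X[, 1])
  f2 <- fit_hansen(fx$tree, fx$painting, X[, 2])
  expect_equal(mf$logLik, f1$logLik + f2$logLik, tolerance = 1e-10)
  expect_equal(mf$p, f1$p + f2$p)
  expect_equal(mf$n, 16 * 2)
  expect_equal(mf$aicc, aicc(f1$logLik + f2$logLik, f1$p + f2$p, 32),
               tolerance = 1e-12)
  ## adding a regime never decreases the joint log-likelihood
  extra <- painting_from_shifts(fx$tree, c(fx$shift, fx$shift %% nrow(fx$tree$edge) + 1L),
                                c("shifted", "extra"))
  mf2 <- fit_multi(fx$tree, extra, X)
  expect_gte(mf2$logLik + 1e-6, mf$logLik)
})
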