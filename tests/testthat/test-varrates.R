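test_that("likelihood matches closed forms and a brute-force oracle", {
  # cherry with unit branches, Y = (0,0), R = 1: density of a bivariate
  # normal at its (profiled) mean = -ln(2*pi)
  ch <- read_newick(text = "(A:1,B:1);")
  Y0 <- matrix(c(0, 0), 2, 1, dimnames = list(c("A", "B"), NULL))
  expect_equal(mn_loglik(Y0, ch, R = matrix(1)), -log(2 * pi),
               tolerance = 1e-12)
  # brute-force vec(Y) ~ N(0, R (x) C) on random trees of <= 6 tips
  for (seed in 1:4) {
    n <- sample(3:6, 1)
    tr <- random_time_tree(n, seed = seed, extant = FALSE, mbl = 2)
    q <- sample(1:3, 1)
    Y <- matrix(rnorm(n * q, sd = 3), n, q,
                dimnames = list(tr$phy$tip.label, NULL))
    A <- matrix(rnorm(q * q), q)
    R <- crossprod(A) + diag(q)
    C <- phylo_cov(tr)$C[rownames(Y), rownames(Y)]
    expect_equal(mn_loglik(Y, tr, R), brute_mn_loglik(Y, C, R),
                 tolerance = 1e-8)
    # pruning computation agrees with the dense reference
    expect_equal(mn_loglik(Y, tr, R, method = "pruning"),
                 mn_loglik(Y, tr, R), tolerance = 1e-8)
    # with random branch scalars too
    sc <- exp(rnorm(nrow(tr$phy$edge), 0, 0.5))
    expect_equal(mn_loglik(Y, tr, R, scalars = sc, method = "pruning"),
                 mn_loglik(Y, tr, R, scalars = sc), tolerance = 1e-8)
  }
})

test_that("likelihood shows the scalar/covariance scale non-identifiability", {
  tr <- random_time_tree(8, seed = 9, extant = FALSE)
  set.seed(10)
  Y <- matrix(rnorm(16), 8, 2, dimnames = list(tr$phy$tip.label, NULL))
  R <- diag(2) + 0.3
  E <- nrow(tr$phy$edge)
  expect_equal(mn_loglik(Y, tr, R, scalars = rep(2, E)),
               mn_loglik(Y, tr, 2 * R), tolerance = 1e-10)
  expect_error(mn_loglik(Y, tr, matrix(c(1, 2, 2, 1), 2)), "positive definite")
})

test_that("q = 1 reduces to the univariate phylogenetic GLS BM likelihood", {
  tr <- random_time_tree(6, seed = 12, extant = FALSE)
  set.seed(13)
  y <- matrix(rnorm(6), 6, 1, dimnames = list(tr$phy$tip.label, NULL))
  sig2 <- 0.7
  C <- sig2 * phylo_cov(tr)$C[rownames(y), rownames(y)]
  # independent univariate oracle: N(mu-hat, sig2*C) density at y
  Ci <- solve(C)
  mu <- sum(Ci %*% y) / sum(Ci)
  v <- y - mu
  oracle <- drop(-0.5 * (as.numeric(determinant(C)$modulus) +
                           t(v) %*% Ci %*% v + 6 * log(2 * pi)))
  expect_equal(mn_loglik(y, tr, matrix(sig2)), oracle, tolerance = 1e-9)
})

test_that("the sampler is seed-deterministic", {
  tr <- random_time_tree(8, seed = 20, extant = FALSE)
  set.seed(21)
  Y <- matrix(rnorm(8 * 2), 8, 2, dimnames = list(tr$phy$tip.label, NULL))
  t1 <- rj_mcmc(Y, tr, iterations = 5000, thin = 10, seed = 5)
  t2 <- rj_mcmc(Y, tr, iterations = 5000, thin = 10, seed = 5)
  expect_identical(t1$r, t2$r)
  expect_identical(t1$loglik, t2$loglik)
  t3 <- rj_mcmc(Y, tr, iterations = 5000, thin = 10, seed = 6)
  expect_false(identical(t3$loglik, t2$loglik))
  expect_error(rj_mcmc(Y, tr, iterations = 0), "positive")
})

test_that("prior-only sampling reproduces the geometric prior on set size", {
  tr <- random_time_tree(10, seed = 30, extant = FALSE)
  set.seed(31)
  Y <- matrix(rnorm(10 * 2), 10, 2, dimnames = list(tr$phy$tip.label, NULL))
  E <- nrow(tr$phy$edge)
  frac <- 0.1                      # prior mean 10% of branches scaled
  tr0 <- rj_mcmc(Y, tr, iterations = 200000, burnin = 20000, thin = 20,
                 seed = 7, beta = 0, prior_mean_frac = frac)
  p <- 1 / (1 + frac * E)
  obs <- table(factor(pmin(tr0$k, 6), levels = 0:6))
  expected <- c(dgeom(0:5, p), 1 - pgeom(5, p))
  gof <- suppressWarnings(chisq.test(as.vector(obs), p = expected))
  expect_gt(gof$p.value, 0.01)
})

test_that("PSRF behaves on iid, separated and identical chains", {
  set.seed(40)
  iid <- lapply(1:2, function(i) rnorm(10000))
  expect_lt(gelman_rubin(iid)$loglik_psrf, 1.01)
  apart <- list(rnorm(2000), rnorm(2000, 100))
  expect_gt(gelman_rubin(apart)$loglik_psrf, 1.2)
  same <- rnorm(500)
  expect_lte(gelman_rubin(list(same, same))$loglik_psrf, 1 + 1e-9)
  expect_error(gelman_rubin(list(rnorm(10))), "2 chains")
  # multi-chain MCMC traces give a full per-scalar report
  tr <- random_time_tree(6, seed = 41, extant = FALSE)
  Y <- matrix(rnorm(12), 6, 2, dimnames = list(tr$phy$tip.label, NULL))
  chains <- rj_mcmc(Y, tr, iterations = 20000, thin = 20, seed = 1,
                    chains = 2)
  rep_ <- gelman_rubin(chains)
  expect_length(rep_$scalar_psrf, nrow(tr$phy$edge))
  # the estimator can dip below 1 by O(1/n) sampling noise, never more
  expect_true(all(rep_$scalar_psrf >= 1 - 5e-3))
})

test_that("run selection retains the highest-mean run with documented ties", {
  fake <- function(mll) structure(list(loglik = rnorm(200, mll, 0.01),
                                       r = matrix(1, 200, 4), k = rep(0, 200)),
                                  class = "vr_trace")
  set.seed(50)
  reps <- list(fake(-100), fake(-95), fake(-98))
  sel <- suppressWarnings(select_run(reps))
  expect_equal(sel$index, 2L)
  # tie -> lowest index
  set.seed(51)
  a <- fake(-95)
  tie <- suppressWarnings(select_run(list(a, a)))
  expect_equal(tie$index, 1L)
  expect_warning(select_run(list(fake(-90))), "single replicate")
  expect_error(suppressWarnings(select_run(list(fake(-100), fake(-95)),
                                           strict = TRUE)), "converged")
})

test_that("posterior concentrates near truth in a single-rate regime", {
  # data simulated under single-rate BM: branch posterior means hug 1
  tr <- random_time_tree(25, seed = 60, extant = FALSE, mbl = 2)
  C <- phylo_cov(tr)$C
  set.seed(61)
  ch <- chol(C)
  Y <- crossprod(ch, matrix(rnorm(25 * 3), 25, 3)) * 0.5
  rownames(Y) <- rownames(C)
  trc <- rj_mcmc(Y, tr, iterations = 100000, thin = 50, seed = 62)
  pm <- posterior_mean_scalars(trc)
  expect_gt(mean(pm >= 0.5 & pm <= 2), 0.9)
})

test_that("a strong clade scalar is recovered by the sampler", {
  hits <- 0
  for (s in 1:3) {
    sp <- sim_spec(n_birds = 10, n_theropods = 8, n_nontheropods = 8,
                   K = 30, n_regions = 2, missingness = 0, prealigned = TRUE,
                   rho = 0, seed = 600 + s,
                   scalars = list(NonTheropodDinosauria = 8))
    tr <- simulate_tree(sp)
    d <- simulate_landmarks(tr, sp)
    Y <- two_d_array(d$coords)[tr$phy$tip.label, ]
    pca <- phylo_pca(Y, phylo_cov(tr))
    sc <- pca$scores[, seq_len(min(4, pca$q)), drop = FALSE]
    trc <- rj_mcmc(sc, tr, iterations = 100000, thin = 100, seed = s)
    pm <- posterior_mean_scalars(trc)
    idx <- clade_branches(tr, "NonTheropodDinosauria")
    hits <- hits + (mean(pm[idx]) > mean(pm[-idx]))
  }
  expect_gte(hits, 2)
})

test_that("model comparison favours variable rates only when warranted", {
  # identical models (scalars frozen both arms, same seeds): log BF exactly 0
  tr <- random_time_tree(10, seed = 70, extant = FALSE)
  set.seed(71)
  Y <- matrix(rnorm(20), 10, 2, dimnames = list(tr$phy$tip.label, NULL))
  cmp0 <- model_compare(Y, tr, rungs = 4, iter_per_rung = 2000, seed = 3,
                        freeze_scalars = TRUE)
  expect_equal(cmp0$log_bf, 0)
  expect_error(model_compare(Y, tr, rungs = 1), "rungs")
  # a 20x clade scalar on a 30-tip tree: positive log BF
  sp <- sim_spec(n_birds = 12, n_theropods = 9, n_nontheropods = 9, K = 30,
                 n_regions = 2, missingness = 0, prealigned = TRUE, rho = 0,
                 seed = 72, scalars = list(NonTheropodDinosauria = 20))
  trs <- simulate_tree(sp)
  d <- simulate_landmarks(trs, sp)
  pca <- phylo_pca(two_d_array(d$coords)[trs$phy$tip.label, ],
                   phylo_cov(trs))
  sc <- pca$scores[, seq_len(min(3, pca$q)), drop = FALSE]
  cmp1 <- model_compare(sc, trs, rungs = 8, iter_per_rung = 5000, seed = 4)
  expect_gt(cmp1$log_bf, 0)
})

test_that("trace files round-trip the sparse scalar encoding", {
  tr <- random_time_tree(6, seed = 80, extant = FALSE)
  Y <- matrix(rnorm(12), 6, 2, dimnames = list(tr$phy$tip.label, NULL))
  trc <- rj_mcmc(Y, tr, iterations = 10000, thin = 50, seed = 2)
  f <- tempfile(fileext = ".tsv")
  write_trace_tsv(trc, f)
  d <- read.delim(f)
  expect_equal(nrow(d), nrow(trc$r))
  expect_equal(d$loglik, trc$loglik, tolerance = 1e-6)
  expect_equal(d$k, trc$k)
  unlink(f)
})
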