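make_trace <- function(r, elen = NULL) {
  structure(list(r = r, loglik = rnorm(nrow(r)), k = rowSums(r != 1)),
            class = "vr_trace")
}

test_that("time-corrected clade means follow the documented arithmetic", {
  # two cherries with branch sums 10 and 20, all scalars 1
  nwk <- "((A:2.5,B:2.5):1,(C:5,D:5):1);"
  tr <- read_newick(text = nwk, tip_ages = "infer")
  tr$groups <- setNames(c("G1", "G1", "G2", "G2"), c("A", "B", "C", "D"))
  expect_equal(clade_branch_sum(tr, "G1"), 5)
  expect_equal(clade_branch_sum(tr, "G2"), 10)
  S <- 7
  trace <- make_trace(matrix(1, S, nrow(tr$phy$edge)))
  cms <- clade_mean_scalars(trace, tr)
  expect_equal(dim(cms), c(S, 2))             # one value per posterior sample
  expect_equal(unique(cms[, "G1"]), 1 / 5)
  expect_equal(unique(cms[, "G2"]), 1 / 10)
  # doubling all branch lengths halves every time-corrected value
  tr2 <- tr
  tr2$phy$edge.length <- tr2$phy$edge.length * 2
  tr2 <- time_tree(tr2$phy, tip_ages = "infer")
  tr2$groups <- tr$groups
  cms2 <- clade_mean_scalars(trace, tr2)
  expect_equal(cms2, cms / 2, tolerance = 1e-12)
  # height vs branch-sum differ by a per-group constant only
  cmh <- clade_mean_scalars(trace, tr, scaling = "height")
  ratio <- cms / cmh
  expect_equal(apply(ratio, 2, function(x) diff(range(x))), c(G1 = 0, G2 = 0))
  # uncorrected option drops the divisor
  expect_equal(unique(clade_mean_scalars(trace, tr, scaling = "none")[, 1]), 1)
})

test_that("rank-sum comparison separates what should separate and no more", {
  set.seed(1)
  res <- compare_groups(list(a = rnorm(500), b = rnorm(500, 5)))
  expect_lt(res$p_value, 1e-10)
  expect_true(res$significant)
  same <- rep(c(1, 2, 3), 20)
  res2 <- compare_groups(list(a = same, b = same))
  expect_gt(res2$p_value, 0.9)
  expect_message(compare_groups(list(a = rep(1, 5), b = rep(1, 5))),
                 "degenerate")
  expect_error(compare_groups(list(a = rnorm(5))), "2 groups")
})

test_that("rank-sum type-I error is controlled at the stringent threshold", {
  # two groups repeatedly drawn from one null distribution
  set.seed(2)
  flags <- replicate(200, {
    x <- rnorm(80); y <- rnorm(80)
    compare_groups(list(a = x, b = y))$significant
  })
  expect_lte(mean(flags), 0.01)
})

test_that("sigma_mult has its star-tree closed form and oracle", {
  # star tree, q = 1: variance of tips about the mean over branch length
  st <- star_tree(9, b = 4)
  set.seed(3)
  y <- matrix(rnorm(9), 9, 1, dimnames = list(st$phy$tip.label, NULL))
  got <- sigma_mult(y, phylo_cov(st))$pooled
  expect_equal(got, sum((y - mean(y))^2) / (9 * 4), tolerance = 1e-10)
  # brute-force GLS computation on small trees (explicit eigen C^(-1/2))
  for (seed in 4:6) {
    tr <- random_time_tree(6, seed = seed, extant = FALSE)
    Y <- matrix(rnorm(6 * 4), 6, 4, dimnames = list(tr$phy$tip.label, NULL))
    C <- phylo_cov(tr)$C[rownames(Y), rownames(Y)]
    eg <- eigen(C, symmetric = TRUE)
    P <- eg$vectors %*% diag(1 / sqrt(eg$values)) %*% t(eg$vectors)
    Ci <- solve(C)
    a <- drop((t(rep(1, 6)) %*% Ci %*% Y) / sum(Ci))
    U <- P %*% sweep(Y, 2, a)
    part <- c(1, 1, 2, 2)
    brute <- vapply(split(1:4, part), function(cc)
      sum(U[, cc]^2) / (6 * length(cc)), numeric(1))
    got <- sigma_mult(Y, C, partition = part, by = "traits")$rates
    expect_equal(unname(got), unname(brute), tolerance = 1e-10)
  }
})

test_that("sigma_mult normalization makes partitions of unequal size comparable", {
  tr <- random_time_tree(8, seed = 7, extant = FALSE)
  set.seed(8)
  Y <- matrix(rnorm(8 * 3), 8, 3, dimnames = list(tr$phy$tip.label, NULL))
  C <- phylo_cov(tr)
  one <- sigma_mult(Y, C, partition = rep(1, 3), by = "traits")$rates
  # duplicating every column doubles the raw sum but not the per-trait rate
  Y2 <- cbind(Y, Y)
  two <- sigma_mult(Y2, C, partition = rep(1, 6), by = "traits")$rates
  expect_equal(unname(two), unname(one), tolerance = 1e-12)
})

test_that("sigma_mult recovers a 4x rate difference between taxon groups", {
  hits <- 0
  nsims <- 30
  for (s in seq_len(nsims)) {
    sp <- sim_spec(n_birds = 10, n_theropods = 10, n_nontheropods = 10,
                   K = 12, n_regions = 2, missingness = 0, seed = 400 + s,
                   scalars = list(NonTheropodDinosauria = 4))
    tra <- simulate_tree(sp)
    # evolve traits under the true branch-scaled covariance, then estimate
    # per-group rates assuming the unscaled tree
    Cs <- phylo_cov(tra, simulate_landmarks(tra, sp)$truth$edge_scalars)$C
    set.seed(4000 + s)
    Y <- crossprod(chol(Cs), matrix(rnorm(30 * 6), 30, 6))
    rownames(Y) <- rownames(Cs)
    grp <- tra$groups[rownames(Y)]
    est <- sigma_mult(Y, phylo_cov(tra), partition = grp, by = "taxa")$rates
    r <- est["NonTheropodDinosauria"] / est["Aves"]
    hits <- hits + (r >= 2.5 && r <= 6)
  }
  expect_gte(hits, ceiling(0.8 * nsims))
})

test_that("sigma_mult permutation-free test calibrates and detects", {
  # exact null: single-rate BM; moderate alternative: strong rate ratio
  set.seed(9)
  tra <- random_time_tree(20, extant = FALSE, mbl = 2)
  grp <- setNames(rep(c("g1", "g2"), each = 10), tra$phy$tip.label)
  C <- phylo_cov(tra)$C
  ch <- chol(C)
  ps <- replicate(60, {
    Y <- crossprod(ch, matrix(rnorm(20 * 4), 20, 4))
    rownames(Y) <- rownames(C)
    sigma_mult_test(Y, C, partition = grp[rownames(Y)], by = "taxa",
                    nsim = 49)$p_value
  })
  expect_gt(mean(ps < 0.05), 0)  # not degenerate at 0 rejections... bound below
  expect_lt(mean(ps < 0.05), 0.2)
  expect_gt(mean(ps), 0.3)       # roughly uniform, not collapsed near 0
  # the trivial case: observed ratio 1 gives p ~ 1
  Yc <- matrix(rep(crossprod(ch, rnorm(20)), 2), 20, 2)
  rownames(Yc) <- rownames(C)
  pt <- sigma_mult_test(Yc, C, partition = c(1, 2), by = "traits",
                        nsim = 49)
  expect_equal(pt$observed_ratio, 1, tolerance = 1e-9)
  expect_gt(pt$p_value, 0.9)
  expect_error(sigma_mult_test(Yc, C, rep(1, 20), nsim = 0), "nsim")
})

test_that("per-landmark rates rank fast regions above slow ones", {
  hits <- 0
  for (s in 1:10) {
    sp <- sim_spec(n_birds = 6, n_theropods = 5, n_nontheropods = 5, K = 24,
                   n_regions = 2, sigma2 = c(1e-4, 5e-4), rho = 0,
                   missingness = 0, prealigned = TRUE, seed = 900 + s)
    tr <- simulate_tree(sp)
    d <- simulate_landmarks(tr, sp)
    al <- gpa(d)
    ord <- match(tr$phy$tip.label, al$specimens)
    C <- phylo_cov(tr)
    rates <- per_landmark_rates(al$coords[, , ord], C)
    fast <- mean(rates[d$regions == "region_02"])
    slow <- mean(rates[d$regions == "region_01"])
    hits <- hits + (fast > slow)
  }
  expect_gte(hits, 9)
  # constant landmark has rate 0 and permutation equivariance holds
  tr <- random_time_tree(6, seed = 10, extant = FALSE)
  set.seed(11)
  A <- array(rnorm(5 * 3 * 6), c(5, 3, 6),
             dimnames = list(NULL, NULL, tr$phy$tip.label))
  A[2, , ] <- 0.5  # identical across specimens
  C <- phylo_cov(tr)
  r <- per_landmark_rates(A, C)
  expect_equal(unname(r[2]), 0, tolerance = 1e-12)
  perm <- c(3, 1, 2, 5, 4)
  r2 <- per_landmark_rates(A[perm, , ], C)
  expect_equal(unname(r2), unname(r[perm]), tolerance = 1e-12)
})

test_that("the subsampling protocol keeps one bird per order and reproduces", {
  sp <- tiny_spec(seed = 12, missingness = 0)
  tr <- simulate_tree(sp)
  d <- simulate_landmarks(tr, sp)
  birds <- clade_tips(tr, "Aves")
  orders <- data.frame(taxon = birds,
                       order = rep(c("ord1", "ord2", "ord3"), length.out = 6))
  res1 <- subsample_protocol(d, tr, orders, iterations = 2, seed = 5)
  res2 <- subsample_protocol(d, tr, orders, iterations = 2, seed = 5)
  expect_identical(res1, res2)
  expect_equal(ncol(res1), 3)  # one summary per group
  # count check: an iteration keeps exactly one bird per order + all fossils
  counter <- function(dd, tt) {
    b <- intersect(tt$phy$tip.label, birds)
    c(n_birds = length(b), n_total = length(tt$phy$tip.label))
  }
  res3 <- subsample_protocol(d, tr, orders, iterations = 3, seed = 6,
                             analysis = counter)
  expect_true(all(res3[, "n_birds"] == 3))
  expect_true(all(res3[, "n_total"] == 3 + 8))
  expect_error(subsample_protocol(d, tr, orders[-1, ], iterations = 1),
               "cover")
})
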