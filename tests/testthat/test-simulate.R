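test_that("simulated trees honour the spec: counts, tags, ages, determinism", {
  sp <- tiny_spec(seed = 42)
  tr1 <- simulate_tree(sp)
  tr2 <- simulate_tree(sp)
  expect_equal(write_newick(tr1), write_newick(tr2))  # seed-reproducible
  expect_equal(length(tr1$phy$tip.label), 14L)
  tab <- table(tr1$groups)
  expect_equal(unname(tab[c("Aves", "NonAvianTheropoda",
                            "NonTheropodDinosauria")]), c(6L, 4L, 4L),
               ignore_attr = TRUE)
  birds <- clade_tips(tr1, "Aves")
  expect_true(all(tr1$tip_ages[birds] == 0))
  fossils <- setdiff(names(tr1$tip_ages), birds)
  expect_true(all(tr1$tip_ages[fossils] >= sp$fossil_age_range[1]))
  expect_true(all(tr1$tip_ages[fossils] <= sp$fossil_age_range[2]))
  # the default preset matches the intended sampling design: 77 tips
  expect_error(sim_spec(n_birds = 1), "at least 2")
  df <- sim_spec()
  expect_equal(df$n_birds + df$n_theropods + df$n_nontheropods, 77L)
})

test_that("landmark simulation is reproducible and respects masks", {
  sp <- tiny_spec(seed = 9, missingness = 0.3)
  tr <- simulate_tree(sp)
  d1 <- simulate_landmarks(tr, sp)
  d2 <- simulate_landmarks(tr, sp)
  expect_identical(d1$coords, d2$coords)
  # masked regions contain no finite coordinates; present regions complete
  for (i in seq_len(nrow(d1$present)))
    for (rg in colnames(d1$present)) {
      vals <- d1$coords[d1$regions == rg, , i]
      if (d1$present[i, rg]) expect_true(all(is.finite(vals)))
      else expect_true(all(is.na(vals)))
    }
  # only fossils lose regions
  birds <- clade_tips(tr, "Aves")
  expect_true(all(d1$present[birds, ]))
  # truth record carries what was used
  expect_equal(d1$truth$rho, sp$rho)
  expect_equal(length(d1$truth$edge_scalars), nrow(tr$phy$edge))
})

test_that("tip covariance across replicates matches the closed form sigma2*C", {
  # 5-tip tree, one region, rho = 0, prealigned: replicate simulations give
  # an empirical tip covariance per trait that converges to sigma2 * C
  tr <- random_time_tree(5, seed = 2, extant = FALSE, mbl = 5)
  sp <- sim_spec(n_birds = 2, n_theropods = 2, n_nontheropods = 2, K = 8,
                 n_regions = 1, sigma2 = 1e-3, rho = 0, missingness = 0,
                 prealigned = TRUE, seed = NULL)
  C <- phylo_cov(tr)$C
  nrep <- 400
  set.seed(99)
  acc <- array(0, c(5, 5))
  for (r in seq_len(nrep)) {
    d <- simulate_landmarks(tr, sp)
    X <- two_d_array(d$coords)[rownames(C), ]
    Xc <- sweep(X, 2, as.vector(t(d$truth$template)))  # deviation from root
    acc <- acc + tcrossprod(Xc) / ncol(X)
  }
  emp <- acc / nrep
  expect_equal(emp, 1e-3 * C, tolerance = 0.15, ignore_attr = TRUE)
})

test_that("a clade scalar inflates within-clade divergence accordingly", {
  sp <- tiny_spec(seed = 5, missingness = 0, prealigned = TRUE, rho = 0,
                  K = 60, n_regions = 4, sigma2 = 1e-4,
                  scalars = list(NonTheropodDinosauria = 10))
  tr <- simulate_tree(sp)
  d <- simulate_landmarks(tr, sp)
  r <- d$truth$edge_scalars
  idx <- clade_branches(tr, "NonTheropodDinosauria")
  expect_true(all(r[idx] == 10) && all(r[-idx] == 1))
  # mean squared independent contrast inside the scaled clade is ~10x the
  # background at large K (contrasts standardized by the unscaled tree)
  X <- two_d_array(d$coords)
  contrast_ms <- function(tree, taxa) {
    sub <- keep_taxa(tree, taxa)
    pic <- apply(X[sub$phy$tip.label, ], 2, function(y)
      ape::pic(y, ape::multi2di(sub$phy)))
    mean(pic^2)
  }
  fast <- contrast_ms(tr, clade_tips(tr, "NonTheropodDinosauria"))
  slow <- contrast_ms(tr, clade_tips(tr, "NonAvianTheropoda"))
  expect_gt(fast / slow, 4)
  expect_lt(fast / slow, 25)
})

test_that("zero-depth tree leaves all specimens at the template", {
  nwk <- "(A:1e-12,B:1e-12,C:1e-12);"
  tr <- read_newick(text = nwk)
  sp <- sim_spec(n_birds = 2, n_theropods = 2, n_nontheropods = 2, K = 12,
                 n_regions = 2, missingness = 0, prealigned = TRUE, seed = 3)
  d <- simulate_landmarks(tr, sp)
  for (i in 1:3)
    expect_equal(d$coords[, , i], d$truth$template, tolerance = 1e-4,
                 ignore_attr = TRUE)
})

test_that("per-region disparity ranks follow the region base rates", {
  # two regions with 16-fold rate difference: empirical disparity ordering
  # matches in the clear majority of replicates
  hits <- 0
  for (s in 1:20) {
    sp <- sim_spec(n_birds = 4, n_theropods = 3, n_nontheropods = 3, K = 24,
                   n_regions = 2, sigma2 = c(1e-4, 16e-4), rho = 0,
                   missingness = 0, prealigned = TRUE, seed = 100 + s)
    tr <- simulate_tree(sp)
    d <- simulate_landmarks(tr, sp)
    al <- gpa(d)
    pv <- sapply(unique(d$regions), function(rg)
      sum(apply(al$coords[d$regions == rg, , ], 3, var)) )
    hits <- hits + (pv["region_02"] > pv["region_01"])
  }
  expect_gte(hits, 17)
})

test_that("make_synthetic writes a complete, readable dataset", {
  dir <- tempfile("synth")
  sp <- tiny_spec(seed = 7)
  out <- make_synthetic(sp, dir)
  expect_true(all(file.exists(unlist(out$paths))))
  tr <- read_newick(file = out$paths$tree, tip_ages = out$paths$ages,
                    groups = out$paths$groups)
  expect_equal(sort(tr$phy$tip.label), sort(out$tree$phy$tip.label))
  d <- read_landmarks_csv(out$paths$coords, out$paths$regions,
                          out$paths$modules)
  expect_equal(dim(d$coords), dim(out$data$coords))
  got <- d$coords[, , dimnames(out$data$coords)[[3]]]
  expect_equal(got, out$data$coords, tolerance = 1e-9, ignore_attr = TRUE)
  truth <- read.delim(out$paths$truth, header = FALSE)
  expect_true(any(grepl("^sigma2", truth$V1)))
  unlink(dir, recursive = TRUE)
})

test_that("TPS round-trip preserves coordinates and ids", {
  set.seed(8)
  A <- as_array3(lapply(1:3, function(i) matrix(rnorm(15), 5, 3)),
                 ids = c("a", "b", "c"))
  f <- tempfile(fileext = ".tps")
  write_tps(A, f)
  B <- read_tps(f)
  expect_equal(dimnames(B)[[3]], c("a", "b", "c"))
  expect_equal(B, A, tolerance = 1e-8, ignore_attr = TRUE)
  unlink(f)
})
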