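# Shared fixtures: small trees, landmark configurations and simulation
# presets built in code at test time.

# ((A:1,B:1):1,C:2); the worked 3-tip example used throughout
tree3 <- function() read_newick(text = "((A:1,B:1):1,C:2);")

# ultrametric star tree with n tips at depth b
star_tree <- function(n = 6, b = 1) {
  nwk <- paste0("(", paste(sprintf("t%d:%g", seq_len(n), b), collapse = ","),
                ");")
  read_newick(text = nwk)
}

# random dated tree: random topology, random fossil tip ages, MBL-dated
random_time_tree <- function(n, seed = NULL, extant = TRUE, mbl = 1) {
  if (!is.null(seed)) set.seed(seed)
  topo <- ape::rtree(n, br = NULL)
  ages <- if (extant) setNames(rep(0, n), topo$tip.label) else
    setNames(runif(n, 0, 100), topo$tip.label)
  mbl_date(topo, tip_ages = ages, mbl = mbl)
}

# a planar triangle plus apex point (non-degenerate 3D tetrahedron-ish)
base_config <- function() {
  rbind(c(0, 0, 0), c(1, 0, 0), c(0.3, 1.2, 0), c(0.4, 0.4, 0.9))
}

rot_z <- function(theta) {
  rbind(c(cos(theta), -sin(theta), 0),
        c(sin(theta), cos(theta), 0),
        c(0, 0, 1))
}

# K x 3 x N array from list of K x 3 matrices
as_array3 <- function(confs, ids = NULL) {
  K <- nrow(confs[[1]])
  A <- array(NA_real_, c(K, 3, length(confs)),
             dimnames = list(NULL, c("x", "y", "z"),
                             ids %||% sprintf("s%d", seq_along(confs))))
  for (i in seq_along(confs)) A[, , i] <- confs[[i]]
  A
}
`%||%` <- function(a, b) if (is.null(a)) b else a

# tiny simulation preset used by several test files
tiny_spec <- function(seed = 11, ...) {
  args <- utils::modifyList(
    list(n_birds = 6L, n_theropods = 4L, n_nontheropods = 4L, K = 24L,
         n_regions = 4L, seed = seed, missingness = 0.1), list(...))
  do.call(sim_spec, args)
}

# brute-force matrix-normal log-density of Y (GLS-centred) with cov R (x) C
brute_mn_loglik <- function(Y, C, R) {
  N <- nrow(Y); q <- ncol(Y)
  Ci <- solve(C); one <- rep(1, N)
  a <- drop((t(one) %*% Ci %*% Y) / sum(Ci))
  v <- as.vector(Y - rep(1, N) %o% a)
  S <- kronecker(R, C)
  drop(-0.5 * (as.numeric(determinant(S)$modulus) + t(v) %*% solve(S, v) +
                 N * q * log(2 * pi)))
}
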