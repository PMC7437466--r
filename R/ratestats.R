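# Clade-level and landmark-level rate summaries: time-corrected mean rate
# scalars with rank-sum tests, the sigma-mult multivariate rate statistic
# with simulation-based significance, per-landmark rates and the taxonomic
# subsampling protocol.

#' Time-corrected per-clade mean rate scalars
#'
#' For each posterior sample and each tagged group, the mean of the branch
#' rate scalars over the group's branches, divided by a time correction:
#' either the sum of the group's branch lengths (default) or the subtree
#' height. The two conventions differ only by a per-group positive constant.
#'
#' @param trace A `vr_trace` (post-burn-in samples).
#' @param tree The [time_tree] the trace was sampled on (grouped).
#' @param groups Group tags to summarise (default: all tags on the tree).
#' @param scaling `"branch_sum"` (sum of branch lengths), `"height"`
#'   (subtree height), or `"none"`. The time correction divides by a
#'   deterministic per-group constant, so corrected values are on different
#'   scales across groups even when every branch has scalar 1; `"none"`
#'   leaves the mean scalar itself, whose null expectation is the same for
#'   every group, and is therefore the right input for null-calibrated
#'   significance testing of rate differences.
#' @param include_stem Include each clade's stem branch?
#' @return `S x G` matrix of time-corrected mean scalars (samples x groups).
#' @export
clade_mean_scalars <- function(trace, tree, groups = NULL,
                               scaling = c("branch_sum", "height", "none"),
                               include_stem = FALSE) {
  stopifnot(inherits(trace, "vr_trace"), inherits(tree, "time_tree"))
  scaling <- match.arg(scaling)
  if (is.null(groups)) groups <- unique(tree$groups)
  if (!length(groups)) stop("no group tags available")
  out <- sapply(groups, function(g) {
    idx <- clade_branches(tree, g, include_stem)
    if (!length(idx)) stop("empty branch set for group: ", g)
    denom <- switch(scaling,
                    branch_sum = sum(tree$phy$edge.length[idx]),
                    height = clade_height(tree, g),
                    none = 1)
    rowMeans(trace$r[, idx, drop = FALSE]) / denom
  })
  colnames(out) <- groups
  out
}

#' Pairwise rank-sum comparison of group distributions
#'
#' Two-sided Wilcoxon rank-sum tests for every pair of groups, flagging
#' pairs whose distributions differ at `p < alpha` (default the stringent
#' 5e-5 threshold used for rate-scalar comparisons). Degenerate pairs
#' (both groups constant and identical) get `p = 1` by convention.
#'
#' @param distributions `S x G` matrix (e.g. from [clade_mean_scalars]) or a
#'   named list of numeric vectors.
#' @param alpha Flagging threshold.
#' @return Data frame with columns `group1`, `group2`, `p_value`,
#'   `significant`.
#' @export
compare_groups <- function(distributions, alpha = 5e-5) {
  if (is.matrix(distributions) || is.data.frame(distributions)) {
    distributions <- as.data.frame(distributions)
    distributions <- lapply(distributions, as.numeric)
  }
  gnames <- names(distributions)
  if (length(distributions) < 2L) stop("need at least 2 groups")
  if (any(lengths(distributions) < 2L)) stop("each group needs >= 2 values")
  pairs <- utils::combn(length(distributions), 2)
  res <- apply(pairs, 2, function(ij) {
    x <- distributions[[ij[1]]]; y <- distributions[[ij[2]]]
    if (length(unique(c(x, y))) == 1L) {
      message("degenerate comparison (identical constant groups): p = 1")
      return(1)
    }
    # exact test for small samples, normal approximation with continuity
    # correction otherwise (wilcox.test's own switching rule at n = 50)
    suppressWarnings(wilcox.test(x, y, exact = NULL, correct = TRUE)$p.value)
  })
  data.frame(group1 = gnames[pairs[1, ]], group2 = gnames[pairs[2, ]],
             p_value = as.numeric(res), significant = as.numeric(res) < alpha,
             stringsAsFactors = FALSE)
}

# symmetric inverse square root with eigenvalue floor
.inv_sqrt <- function(C, floor_frac = 1e-12) {
  C <- (C + t(C)) / 2
  eg <- eigen(C, symmetric = TRUE)
  lam <- pmax(eg$values, floor_frac * max(eg$values))
  eg$vectors %*% (t(eg$vectors) / sqrt(lam))
}

#' Multivariate evolutionary rate (sigma-mult)
#'
#' Computes the net multivariate Brownian rate from phylogenetically
#' transformed data `U = C^{-1/2} (Y - 1a')`, with `a` the GLS mean: the
#' total squared transformed deviation divided by (number of contributing
#' taxa x number of traits), per partition. Partitions are either groups of
#' taxa (rows; `by = "taxa"`) or groups of trait columns (`by = "traits"`,
#' e.g. one partition per landmark). Dividing by the trait count makes rates
#' comparable across partitions of unequal size.
#'
#' @param Y `N x p` trait matrix (rows in `C`'s taxon order).
#' @param C A [phylo_cov] or covariance matrix.
#' @param partition Labels: length `N` when `by = "taxa"`, length `p` when
#'   `by = "traits"`. `NULL` pools everything into one rate.
#' @param by Whether the partition labels apply to rows or columns.
#' @return List with `rates` (named per-partition rates), `ratio`
#'   (max / min), `pooled` (single-rate estimate), `U`, `mean`.
#' @export
sigma_mult <- function(Y, C, partition = NULL, by = c("taxa", "traits")) {
  by <- match.arg(by)
  Y <- as.matrix(Y)
  Cm <- .cov_matrix(C)
  stopifnot(nrow(Y) == nrow(Cm))
  N <- nrow(Y); p <- ncol(Y)
  Ci <- .safe_inv(Cm)
  one <- rep(1, N)
  a <- drop((crossprod(one, Ci) %*% Y) / sum(Ci))
  U <- .inv_sqrt(Cm) %*% sweep(Y, 2, a)
  pooled <- sum(U^2) / (N * p)
  if (is.null(partition)) {
    rates <- c(pooled = pooled)
  } else if (by == "taxa") {
    if (length(partition) != N) stop("taxa partition must have length N")
    rates <- vapply(split(seq_len(N), partition), function(idx)
      sum(U[idx, , drop = FALSE]^2) / (length(idx) * p), numeric(1))
  } else {
    if (length(partition) != p) stop("trait partition must have length p")
    rates <- vapply(split(seq_len(p), partition), function(idx)
      sum(U[, idx, drop = FALSE]^2) / (N * length(idx)), numeric(1))
  }
  list(rates = rates, ratio = max(rates) / min(rates), pooled = pooled,
       U = U, mean = a)
}

#' Simulation-based significance test for sigma-mult rate ratios
#'
#' Simulates `nsim` datasets under single-rate multivariate BM with the
#' pooled rate (traits independent, each with the pooled per-trait rate),
#' recomputes the max/min rate ratio for each, and reports
#' `p = (#{simulated ratio >= observed} + 1) / (nsim + 1)`. Trait
#' correlations are not preserved in the null draws; the ratio statistic is
#' computed on per-trait-normalised sums, which makes it only weakly
#' sensitive to them.
#'
#' @inheritParams sigma_mult
#' @param nsim Number of null simulations (>= 1; 999 for reported analyses).
#' @param seed Optional RNG seed.
#' @return List with `p_value`, `observed_ratio`, `null_ratios`, `rates`.
#' @export
sigma_mult_test <- function(Y, C, partition, by = c("taxa", "traits"),
                            nsim = 999L, seed = NULL) {
  by <- match.arg(by)
  if (nsim < 1L) stop("'nsim' must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  Y <- as.matrix(Y)
  Cm <- .cov_matrix(C)
  obs <- sigma_mult(Y, C, partition, by)
  N <- nrow(Y); p <- ncol(Y)
  # null generative model: single pooled per-trait rate, independent traits
  sd_pooled <- sqrt(obs$pooled)
  Chalf <- .mat_sqrt(Cm)
  null_ratios <- vapply(seq_len(nsim), function(s) {
    Ys <- Chalf %*% matrix(rnorm(N * p, sd = sd_pooled), N, p)
    rownames(Ys) <- rownames(Cm)
    sigma_mult(Ys, Cm, partition, by)$ratio
  }, numeric(1))
  p_val <- (sum(null_ratios >= obs$ratio) + 1) / (nsim + 1)
  list(p_value = p_val, observed_ratio = obs$ratio,
       null_ratios = null_ratios, rates = obs$rates)
}

.mat_sqrt <- function(M, floor_frac = 1e-12) {
  M <- (M + t(M)) / 2
  eg <- eigen(M, symmetric = TRUE)
  lam <- pmax(eg$values, floor_frac * max(eg$values, 0), 0)
  eg$vectors %*% (t(eg$vectors) * sqrt(lam))
}

#' Per-landmark evolutionary rates
#'
#' [sigma_mult] with every landmark's three coordinates as its own
#' partition — the per-landmark rate map under single-rate BM.
#'
#' @param aligned An `aligned_dataset` (from [gpa]) or a `K x 3 x N` array.
#' @param C A [phylo_cov] or matrix for the aligned specimens (taxon order =
#'   specimen order of the array).
#' @return Named length-K numeric vector of rates (names = landmark index).
#' @export
per_landmark_rates <- function(aligned, C) {
  A <- if (inherits(aligned, "aligned_dataset")) aligned$coords else aligned
  K <- dim(A)[1]
  Y <- two_d_array(A)
  part <- rep(seq_len(K), each = 3)
  r <- sigma_mult(Y, C, partition = part, by = "traits")$rates
  r[order(as.integer(names(r)))]
}

#' Taxonomic subsampling protocol
#'
#' Repeatedly subsamples one bird per avian order (keeping all fossil taxa),
#' prunes the tree and data, reruns a designated rate analysis and collects
#' the per-group summaries. Used to check that group rate differences are
#' robust to the much denser sampling of extant birds.
#'
#' @param data A [landmark_dataset] whose `meta` has `specimen` and `group`.
#' @param tree A grouped [time_tree].
#' @param orders Data frame (or CSV path) with columns `taxon`, `order`
#'   covering all bird tips.
#' @param iterations Number of subsampling iterations (>= 1).
#' @param seed RNG seed; fixed seed reproduces the draws.
#' @param analysis `"sigma"` (per-group [sigma_mult] on aligned shapes) or a
#'   function `(data_sub, tree_sub) -> named numeric` of per-group values.
#' @param bird_tag Group label identifying birds.
#' @param scope Regions to align/analyse (default all).
#' @return `iterations x G` matrix of per-group rate summaries.
#' @export
subsample_protocol <- function(data, tree, orders, iterations = 100L,
                               seed = 1L, analysis = "sigma",
                               bird_tag = "Aves", scope = NULL) {
  stopifnot(inherits(data, "landmark_dataset"), inherits(tree, "time_tree"))
  if (iterations < 1L) stop("'iterations' must be >= 1")
  if (is.character(orders) && length(orders) == 1L && file.exists(orders))
    orders <- read.csv(orders, stringsAsFactors = FALSE)
  if (!all(c("taxon", "order") %in% names(orders)))
    stop("orders table must have columns taxon, order")
  birds <- clade_tips(tree, bird_tag)
  uncovered <- setdiff(birds, orders$taxon)
  if (length(uncovered))
    stop("orders table does not cover all birds: ",
         paste(utils::head(uncovered, 5), collapse = ", "))
  orders <- orders[orders$taxon %in% birds, ]
  split_orders <- split(orders$taxon, orders$order)
  empty <- lengths(split_orders) == 0L
  if (any(empty)) {
    warning("skipping empty orders: ",
            paste(names(split_orders)[empty], collapse = ", "))
    split_orders <- split_orders[!empty]
  }
  non_birds <- setdiff(tree$phy$tip.label, birds)

  analysis_fun <- if (is.function(analysis)) analysis else
    function(d, tr) {
      al <- gpa(d, scope = scope)
      keep <- al$specimens
      tr2 <- keep_taxa(tr, keep)
      Y <- two_d_array(al$coords)[tr2$phy$tip.label, , drop = FALSE]
      grp <- tr2$groups[rownames(Y)]
      sigma_mult(Y, phylo_cov(tr2), partition = grp, by = "taxa")$rates
    }

  set.seed(seed)
  out <- NULL
  for (it in seq_len(iterations)) {
    chosen <- vapply(split_orders, function(tx)
      if (length(tx) == 1L) tx else sample(tx, 1L), character(1))
    keep <- c(unname(chosen), non_birds)
    tr_sub <- keep_taxa(tree, keep)
    sel <- match(keep, data$meta$specimen)
    d_sub <- landmark_dataset(data$coords[, , sel, drop = FALSE],
                              data$regions, data$modules,
                              data$meta[sel, , drop = FALSE],
                              data$present[sel, , drop = FALSE])
    res <- analysis_fun(d_sub, tr_sub)
    if (is.null(out))
      out <- matrix(NA_real_, iterations, length(res),
                    dimnames = list(NULL, names(res)))
    out[it, names(res)] <- res
  }
  out
}
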