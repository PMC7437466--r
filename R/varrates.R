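# Variable-rates multivariate Brownian motion: reference matrix-normal
# likelihood, reversible-jump MCMC (C++ core), convergence diagnostics,
# marginal-likelihood model comparison and replicate-run selection.

.edge_inputs <- function(tree) {
  phy <- tree$phy  # already postorder
  list(edge = phy$edge, elen = phy$edge.length,
       ntip = length(phy$tip.label),
       nnode = length(phy$tip.label) + phy$Nnode)
}

#' Matrix-normal log-likelihood of the (variable-rates) BM model
#'
#' Profile log-likelihood of an `N x q` trait matrix `Y` under multivariate
#' Brownian motion on a time tree, with optional per-branch rate scalars and
#' trait covariance `R`:
#' `-1/2 [ q ln|C(r)| + N ln|R| + tr(R^-1 (Y-1a')' C(r)^-1 (Y-1a')) + Nq ln 2pi ]`
#' where `C(r)` is the scalar-weighted phylogenetic covariance and `a` the
#' GLS mean under `C(r)`. This dense-matrix form is the reference; the MCMC
#' uses an algebraically identical pruning computation.
#'
#' @param Y `N x q` matrix (rows ordered as `tree$phy$tip.label`) or a
#'   `score_matrix` (its retained scores are used).
#' @param tree A [time_tree].
#' @param R `q x q` symmetric positive-definite trait covariance.
#' @param scalars Optional per-branch positive scalars (postorder edge order).
#' @param method `"dense"` (reference) or `"pruning"` (C++ core).
#' @return Log-likelihood scalar.
#' @export
mn_loglik <- function(Y, tree, R, scalars = NULL, method = c("dense", "pruning")) {
  method <- match.arg(method)
  Y <- .score_rows(Y, tree)
  N <- nrow(Y); q <- ncol(Y)
  R <- as.matrix(R)
  stopifnot(nrow(R) == q, ncol(R) == q)
  if (max(abs(R - t(R))) > 1e-10) stop("R must be symmetric")
  evR <- eigen((R + t(R)) / 2, symmetric = TRUE, only.values = TRUE)$values
  if (min(evR) <= 0) stop("R must be positive definite")
  if (is.null(scalars)) scalars <- rep(1, n_edges(tree))
  if (method == "pruning") {
    ei <- .edge_inputs(tree)
    return(prune_loglik_cpp(Y, ei$edge, ei$elen, scalars, ei$ntip, ei$nnode, R))
  }
  C <- phylo_cov(tree, scalars)$C[rownames(Y), rownames(Y)]
  cC <- tryCatch(chol(C), error = function(e)
    stop("singular phylogenetic covariance"))
  Ci <- chol2inv(cC)
  one <- rep(1, N)
  a <- drop((crossprod(one, Ci) %*% Y) / sum(Ci))
  Xc <- sweep(Y, 2, a)
  cR <- chol(R)
  quad <- sum(diag(chol2inv(cR) %*% crossprod(Xc, Ci %*% Xc)))
  logdetC <- 2 * sum(log(diag(cC)))
  logdetR <- 2 * sum(log(diag(cR)))
  -0.5 * (q * logdetC + N * logdetR + quad + N * q * log(2 * pi))
}

.score_rows <- function(Y, tree) {
  if (inherits(Y, "score_matrix")) {
    sc <- Y$scores
    rownames(sc) <- Y$taxa
    Y <- sc
  }
  Y <- as.matrix(Y)
  tips <- tree$phy$tip.label
  if (!is.null(rownames(Y))) {
    missing <- setdiff(tips, rownames(Y))
    if (length(missing))
      stop("trait matrix lacks rows for: ", paste(missing, collapse = ", "))
    Y <- Y[tips, , drop = FALSE]
  } else if (nrow(Y) != length(tips)) {
    stop("trait matrix rows do not match tree tips")
  } else rownames(Y) <- tips
  Y
}

# empirical Cholesky init for R from phylogenetic independent contrasts
.init_chol <- function(Y, tree) {
  q <- ncol(Y)
  pics <- try(apply(Y, 2, function(y)
    ape::pic(y, ape::multi2di(tree$phy))), silent = TRUE)
  S <- if (inherits(pics, "try-error")) stats::cov(Y) else crossprod(pics) / nrow(pics)
  S <- (S + t(S)) / 2 + diag(1e-10 + 1e-6 * mean(diag(S)), q)
  t(chol(S))
}

#' Reversible-jump MCMC for the variable-rates BM model
#'
#' Samples the posterior over the set of rate-scaled branches, their scalars
#' and the trait covariance `R`, via Metropolis-Hastings with birth / death /
#' perturb / covariance-update moves. Priors: geometric on the number of
#' scaled branches (mean `prior_mean_frac` of branches), log-Normal(0, 1) on
#' scalar values, and weak normal priors on the Cholesky factor of `R`
#' centred on an empirical (independent-contrasts) estimate. The GLS root
#' mean is profiled out. Unscaled branches have scalar exactly 1.
#'
#' @param Y `N x q` trait matrix or `score_matrix`.
#' @param tree A [time_tree].
#' @param iterations Total MCMC iterations (desk-scale default 200000).
#' @param burnin Burn-in iterations (default 10% of `iterations`).
#' @param thin Thinning interval for stored samples.
#' @param seed Integer seed; chain `i` uses `seed + i - 1`.
#' @param chains Number of independent chains.
#' @param prior_mean_frac Prior mean number of scaled branches as a fraction
#'   of the branch count.
#' @param r_meanlog,r_sdlog Log-normal prior parameters for scalar values.
#' @param eps_sd Scale-perturbation step (on log scalars).
#' @param L_step Covariance Cholesky random-walk step.
#' @param beta Likelihood temperature (1 = posterior, 0 = prior-only;
#'   intermediate values are used by stepping-stone sampling).
#' @param fix_scalars If `TRUE`, all scalars are frozen at 1 (single-rate
#'   model); only `R` is updated.
#' @return If `chains == 1`, a `vr_trace`; otherwise a `vr_chains` list of
#'   traces. A `vr_trace` holds matrices `r` (samples x branches), `loglik`,
#'   `k`, `R_vech`, acceptance counts and the run configuration.
#' @export
rj_mcmc <- function(Y, tree, iterations = 200000L, burnin = NULL,
                    thin = 100L, seed = 1L, chains = 1L,
                    prior_mean_frac = 0.02, r_meanlog = 0, r_sdlog = 1,
                    eps_sd = 0.3, L_step = 0.15, beta = 1,
                    fix_scalars = FALSE) {
  stopifnot(inherits(tree, "time_tree"))
  if (iterations <= 0 || thin <= 0) stop("iteration counts must be positive")
  if (is.null(burnin)) burnin <- as.integer(iterations * 0.1)
  if (burnin < 0 || burnin >= iterations) stop("invalid burn-in")
  Y <- .score_rows(Y, tree)
  ei <- .edge_inputs(tree)
  E <- nrow(ei$edge)
  geom_p <- 1 / (1 + prior_mean_frac * E)
  Linit <- .init_chol(Y, tree)
  cfg <- list(iterations = as.integer(iterations), burnin = as.integer(burnin),
              thin = as.integer(thin), beta = beta,
              fix_scalars = fix_scalars, geom_p = geom_p,
              r_meanlog = r_meanlog, r_sdlog = r_sdlog, eps_sd = eps_sd,
              L_step = L_step, Linit = Linit,
              Ldiag_prior_sd = 3, Loff_prior_sd = 3 * max(diag(Linit)))
  run_one <- function(ch) {
    set.seed(seed + ch - 1L)
    out <- vr_mcmc_cpp(Y, ei$edge, ei$elen, ei$ntip, ei$nnode, cfg)
    structure(list(r = out$r, loglik = drop(out$loglik), k = drop(out$k),
                   R_vech = out$R_vech, accept = out$accept,
                   tries = out$tries, edge = ei$edge,
                   edge_length = ei$elen, tip_labels = tree$phy$tip.label,
                   iterations = iterations, burnin = burnin, thin = thin,
                   beta = beta, seed = seed + ch - 1L,
                   fix_scalars = fix_scalars, q = ncol(Y)),
              class = "vr_trace")
  }
  traces <- lapply(seq_len(chains), run_one)
  if (chains == 1L) traces[[1]] else structure(traces, class = "vr_chains")
}

#' @export
print.vr_trace <- function(x, ...) {
  cat("vr_trace:", nrow(x$r), "samples,", ncol(x$r), "branches; mean k =",
      format(mean(x$k), digits = 4), "; mean loglik =",
      format(mean(x$loglik), digits = 6), "\n")
  acc <- ifelse(x$tries > 0, x$accept / x$tries, NA)
  cat("acceptance (birth/death/perturb/cov):",
      paste(format(acc, digits = 2), collapse = " "), "\n")
  invisible(x)
}

#' @export
print.vr_chains <- function(x, ...) {
  cat("vr_chains:", length(x), "chains\n")
  for (tr in x) print(tr)
  invisible(x)
}

#' Posterior mean rate scalar per branch
#' @param trace A `vr_trace`.
#' @return Numeric vector, one value per branch (postorder edge order).
#' @export
posterior_mean_scalars <- function(trace) {
  stopifnot(inherits(trace, "vr_trace"))
  colMeans(trace$r)
}

#' Gelman-Rubin convergence diagnostic
#'
#' Potential scale reduction factor
#' `PSRF = sqrt( ((n-1)/n * W + B/n) / W )` with within-chain variance `W`
#' (mean of per-chain variances) and between-chain variance `B`
#' (`n x` variance of chain means), computed for the log-likelihood and for
#' every branch scalar.
#'
#' @param traces A `vr_chains`, or list of >= 2 `vr_trace`s, or a list of
#'   plain numeric vectors (equal length) for a single statistic.
#' @param threshold Pass threshold on the PSRF (default 1.1).
#' @return Object of class `convergence_report`: list with `loglik_psrf`,
#'   `scalar_psrf` (per branch, `NULL` for plain vectors), `max_psrf`,
#'   `threshold`, `pass`.
#' @export
gelman_rubin <- function(traces, threshold = 1.1) {
  if (inherits(traces, "vr_trace")) stop("need at least 2 chains")
  if (length(traces) < 2L) stop("need at least 2 chains")
  psrf <- function(mat) {  # columns = chains
    n <- nrow(mat)
    W <- mean(apply(mat, 2, var))
    B <- n * var(colMeans(mat))
    if (W <= 0) return(1)
    sqrt(((n - 1) / n * W + B / n) / W)
  }
  if (inherits(traces[[1]], "vr_trace")) {
    n <- min(vapply(traces, function(t) length(t$loglik), integer(1)))
    ll <- vapply(traces, function(t) t$loglik[seq_len(n)], numeric(n))
    ll_psrf <- psrf(ll)
    E <- ncol(traces[[1]]$r)
    sc_psrf <- vapply(seq_len(E), function(e)
      psrf(vapply(traces, function(t) t$r[seq_len(n), e], numeric(n))),
      numeric(1))
  } else {
    n <- min(lengths(traces))
    ll <- vapply(traces, function(v) as.numeric(v[seq_len(n)]), numeric(n))
    ll_psrf <- psrf(ll)
    sc_psrf <- NULL
  }
  maxp <- max(c(ll_psrf, sc_psrf))
  structure(list(loglik_psrf = ll_psrf, scalar_psrf = sc_psrf,
                 max_psrf = maxp, threshold = threshold,
                 pass = maxp < threshold),
            class = "convergence_report")
}

#' @export
print.convergence_report <- function(x, ...) {
  cat("convergence_report: loglik PSRF =", format(x$loglik_psrf, digits = 4))
  if (!is.null(x$scalar_psrf))
    cat("; max scalar PSRF =", format(max(x$scalar_psrf), digits = 4))
  cat("; ", if (x$pass) "PASS" else "FAIL", " at ", x$threshold, "\n", sep = "")
  invisible(x)
}

# log(mean(exp(x))) without overflow
.log_mean_exp <- function(x) {
  m <- max(x)
  m + log(mean(exp(x - m)))
}

# stepping-stone marginal likelihood: temperatures beta_k = (k/K)^(1/alpha)
.stepping_stone <- function(Y, tree, rungs, iter_per_rung, burn_frac, seed,
                            fix_scalars, alpha = 0.3, ...) {
  betas <- (seq(0, rungs) / rungs)^(1 / alpha)
  logml <- 0
  for (k in seq_len(rungs)) {
    b_lo <- betas[k]; b_hi <- betas[k + 1]
    tr <- rj_mcmc(Y, tree, iterations = iter_per_rung,
                  burnin = as.integer(iter_per_rung * burn_frac),
                  thin = max(1L, iter_per_rung %/% 200L),
                  seed = seed + k, beta = b_lo,
                  fix_scalars = fix_scalars, ...)
    logml <- logml + .log_mean_exp((b_hi - b_lo) * tr$loglik)
  }
  logml
}

#' Bayes-factor comparison of variable-rates vs single-rate BM
#'
#' Estimates the marginal likelihood of each model by stepping-stone
#' sampling and reports the log Bayes factor on the `2 * (lnML1 - lnML0)`
#' scale (positive favours variable rates).
#'
#' @inheritParams rj_mcmc
#' @param rungs Number of stepping-stone temperature rungs (>= 2).
#' @param iter_per_rung MCMC iterations per rung.
#' @param burn_frac Burn-in fraction per rung.
#' @param freeze_scalars If `TRUE` the "variable-rates" arm is also run with
#'   scalars frozen at 1, making the two models identical (log BF exactly 0);
#'   used as a self-check.
#' @return List with `log_bf`, `logml_vr`, `logml_sr`, `rungs`.
#' @export
model_compare <- function(Y, tree, rungs = 16L, iter_per_rung = 10000L,
                          burn_frac = 0.2, seed = 1L,
                          freeze_scalars = FALSE, ...) {
  if (rungs < 2L) stop("need at least 2 stepping-stone rungs")
  Y <- .score_rows(Y, tree)
  logml_sr <- .stepping_stone(Y, tree, rungs, iter_per_rung, burn_frac,
                              seed, fix_scalars = TRUE, ...)
  logml_vr <- .stepping_stone(Y, tree, rungs, iter_per_rung, burn_frac,
                              seed, fix_scalars = freeze_scalars, ...)
  list(log_bf = 2 * (logml_vr - logml_sr), logml_vr = logml_vr,
       logml_sr = logml_sr, rungs = rungs)
}

#' Select the replicate run to retain
#'
#' Given replicate MCMC runs, checks convergence across them (PSRF of the
#' log-likelihood) and returns the run with the highest mean post-burn-in
#' log-likelihood. Ties break to the lowest run index.
#'
#' @param replicates List of `vr_trace`s (>= 1).
#' @param threshold PSRF pass threshold.
#' @param strict If `TRUE`, a cross-replicate log-likelihood PSRF above the
#'   threshold is an error ("no converged run"); by default it only warns,
#'   so that a best run can still be reported from imperfect replicates.
#' @return List with `trace` (the retained run), `index`, `criterion`
#'   (per-run mean log-likelihood), `psrf`.
#' @export
select_run <- function(replicates, threshold = 1.1, strict = FALSE) {
  if (inherits(replicates, "vr_trace")) replicates <- list(replicates)
  stopifnot(length(replicates) >= 1L,
            all(vapply(replicates, inherits, logical(1), "vr_trace")))
  crit <- vapply(replicates, function(t) mean(t$loglik), numeric(1))
  psrf <- NA_real_
  if (length(replicates) >= 2L) {
    rep_conv <- gelman_rubin(replicates, threshold)
    psrf <- rep_conv$loglik_psrf
    if (!is.finite(psrf)) psrf <- 1
    if (psrf >= threshold) {
      msg <- paste0("no converged run: log-likelihood PSRF = ", format(psrf))
      if (strict) stop(msg) else warning(msg)
    }
  } else {
    warning("single replicate supplied; returning it without convergence check")
  }
  idx <- which.max(crit)  # which.max takes the first maximum: documented tie-break
  list(trace = replicates[[idx]], index = idx, criterion = crit, psrf = psrf)
}

#' Write a posterior trace as a tab-separated table
#'
#' Columns: `sample`, `loglik`, `k`, then sparse-encoded scaled branches as
#' `branch:value` pairs in a single column.
#'
#' @param trace A `vr_trace`.
#' @param file Output path.
#' @export
write_trace_tsv <- function(trace, file) {
  stopifnot(inherits(trace, "vr_trace"))
  S <- nrow(trace$r)
  enc <- vapply(seq_len(S), function(s) {
    idx <- which(trace$r[s, ] != 1)
    if (!length(idx)) return("")
    paste(sprintf("%d:%.6g", idx, trace$r[s, idx]), collapse = ";")
  }, character(1))
  d <- data.frame(sample = seq_len(S), loglik = trace$loglik, k = trace$k,
                  scalars = enc)
  utils::write.table(d, file, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(file)
}
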