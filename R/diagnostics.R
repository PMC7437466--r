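# Sampling-artefact diagnostics: do groups differ in branch-length
# distributions (which could bias mean rates), and is the inferred rate on a
# branch predicted by that branch's length?

#' Welch two-sample t test on branch lengths between groups
#'
#' Compares the distributions of branch lengths (Myr) between two tagged
#' clades with Welch's unequal-variance t test — densely sampled extant
#' clades have systematically shorter branches, which could artificially
#' depress their mean rate scalars.
#'
#' @param tree A grouped [time_tree].
#' @param groups Character vector of exactly two group tags.
#' @param include_stem Include stem branches?
#' @return List with `t`, `df` (Welch), `p_value`, and per-group `n`.
#' @export
branch_length_ttest <- function(tree, groups, include_stem = FALSE) {
  stopifnot(inherits(tree, "time_tree"), length(groups) == 2L)
  x <- tree$phy$edge.length[clade_branches(tree, groups[1], include_stem)]
  y <- tree$phy$edge.length[clade_branches(tree, groups[2], include_stem)]
  if (length(x) < 2L || length(y) < 2L) stop("each group needs >= 2 branches")
  if (var(x) == 0 && var(y) == 0) {
    if (isTRUE(all.equal(mean(x), mean(y))))
      return(list(t = 0, df = length(x) + length(y) - 2, p_value = 1,
                  n = c(length(x), length(y))))
    stop("zero variance in both groups")
  }
  tt <- t.test(x, y, var.equal = FALSE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p_value = tt$p.value, n = c(length(x), length(y)))
}

#' Regression of log rate on branch length
#'
#' Ordinary least squares of the log-transformed posterior-mean branch rate
#' scalar on branch length. A strong relationship would indicate that rate
#' heterogeneity is an artefact of branch-length estimation rather than a
#' biological signal.
#'
#' @param trace A `vr_trace` (or a numeric vector of per-branch mean rates).
#' @param tree The [time_tree] the trace was sampled on.
#' @return List with `slope`, `intercept`, `r_squared`, `p_value`, `n`.
#' @export
rate_branchlength_regression <- function(trace, tree) {
  stopifnot(inherits(tree, "time_tree"))
  rates <- if (inherits(trace, "vr_trace")) posterior_mean_scalars(trace)
  else as.numeric(trace)
  t_j <- tree$phy$edge.length
  if (length(rates) != length(t_j))
    stop("one rate per branch required")
  if (length(t_j) < 3L) stop("need at least 3 branches")
  lr <- log(rates)
  if (var(lr) < 1e-24 * max(1, mean(lr)^2))  # constant rates: no trend
    return(list(slope = 0, intercept = mean(lr), r_squared = 0, p_value = 1,
                n = length(t_j)))
  fit <- lm(lr ~ t_j)
  sm <- summary(fit)
  slope_p <- if (nrow(sm$coefficients) > 1) sm$coefficients[2, 4] else NA_real_
  if (sm$sigma == 0) slope_p <- if (abs(coef(fit)[2]) > 0) 0 else 1
  r2 <- sm$r.squared
  if (!is.finite(r2)) r2 <- 0  # constant response: no variance explained
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       r_squared = r2, p_value = unname(slope_p),
       n = length(t_j))
}
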