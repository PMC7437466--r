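# Phylogenetic principal components analysis: eigen-decomposition of the
# evolutionary (GLS) trait covariance about the phylogenetic mean, with
# dimension reduction to the axes holding a target cumulative variance.

# Cholesky-based inverse with a ridge fallback for ill-conditioned C
# (fossil-heavy trees can produce near-duplicate rows).
.safe_inv <- function(C, cond_max = 1e12) {
  C <- (C + t(C)) / 2
  ev <- eigen(C, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0 || max(ev) / min(ev) > cond_max) {
    ridge <- 1e-8 * sum(diag(C)) / nrow(C)
    warning("phylogenetic covariance ill-conditioned; adding ridge ",
            format(ridge))
    C <- C + diag(ridge, nrow(C))
  }
  ch <- tryCatch(chol(C), error = function(e)
    stop("phylogenetic covariance singular after ridge"))
  chol2inv(ch)
}

#' Phylogenetic (GLS) mean
#'
#' The generalized-least-squares estimate of the ancestral trait vector:
#' `a = (1' C^-1 1)^-1 1' C^-1 X`.
#'
#' @param X `N x p` trait matrix (rows in the covariance's taxon order).
#' @param C A [phylo_cov] or `N x N` covariance matrix.
#' @return Length-`p` vector.
#' @export
phylo_mean <- function(X, C) {
  X <- as.matrix(X)
  Cm <- .cov_matrix(C)
  stopifnot(nrow(X) == nrow(Cm))
  Ci <- .safe_inv(Cm)
  one <- rep(1, nrow(X))
  drop((crossprod(one, Ci) %*% X) / sum(Ci))
}

#' Phylogenetic principal components analysis
#'
#' Eigen-decomposes the evolutionary covariance
#' `(N-1)^-1 (X - 1a')' C^-1 (X - 1a')` about the GLS mean `a`, projects the
#' centred data onto the eigenvectors and retains the smallest number of
#' axes whose cumulative variance fraction reaches `var_cutoff`.
#'
#' @inheritParams phylo_mean
#' @param var_cutoff Cumulative variance fraction to retain (default 0.95).
#' @return Object of class `score_matrix`: list with `scores` (`N x q`),
#'   `all_scores`, `eigenvalues`, `loadings` (columns are axes), `varfrac`,
#'   `cumvar`, `q`, `mean`, `taxa`.
#' @export
phylo_pca <- function(X, C, var_cutoff = 0.95) {
  X <- as.matrix(X)
  Cm <- .cov_matrix(C)
  stopifnot(nrow(X) == nrow(Cm))
  N <- nrow(X)
  Ci <- .safe_inv(Cm)
  one <- rep(1, N)
  a <- drop((crossprod(one, Ci) %*% X) / sum(Ci))
  Xc <- sweep(X, 2, a)
  E <- crossprod(Xc, Ci %*% Xc) / (N - 1)
  eg <- eigen((E + t(E)) / 2, symmetric = TRUE)
  lam <- pmax(eg$values, 0)
  varfrac <- lam / sum(lam)
  cumvar <- cumsum(varfrac)
  q <- which(cumvar + 1e-12 >= var_cutoff)[1]
  scores <- Xc %*% eg$vectors
  colnames(scores) <- paste0("PC", seq_len(ncol(scores)))
  structure(list(scores = scores[, seq_len(q), drop = FALSE],
                 all_scores = scores, eigenvalues = lam,
                 loadings = eg$vectors, varfrac = varfrac, cumvar = cumvar,
                 q = q, mean = a, taxa = rownames(X) %||% rownames(Cm)),
            class = "score_matrix")
}

#' @export
print.score_matrix <- function(x, ...) {
  cat("score_matrix:", nrow(x$scores), "taxa,", x$q,
      "axes retained (cumulative variance",
      sprintf("%.1f%%)\n", 100 * x$cumvar[x$q]))
  invisible(x)
}

#' Write phylogenetic PCA results as CSV
#' @param pca A `score_matrix`.
#' @param dir Output directory.
#' @param prefix File-name prefix.
#' @export
write_pca_csv <- function(pca, dir, prefix = "pca") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sc <- data.frame(taxon = pca$taxa, pca$scores, check.names = FALSE)
  write.csv(sc, file.path(dir, paste0(prefix, "_scores.csv")),
            row.names = FALSE)
  vt <- data.frame(axis = seq_along(pca$eigenvalues),
                   eigenvalue = pca$eigenvalues, varfrac = pca$varfrac,
                   cumvar = pca$cumvar)
  write.csv(vt, file.path(dir, paste0(prefix, "_variance.csv")),
            row.names = FALSE)
  invisible(dir)
}
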