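# Generalized Procrustes analysis and related shape geometry.
# Rotations use the SVD orthogonal-Procrustes solution with a determinant
# correction so that reflections are never introduced (landmark homology
# forbids mirroring).

.centroid_size <- function(m) sqrt(sum(scale(m, scale = FALSE)^2))

# optimal rotation taking m onto target (both centred); no reflection
.opt_rot <- function(m, target) {
  s <- svd(crossprod(m, target))
  R <- s$u %*% t(s$v)
  if (det(R) < 0) {
    u <- s$u; u[, ncol(u)] <- -u[, ncol(u)]
    R <- u %*% t(s$v)
  }
  R
}

#' Generalized Procrustes alignment
#'
#' Iteratively removes translation, scale and rotation from a set of landmark
#' configurations: each specimen is centred, scaled to unit centroid size and
#' rotated (reflection-free) onto the evolving consensus until the consensus
#' stabilises. Alignment may be restricted to a set of regions (`scope`);
#' specimens missing any region in scope are excluded, mirroring per-region
#' maximal sampling of incomplete fossils.
#'
#' @param data A [landmark_dataset] or a bare `K x 3 x N` array.
#' @param scope Character vector of regions to align jointly (default: all).
#' @param tol Convergence tolerance on the consensus change (root sum of
#'   squares) between iterations. The tight default leaves the result within
#'   ~1e-9 of the fixed point, so alignment is reproducible to well below
#'   measurement precision.
#' @param max_iter Maximum number of alignment iterations.
#' @return An object of class `aligned_dataset`: list with `coords` (aligned
#'   `K' x 3 x N'` array, unit centroid size), `consensus` (`K' x 3`, itself
#'   at unit centroid size), `csize` (original centroid sizes), `specimens`,
#'   `landmarks` (indices into the input), `scope`, `iterations`.
#' @export
gpa <- function(data, scope = NULL, tol = 1e-13, max_iter = 500L) {
  if (inherits(data, "landmark_dataset")) {
    regions <- data$regions
    if (is.null(scope)) scope <- unique(regions)
    unknown <- setdiff(scope, unique(regions))
    if (length(unknown)) stop("unknown regions: ", paste(unknown, collapse = ", "))
    lm_idx <- which(regions %in% scope)
    keep <- which(apply(data$present[, scope, drop = FALSE], 1, all))
    if (length(keep) < 2L)
      stop("fewer than 2 specimens preserve all regions in scope")
    A <- data$coords[lm_idx, , keep, drop = FALSE]
  } else {
    A <- data
    lm_idx <- seq_len(dim(A)[1])
    scope <- scope %||% "all"
  }
  K <- dim(A)[1]; N <- dim(A)[3]
  if (K < 3L) stop("need at least 3 landmarks to align")
  if (anyNA(A)) stop("aligned scope contains missing coordinates")

  csize <- numeric(N)
  X <- A
  for (i in seq_len(N)) {
    m <- scale(A[, , i], scale = FALSE)     # centre
    csize[i] <- sqrt(sum(m^2))
    if (csize[i] == 0) stop("specimen ", i, " has zero centroid size")
    X[, , i] <- m / csize[i]                # unit centroid size
  }
  # check non-degenerate geometry (need rank >= 2 for a defined rotation)
  if (qr(X[, , 1])$rank < 2L)
    stop("landmarks are collinear; rotation is undefined")

  consensus <- X[, , 1]
  iter <- 0L
  repeat {
    iter <- iter + 1L
    for (i in seq_len(N)) X[, , i] <- X[, , i] %*% .opt_rot(X[, , i], consensus)
    new_cons <- apply(X, c(1, 2), mean)
    new_cons <- scale(new_cons, scale = FALSE)
    new_cons <- new_cons / sqrt(sum(new_cons^2))
    delta <- sqrt(sum((new_cons - consensus)^2))
    consensus <- new_cons
    if (delta < tol || iter >= max_iter) break
  }
  # final rotation pass onto the converged consensus
  for (i in seq_len(N)) X[, , i] <- X[, , i] %*% .opt_rot(X[, , i], consensus)
  consensus <- apply(X, c(1, 2), mean)
  # pin the arbitrary joint orientation to the consensus principal axes so
  # that alignment is idempotent and independent of input orientation
  pa <- .principal_frame(consensus)
  for (i in seq_len(N)) X[, , i] <- X[, , i] %*% pa
  consensus <- consensus %*% pa
  dimnames(consensus) <- dimnames(X)[1:2]

  structure(list(coords = X, consensus = consensus, csize = csize,
                 specimens = dimnames(A)[[3]], landmarks = lm_idx,
                 scope = scope, iterations = iter),
            class = "aligned_dataset")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# rotation to the principal axes of a centred configuration, with a fixed
# sign convention (largest-magnitude loading positive; proper rotation)
.principal_frame <- function(m) {
  v <- eigen(crossprod(scale(m, scale = FALSE)), symmetric = TRUE)$vectors
  for (j in 1:3) if (v[which.max(abs(v[, j])), j] < 0) v[, j] <- -v[, j]
  if (det(v) < 0) v[, 3] <- -v[, 3]
  v
}

#' @export
print.aligned_dataset <- function(x, ...) {
  cat("aligned_dataset:", dim(x$coords)[3], "specimens,",
      dim(x$coords)[1], "landmarks; scope:",
      paste(x$scope, collapse = ", "), "\n")
  invisible(x)
}

#' Procrustes distance between two configurations
#'
#' Root sum of squared coordinate differences over landmarks. By default the
#' two configurations are assumed to be in a common aligned frame; with
#' `align = TRUE` the second is first centred, scaled to the first's centroid
#' size and optimally rotated (no reflection) onto the first.
#'
#' @param a,b `K x 3` matrices with equal K.
#' @param align Superimpose `b` on `a` before measuring?
#' @return Non-negative scalar; 0 iff the configurations coincide.
#' @export
procrustes_distance <- function(a, b, align = FALSE) {
  a <- as.matrix(a); b <- as.matrix(b)
  if (!all(dim(a) == dim(b)))
    stop("configurations have different dimensions")
  if (align) {
    a <- scale(a, scale = FALSE); a <- a / sqrt(sum(a^2))
    b <- scale(b, scale = FALSE); b <- b / sqrt(sum(b^2))
    b <- b %*% .opt_rot(b, a)
  }
  sqrt(sum((a - b)^2))
}

#' Per-landmark deviation from the consensus shape
#'
#' For every specimen and landmark, the Euclidean distance between that
#' landmark's aligned position and its position in the consensus (mean)
#' configuration — the per-landmark distance-from-mean map.
#'
#' @param aligned An [gpa] result (`aligned_dataset`).
#' @param reference Optional `K x 3` reference configuration; default the
#'   consensus.
#' @return `N x K` matrix of distances.
#' @export
per_landmark_deviation <- function(aligned, reference = NULL) {
  stopifnot(inherits(aligned, "aligned_dataset"))
  ref <- reference %||% aligned$consensus
  A <- aligned$coords
  K <- dim(A)[1]; N <- dim(A)[3]
  out <- matrix(0, N, K, dimnames = list(aligned$specimens, NULL))
  for (i in seq_len(N))
    out[i, ] <- sqrt(rowSums((A[, , i] - ref)^2))
  out
}
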