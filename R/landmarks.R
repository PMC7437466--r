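#' Landmark dataset
#'
#' Container for 3D landmark configurations: a `K x 3 x N` array (K landmarks,
#' xyz, N specimens), a region map assigning every landmark to exactly one
#' anatomical region, an optional region -> module grouping, and a per-specimen
#' per-region presence mask recording which regions each (typically fossil)
#' specimen preserves. Coordinates of absent regions are `NA`.
#'
#' @param coords Numeric array `K x 3 x N` with specimen names in
#'   `dimnames(coords)[[3]]`.
#' @param regions Character/factor of length K: region of each landmark.
#' @param modules Optional named character vector region -> module. Default:
#'   each region is its own module.
#' @param meta Optional data frame with one row per specimen (column
#'   `specimen` required; `group`, `age` used downstream).
#' @param present Optional `N x R` logical matrix (specimens x regions).
#'   Default inferred from non-`NA` coordinates.
#' @return An object of class `landmark_dataset`.
#' @export
landmark_dataset <- function(coords, regions, modules = NULL, meta = NULL,
                             present = NULL) {
  stopifnot(is.array(coords), length(dim(coords)) == 3L, dim(coords)[2] == 3L)
  K <- dim(coords)[1]; N <- dim(coords)[3]
  regions <- as.character(regions)
  if (length(regions) != K)
    stop("'regions' must assign each of the ", K, " landmarks to one region")
  if (anyNA(regions)) stop("every landmark must belong to exactly one region")
  specimens <- dimnames(coords)[[3]]
  if (is.null(specimens)) {
    specimens <- sprintf("spec_%03d", seq_len(N))
    dimnames(coords)[[3]] <- specimens
  }
  region_levels <- unique(regions)
  if (is.null(modules)) modules <- setNames(region_levels, region_levels)
  if (!all(region_levels %in% names(modules)))
    stop("module scheme does not cover regions: ",
         paste(setdiff(region_levels, names(modules)), collapse = ", "))
  if (is.null(present)) {
    present <- t(vapply(region_levels, function(r)
      apply(coords[regions == r, 1, , drop = FALSE], 3,
            function(x) all(is.finite(x))), logical(N)))
    present <- t(present)  # N x R
    dimnames(present) <- list(specimens, region_levels)
  }
  if (is.null(meta)) meta <- data.frame(specimen = specimens,
                                        stringsAsFactors = FALSE)
  stopifnot(nrow(meta) == N)
  structure(list(coords = coords, regions = regions, modules = modules,
                 meta = meta, present = present),
            class = "landmark_dataset")
}

#' @export
print.landmark_dataset <- function(x, ...) {
  cat("landmark_dataset:", dim(x$coords)[3], "specimens,",
      dim(x$coords)[1], "landmarks,", length(unique(x$regions)), "regions\n")
  invisible(x)
}

#' Flatten a landmark array to a specimen x coordinate matrix
#'
#' Rows are specimens; columns are landmark-major `(x1, y1, z1, x2, ...)`.
#' @param A `K x 3 x N` array.
#' @return `N x 3K` matrix.
#' @export
two_d_array <- function(A) {
  K <- dim(A)[1]; N <- dim(A)[3]
  out <- t(apply(A, 3, function(m) as.vector(t(m))))
  dim(out) <- c(N, 3L * K)
  rownames(out) <- dimnames(A)[[3]]
  colnames(out) <- paste0(rep(seq_len(K), each = 3), "_", c("x", "y", "z"))
  out
}

#' Rebuild a landmark array from a flattened matrix
#' @param X `N x 3K` matrix as produced by [two_d_array].
#' @return `K x 3 x N` array.
#' @export
arrayspecs <- function(X) {
  N <- nrow(X); K <- ncol(X) / 3L
  A <- array(NA_real_, c(K, 3L, N),
             dimnames = list(NULL, c("x", "y", "z"), rownames(X)))
  for (i in seq_len(N)) A[, , i] <- matrix(X[i, ], K, 3L, byrow = TRUE)
  A
}

#' Read landmark coordinates from long-format CSV
#'
#' Expected columns: `specimen`, `landmark_id`, `x`, `y`, `z`.
#' @param file CSV path.
#' @param regions,modules,meta Passed to [landmark_dataset]; `regions` may be
#'   a CSV path (columns `landmark_id`, `region`) and `modules` a CSV path
#'   (columns `region`, `module`).
#' @return A [landmark_dataset].
#' @export
read_landmarks_csv <- function(file, regions, modules = NULL, meta = NULL) {
  d <- read.csv(file, stringsAsFactors = FALSE)
  need <- c("specimen", "landmark_id", "x", "y", "z")
  if (!all(need %in% names(d)))
    stop("coordinate CSV must have columns ", paste(need, collapse = ", "))
  specs <- unique(d$specimen)
  lms <- sort(unique(d$landmark_id))
  K <- length(lms); N <- length(specs)
  A <- array(NA_real_, c(K, 3L, N),
             dimnames = list(NULL, c("x", "y", "z"), specs))
  i <- match(d$landmark_id, lms); j <- match(d$specimen, specs)
  A[cbind(i, 1L, j)] <- d$x
  A[cbind(i, 2L, j)] <- d$y
  A[cbind(i, 3L, j)] <- d$z
  if (is.character(regions) && length(regions) == 1L && file.exists(regions)) {
    rm_ <- read.csv(regions, stringsAsFactors = FALSE)
    regions <- rm_$region[match(lms, rm_$landmark_id)]
  }
  if (is.character(modules) && length(modules) == 1L && file.exists(modules)) {
    ms <- read.csv(modules, stringsAsFactors = FALSE)
    modules <- setNames(ms$module, ms$region)
  }
  landmark_dataset(A, regions, modules, meta)
}

#' Write landmark coordinates to long-format CSV
#' @param data A [landmark_dataset].
#' @param file Output CSV path.
#' @export
write_landmarks_csv <- function(data, file) {
  A <- data$coords
  K <- dim(A)[1]; N <- dim(A)[3]
  d <- data.frame(
    specimen = rep(dimnames(A)[[3]], each = K),
    landmark_id = rep(seq_len(K), N),
    x = as.vector(A[, 1, ]), y = as.vector(A[, 2, ]), z = as.vector(A[, 3, ]))
  write.csv(d, file, row.names = FALSE)
  invisible(file)
}

#' Read a TPS landmark file
#'
#' Minimal reader for the TPS format used in geometric morphometrics:
#' `LM=K` or `LM3=K` records followed by K coordinate lines and an `ID=` or
#' `IMAGE=` line naming the specimen. 2D files are padded with z = 0.
#'
#' @param file TPS file path.
#' @return `K x 3 x N` array with specimen names.
#' @export
read_tps <- function(file) {
  lines <- trimws(readLines(file))
  lines <- lines[nzchar(lines)]
  starts <- grep("^LM3?=", lines)
  if (!length(starts)) stop("no LM= records found in ", file)
  confs <- list(); ids <- character(0)
  for (s in seq_along(starts)) {
    i <- starts[s]
    k <- as.integer(sub("^LM3?=", "", lines[i]))
    block <- lines[(i + 1):(i + k)]
    xyz <- do.call(rbind, lapply(strsplit(block, "\\s+"), as.numeric))
    if (ncol(xyz) == 2L) xyz <- cbind(xyz, 0)
    if (ncol(xyz) != 3L) stop("malformed coordinate line in ", file)
    end <- if (s < length(starts)) starts[s + 1] - 1L else length(lines)
    idline <- grep("^(ID|IMAGE)=", lines[(i + k + 1):end], value = TRUE)
    ids[s] <- if (length(idline)) sub("^(ID|IMAGE)=", "", idline[1]) else
      sprintf("spec_%03d", s)
    confs[[s]] <- xyz
  }
  K <- unique(vapply(confs, nrow, integer(1)))
  if (length(K) != 1L) stop("TPS records have differing landmark counts")
  A <- array(NA_real_, c(K, 3L, length(confs)),
             dimnames = list(NULL, c("x", "y", "z"), ids))
  for (s in seq_along(confs)) A[, , s] <- confs[[s]]
  A
}

#' Write landmark configurations to a TPS file
#' @param A `K x 3 x N` array.
#' @param file Output path.
#' @export
write_tps <- function(A, file) {
  K <- dim(A)[1]; N <- dim(A)[3]
  ids <- dimnames(A)[[3]]
  con <- file(file, "w"); on.exit(close(con))
  for (i in seq_len(N)) {
    cat(sprintf("LM3=%d\n", K), file = con)
    utils::write.table(format(A[, , i], digits = 10), con,
                       row.names = FALSE, col.names = FALSE, quote = FALSE)
    cat(sprintf("ID=%s\n", ids[i]), file = con)
  }
  invisible(file)
}
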