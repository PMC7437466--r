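#' @useDynLib morphorates, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats rnorm runif rlnorm sd var cor dist lm coef pt qnorm
#'   wilcox.test t.test dnorm setNames aggregate quantile median
#' @importFrom utils read.csv write.csv
NULL

#' Time-calibrated phylogeny
#'
#' Wraps an `ape` `phylo` object together with tip ages (Ma before present)
#' and optional taxon group labels into a validated time tree. Branch lengths
#' are in Myr; node ages are measured backwards from the present, so the age
#' of a node equals the root age minus its path length from the root. The
#' constructor checks that every tip's computed age matches its recorded age,
#' i.e. that the tree really is drawn in time units.
#'
#' @param phy An `ape::phylo` object with branch lengths (Myr). Polytomies
#'   are allowed and preserved.
#' @param tip_ages Named numeric vector of tip ages in Ma (0 = extant).
#'   Tips absent from the vector are taken as extant. Default: all extant.
#'   The string `"infer"` reads ages off the branch lengths, treating the
#'   deepest tip as extant.
#' @param groups Optional named character vector mapping taxon -> group label
#'   (e.g. `"Aves"`, `"NonAvianTheropoda"`, `"NonTheropodDinosauria"`).
#' @param tol Tolerance for the tip-age consistency check.
#' @return An object of class `time_tree`: a list with elements `phy`
#'   (edges in postorder), `tip_ages`, `groups`, `root_age`, `node_ages`.
#' @export
time_tree <- function(phy, tip_ages = NULL, groups = NULL, tol = 1e-6) {
  if (!inherits(phy, "phylo")) stop("'phy' must be an ape 'phylo' object")
  if (is.null(phy$edge.length)) stop("tree has no branch lengths")
  if (any(phy$edge.length < 0)) stop("negative branch lengths are not allowed")
  ntip <- length(phy$tip.label)
  if (ntip < 2L) stop("tree must have at least 2 tips")
  if (anyDuplicated(phy$tip.label))
    stop("duplicate tip labels: ", paste(unique(
      phy$tip.label[duplicated(phy$tip.label)]), collapse = ", "))
  phy <- ape::reorder.phylo(phy, "postorder")

  if (identical(tip_ages, "infer")) {
    # take the deepest tip as extant and read the rest off the branch lengths
    d <- ape::node.depth.edgelength(phy)[seq_len(ntip)]
    tip_ages <- setNames(max(d) - d, phy$tip.label)
  }
  ages <- setNames(rep(0, ntip), phy$tip.label)
  if (!is.null(tip_ages)) {
    if (is.null(names(tip_ages))) stop("'tip_ages' must be a named vector")
    unknown <- setdiff(names(tip_ages), phy$tip.label)
    if (length(unknown))
      stop("tip_ages refer to unknown taxa: ", paste(unknown, collapse = ", "))
    ages[names(tip_ages)] <- tip_ages
  }
  if (any(ages < 0)) stop("tip ages must be >= 0")

  depth <- ape::node.depth.edgelength(phy)  # root-to-node path lengths
  implied_root <- depth[seq_len(ntip)] + ages
  root_age <- max(implied_root)
  if (max(abs(implied_root - root_age)) > tol)
    stop("tip ages inconsistent with branch lengths: root-to-tip path + age ",
         "differs across tips by ", format(diff(range(implied_root))))
  node_ages <- root_age - depth

  if (!is.null(groups)) {
    if (is.null(names(groups))) stop("'groups' must be a named vector")
    unknown <- setdiff(names(groups), phy$tip.label)
    if (length(unknown))
      stop("groups refer to unknown taxa: ", paste(unknown, collapse = ", "))
    groups <- groups[phy$tip.label[phy$tip.label %in% names(groups)]]
  }

  structure(list(phy = phy, tip_ages = ages, groups = groups,
                 root_age = root_age, node_ages = node_ages),
            class = "time_tree")
}

#' @export
print.time_tree <- function(x, ...) {
  cat("time_tree:", length(x$phy$tip.label), "tips, root age",
      format(x$root_age, digits = 6), "Ma\n")
  if (!is.null(x$groups))
    print(table(x$groups))
  invisible(x)
}

n_tips <- function(tree) length(tree$phy$tip.label)
n_edges <- function(tree) nrow(tree$phy$edge)

#' Read a Newick tree with tip ages
#'
#' Parses a Newick string or file and attaches tip ages, validating that the
#' branch lengths are consistent with the recorded ages (all root-to-tip
#' path lengths plus tip ages must agree).
#'
#' @param text Newick string (mutually exclusive with `file`).
#' @param file Path to a Newick file.
#' @param tip_ages Named numeric vector, or a data frame / path to a
#'   2-column CSV with columns `taxon`, `age_Ma`. Missing taxa get age 0.
#' @param groups Optional taxon -> group vector, data frame or CSV path
#'   (columns `taxon`, `group`).
#' @return A [time_tree].
#' @export
read_newick <- function(text = NULL, file = NULL, tip_ages = NULL,
                        groups = NULL) {
  if (is.null(text) == is.null(file))
    stop("supply exactly one of 'text' or 'file'")
  phy <- tryCatch(
    if (is.null(text)) ape::read.tree(file = file) else ape::read.tree(text = text),
    error = function(e) stop("Newick parse error: ", conditionMessage(e)),
    warning = function(w) stop("Newick parse error: ", conditionMessage(w)))
  if (is.null(phy)) stop("Newick parse error: no tree found")
  if (!identical(tip_ages, "infer"))
    tip_ages <- .as_named(tip_ages, c("taxon", "age_Ma"))
  time_tree(phy, tip_ages = tip_ages,
            groups = .as_named(groups, c("taxon", "group")))
}

# accept named vector, data frame, or CSV path
.as_named <- function(x, cols) {
  if (is.null(x)) return(NULL)
  if (is.character(x) && length(x) == 1L && is.null(names(x)) && file.exists(x))
    x <- read.csv(x, stringsAsFactors = FALSE)
  if (is.data.frame(x)) {
    if (!all(cols %in% names(x)))
      stop("table must have columns ", paste(cols, collapse = ", "))
    return(setNames(x[[cols[2]]], x[[cols[1]]]))
  }
  if (is.null(names(x))) stop("expected a named vector, data frame or CSV path")
  x
}

#' Write a time tree to Newick
#'
#' @param tree A [time_tree].
#' @param file Optional path; if `NULL` the Newick string is returned.
#' @return The Newick string, invisibly when written to file.
#' @export
write_newick <- function(tree, file = NULL) {
  stopifnot(inherits(tree, "time_tree"))
  txt <- ape::write.tree(tree$phy)
  if (is.null(file)) return(txt)
  writeLines(txt, file)
  invisible(txt)
}

#' Minimum-branch-length tree dating
#'
#' Time-calibrates a topology to fossil tip ages. Node ages are assigned in a
#' single postorder pass: each node's age is the maximum over its children of
#' (child age + `mbl`), where a tip's age is its first-appearance age. This
#' is the minimal-age solution in which every node is at least as old as its
#' oldest descendant tip and every branch is at least `mbl` Myr long.
#'
#' @param phy Topology: an `ape::phylo` (branch lengths, if any, are ignored)
#'   or a [time_tree].
#' @param tip_ages Named vector (or data frame / CSV path) of first-appearance
#'   ages in Ma; missing taxa are extant (0).
#' @param mbl Minimum branch length in Myr (> 0); default 1.
#' @param groups Optional taxon -> group vector carried to the result.
#' @return A dated [time_tree].
#' @export
mbl_date <- function(phy, tip_ages = NULL, mbl = 1, groups = NULL) {
  if (!is.numeric(mbl) || length(mbl) != 1L || !is.finite(mbl) || mbl <= 0)
    stop("'mbl' must be a single positive number")
  if (inherits(phy, "time_tree")) phy <- phy$phy
  if (!inherits(phy, "phylo")) stop("'phy' must be a phylo or time_tree")
  phy <- ape::reorder.phylo(phy, "postorder")
  ntip <- length(phy$tip.label)
  nnode <- ntip + phy$Nnode
  ages <- setNames(rep(0, ntip), phy$tip.label)
  tip_ages <- .as_named(tip_ages, c("taxon", "age_Ma"))
  if (!is.null(tip_ages)) {
    if (!all(is.finite(tip_ages))) stop("tip ages must be finite")
    unknown <- setdiff(names(tip_ages), phy$tip.label)
    if (length(unknown))
      stop("tip_ages refer to unknown taxa: ", paste(unknown, collapse = ", "))
    ages[names(tip_ages)] <- tip_ages
  }
  node_age <- c(ages, rep(-Inf, phy$Nnode))
  # postorder: children are finalized before their parent
  for (e in seq_len(nrow(phy$edge))) {
    p <- phy$edge[e, 1]; ch <- phy$edge[e, 2]
    node_age[p] <- max(node_age[p], node_age[ch] + mbl)
  }
  phy$edge.length <- node_age[phy$edge[, 1]] - node_age[phy$edge[, 2]]
  time_tree(phy, tip_ages = ages, groups = groups)
}

#' Phylogenetic covariance matrix
#'
#' Builds the Brownian-motion covariance matrix implied by a time tree:
#' `C[i, j]` is the sum of (scalar x branch length) over the branches shared
#' by the root paths of tips i and j. With all scalars 1 this is the shared
#' path length in Myr; branch-specific rate scalars implement the
#' variable-rates model's covariance.
#'
#' @param tree A [time_tree].
#' @param scalars Optional per-branch positive multipliers, one per row of
#'   `tree$phy$edge` (postorder).
#' @return An object of class `phylo_cov`: list with `C` (N x N, tip order of
#'   `tree$phy$tip.label`), `taxa`, and `scalars`.
#' @export
phylo_cov <- function(tree, scalars = NULL) {
  stopifnot(inherits(tree, "time_tree"))
  phy <- tree$phy
  if (!is.null(scalars)) {
    if (length(scalars) != nrow(phy$edge))
      stop("'scalars' must have one entry per branch (", nrow(phy$edge), ")")
    if (any(!is.finite(scalars)) || any(scalars <= 0))
      stop("branch scalars must be positive")
    phy$edge.length <- phy$edge.length * scalars
  }
  C <- ape::vcv(phy)
  C <- C[phy$tip.label, phy$tip.label]
  structure(list(C = C, taxa = phy$tip.label, scalars = scalars),
            class = "phylo_cov")
}

.cov_matrix <- function(C) {
  if (inherits(C, "phylo_cov")) C$C else as.matrix(C)
}

#' Tips belonging to a tagged group
#' @param tree A [time_tree] with `groups`.
#' @param tag Group label.
#' @return Character vector of tip labels.
#' @export
clade_tips <- function(tree, tag) {
  stopifnot(inherits(tree, "time_tree"))
  if (is.null(tree$groups)) stop("tree has no group labels")
  tips <- names(tree$groups)[tree$groups == tag]
  if (!length(tips)) stop("unknown group tag: ", tag)
  tips
}

#' Branch set of a tagged clade
#'
#' Returns the indices (rows of `tree$phy$edge`) of the branches inside the
#' clade spanned by a group's tips: all branches descending from the group's
#' most recent common ancestor. The stem branch leading to the clade is
#' excluded by default; the branch leading to crown birds, for instance, is
#' then treated separately from the crown radiation itself.
#'
#' @inheritParams clade_tips
#' @param include_stem Include the branch subtending the clade's MRCA?
#' @return Integer vector of edge indices.
#' @export
clade_branches <- function(tree, tag, include_stem = FALSE) {
  tips <- clade_tips(tree, tag)
  phy <- tree$phy
  tip_idx <- match(tips, phy$tip.label)
  if (length(tip_idx) == 1L)  # singleton group: its own branch
    return(which(phy$edge[, 2] == tip_idx))
  mrca <- ape::getMRCA(phy, tip_idx)
  desc <- .descendants(phy, mrca)
  idx <- which(phy$edge[, 1] %in% c(mrca, desc))
  if (include_stem) idx <- c(which(phy$edge[, 2] == mrca), idx)
  sort(idx)
}

# all nodes strictly below 'node'
.descendants <- function(phy, node) {
  out <- integer(0)
  stack <- node
  while (length(stack)) {
    kids <- phy$edge[phy$edge[, 1] %in% stack, 2]
    out <- c(out, kids)
    stack <- kids[kids > length(phy$tip.label)]
  }
  out
}

#' Summed branch lengths of a tagged clade
#' @inheritParams clade_branches
#' @return Sum of branch lengths (Myr) over [clade_branches].
#' @export
clade_branch_sum <- function(tree, tag, include_stem = FALSE) {
  sum(tree$phy$edge.length[clade_branches(tree, tag, include_stem)])
}

#' Subtree height of a tagged clade
#'
#' Height of the clade as the maximum path length from the clade's MRCA to
#' any of its tips (the temporal depth of the subtree).
#' @inheritParams clade_branches
#' @export
clade_height <- function(tree, tag) {
  tips <- clade_tips(tree, tag)
  phy <- tree$phy
  tip_idx <- match(tips, phy$tip.label)
  if (length(tip_idx) == 1L)
    return(tree$phy$edge.length[which(phy$edge[, 2] == tip_idx)])
  mrca <- ape::getMRCA(phy, tip_idx)
  mrca_age <- tree$node_ages[mrca]
  max(mrca_age - tree$node_ages[tip_idx])
}

#' Extract a tagged clade as its own time tree
#' @inheritParams clade_tips
#' @return A [time_tree] for the clade's tips.
#' @export
clade_subtree <- function(tree, tag) {
  keep_taxa(tree, clade_tips(tree, tag))
}

#' Prune a time tree to a set of tips
#' @param tree A [time_tree].
#' @param taxa Tip labels to keep.
#' @return A [time_tree].
#' @export
keep_taxa <- function(tree, taxa) {
  stopifnot(inherits(tree, "time_tree"))
  missing <- setdiff(taxa, tree$phy$tip.label)
  if (length(missing)) stop("unknown taxa: ", paste(missing, collapse = ", "))
  phy <- ape::keep.tip(tree$phy, taxa)
  grp <- if (is.null(tree$groups)) NULL else
    tree$groups[names(tree$groups) %in% taxa]
  time_tree(phy, tip_ages = tree$tip_ages[taxa], groups = grp)
}
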