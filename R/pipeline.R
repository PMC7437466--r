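# End-to-end orchestration: configuration, per-region alignment -> pPCA ->
# variable-rates MCMC -> rate reports, plus sigma-mult, disparity and
# sampling diagnostics, with a manifest recording seeds and settings.

#' Build a run configuration
#'
#' Collects input paths (or in-memory objects) and analysis settings into a
#' validated configuration for [run_pipeline]. Settings may also be read
#' from a YAML file via [read_config].
#'
#' @param tree A [time_tree] or Newick path.
#' @param data A [landmark_dataset] or coordinate CSV path.
#' @param regions,modules,groups,tip_ages Paths used when `tree` / `data`
#'   are file paths (see [read_landmarks_csv], [read_newick]).
#' @param region_list Regions to analyse (default: all in the data).
#' @param alignment `"local"` (separate Procrustes fit per region) or
#'   `"global"` (one fit across `region_list`, preserving relative
#'   positions).
#' @param mcmc List of MCMC settings: `iterations`, `burnin`, `thin`,
#'   `chains`, `replicates`.
#' @param scaling Time-correction convention for clade mean scalars.
#' @param var_cutoff Cumulative variance retained by the PCA.
#' @param subsample Optional list with `orders` (table/CSV) and `iterations`
#'   to enable the taxonomic subsampling protocol.
#' @param seed Master RNG seed.
#' @param out_dir Output directory (`NULL` for no files).
#' @return Object of class `run_config`.
#' @export
run_config <- function(tree, data, regions = NULL, modules = NULL,
                       groups = NULL, tip_ages = NULL, region_list = NULL,
                       alignment = c("local", "global"),
                       mcmc = list(), scaling = "branch_sum",
                       var_cutoff = 0.95, subsample = NULL, seed = 1L,
                       out_dir = NULL) {
  alignment <- match.arg(alignment)
  if (is.character(tree)) {
    if (!file.exists(tree)) stop("tree file not found: ", tree)
    tree <- read_newick(file = tree, tip_ages = tip_ages, groups = groups)
  }
  if (is.character(data)) {
    if (!file.exists(data)) stop("coordinate file not found: ", data)
    data <- read_landmarks_csv(data, regions, modules)
  }
  stopifnot(inherits(tree, "time_tree"), inherits(data, "landmark_dataset"))
  all_regions <- unique(data$regions)
  if (is.null(region_list)) region_list <- all_regions
  unknown <- setdiff(region_list, all_regions)
  if (length(unknown))
    stop("unknown region/module name(s) in config: ",
         paste(unknown, collapse = ", "))
  mcmc_defaults <- list(iterations = 200000L, burnin = NULL, thin = 100L,
                        chains = 2L, replicates = 3L)
  mcmc <- utils::modifyList(mcmc_defaults, mcmc)
  structure(list(tree = tree, data = data, region_list = region_list,
                 alignment = alignment, mcmc = mcmc, scaling = scaling,
                 var_cutoff = var_cutoff, subsample = subsample,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "run_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file with keys matching [run_config] arguments (file
#'   paths for `tree`, `data`, `regions`, `modules`, `groups`, `tip_ages`).
#' @return A `run_config`.
#' @export
read_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- y[intersect(names(y), names(formals(run_config)))]
  do.call(run_config, args)
}

.log_stage <- function(journal, stage, region, msg) {
  line <- sprintf("[%s] stage=%s region=%s %s",
                  format(Sys.time(), "%H:%M:%S"), stage, region, msg)
  if (!is.null(journal)) cat(line, "\n", file = journal, append = TRUE)
  invisible(line)
}

#' Run the full comparative pipeline
#'
#' For each region in the configuration: Procrustes alignment (local per
#' region, or one global fit), phylogenetic PCA retaining the axes that
#' reach the variance cutoff, replicate variable-rates MCMC runs with a
#' convergence check and run selection, time-corrected per-group mean rate
#' scalars and rank-sum comparisons, per-group sigma-mult rates with
#' simulation significance, and Procrustes-variance disparity with
#' permutation tests. Tree-level sampling diagnostics (branch-length t test,
#' log-rate-vs-branch-length regression) are computed once. Any stage
#' failure aborts with the stage and region named.
#'
#' @param config A [run_config].
#' @param nsim Simulations for the sigma-mult test.
#' @param nperm Permutations for the disparity test.
#' @return Object of class `pipeline_result`: per-region results
#'   (`alignment` summary, `pca`, `trace`, `rates`, `rate_tests`,
#'   `sigma`, `disparity`), `diagnostics`, optional `subsample`, `manifest`.
#' @export
run_pipeline <- function(config, nsim = 199L, nperm = 199L) {
  stopifnot(inherits(config, "run_config"))
  tree <- config$tree; data <- config$data
  journal <- NULL
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    journal <- file.path(config$out_dir, "run_journal.log")
    cat("", file = journal)
  }
  regions <- config$region_list
  global_aln <- NULL
  if (config$alignment == "global")
    global_aln <- .stage("align", "global", gpa(data, scope = regions))

  results <- list()
  diag_trace <- NULL; diag_tree <- NULL
  for (rg in regions) {
    .log_stage(journal, "align", rg, "start")
    aln <- if (config$alignment == "global") {
      sub <- .subset_alignment(global_aln, data, rg)
      sub
    } else .stage("align", rg, gpa(data, scope = rg))
    keep <- aln$specimens
    tr <- .stage("prune", rg, keep_taxa(tree, keep))
    Y <- two_d_array(aln$coords)[tr$phy$tip.label, , drop = FALSE]
    grp <- tr$groups[rownames(Y)]

    .log_stage(journal, "pca", rg, "start")
    pca <- .stage("pca", rg,
                  phylo_pca(Y, phylo_cov(tr), config$var_cutoff))

    .log_stage(journal, "mcmc", rg,
               sprintf("%d replicates x %d iterations",
                       config$mcmc$replicates, config$mcmc$iterations))
    reps <- lapply(seq_len(config$mcmc$replicates), function(r)
      .stage("mcmc", rg, rj_mcmc(pca, tr,
                                 iterations = config$mcmc$iterations,
                                 burnin = config$mcmc$burnin,
                                 thin = config$mcmc$thin,
                                 seed = config$seed + 1000L * r +
                                   match(rg, regions))))
    sel <- .stage("select_run", rg, select_run(reps))
    trace <- sel$trace
    if (is.null(diag_trace)) { diag_trace <- trace; diag_tree <- tr }

    rates <- .stage("rates", rg,
                    clade_mean_scalars(trace, tr, scaling = config$scaling))
    tests <- .stage("rate_tests", rg, compare_groups(rates))
    sig <- .stage("sigma", rg,
                  sigma_mult_test(Y, phylo_cov(tr), partition = grp,
                                  by = "taxa", nsim = nsim,
                                  seed = config$seed + match(rg, regions)))
    disp <- .stage("disparity", rg,
                   disparity_permutation_test(aln$coords, grp, nperm = nperm,
                                              seed = config$seed +
                                                match(rg, regions)))
    results[[rg]] <- list(alignment = list(n = length(keep),
                                           iterations = aln$iterations),
                          pca = pca, trace = trace, psrf = sel$psrf,
                          rates = rates, rate_tests = tests,
                          sigma = sig, disparity = disp)
    .log_stage(journal, "done", rg, sprintf("n=%d q=%d", length(keep), pca$q))
  }

  diagnostics <- .stage("diagnostics", "tree", list(
    branch_lengths = branch_length_ttest(
      diag_tree, utils::head(setdiff(unique(diag_tree$groups), NA), 2)),
    rate_regression = rate_branchlength_regression(diag_trace, diag_tree)))

  subs <- NULL
  if (!is.null(config$subsample))
    subs <- .stage("subsample", "all", subsample_protocol(
      data, tree, config$subsample$orders,
      iterations = config$subsample$iterations %||% 100L,
      seed = config$seed))

  manifest <- list(
    package_version = as.character(utils::packageVersion("morphorates")),
    seed = config$seed, regions = regions, alignment = config$alignment,
    mcmc = config$mcmc[c("iterations", "thin", "replicates")],
    scaling = config$scaling, var_cutoff = config$var_cutoff,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))

  out <- structure(list(regions = results, diagnostics = diagnostics,
                        subsample = subs, manifest = manifest),
                   class = "pipeline_result")
  if (!is.null(config$out_dir)) .write_pipeline(out, config$out_dir)
  out
}

.stage <- function(stage, region, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("pipeline failed at stage '%s' (region '%s'): %s",
                 stage, region, conditionMessage(e)), call. = FALSE))
}

# restrict a global alignment to one region's landmarks
.subset_alignment <- function(global_aln, data, region) {
  lm_in_region <- which(data$regions[global_aln$landmarks] == region)
  out <- global_aln
  out$coords <- global_aln$coords[lm_in_region, , , drop = FALSE]
  out$consensus <- global_aln$consensus[lm_in_region, , drop = FALSE]
  out$landmarks <- global_aln$landmarks[lm_in_region]
  out$scope <- region
  out
}

.write_pipeline <- function(res, dir) {
  for (rg in names(res$regions)) {
    r <- res$regions[[rg]]
    pref <- file.path(dir, gsub("[^A-Za-z0-9_]", "_", rg))
    rates_df <- data.frame(group = rep(colnames(r$rates),
                                       each = nrow(r$rates)),
                           sample_index = rep(seq_len(nrow(r$rates)),
                                              ncol(r$rates)),
                           value = as.vector(r$rates))
    write.csv(rates_df, paste0(pref, "_rates.csv"), row.names = FALSE)
    write.csv(r$rate_tests, paste0(pref, "_rate_tests.csv"),
              row.names = FALSE)
    write.csv(data.frame(group = names(r$sigma$rates),
                         sigma_mult = unname(r$sigma$rates),
                         ratio_p = r$sigma$p_value),
              paste0(pref, "_sigma.csv"), row.names = FALSE)
    write.csv(r$disparity, paste0(pref, "_disparity.csv"), row.names = FALSE)
  }
  dg <- res$diagnostics
  write.csv(data.frame(t = dg$branch_lengths$t, df = dg$branch_lengths$df,
                       p = dg$branch_lengths$p_value,
                       slope = dg$rate_regression$slope,
                       r_squared = dg$rate_regression$r_squared,
                       slope_p = dg$rate_regression$p_value),
            file.path(dir, "diagnostics.csv"), row.names = FALSE)
  jsonlite::write_json(res$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("pipeline_result:", length(x$regions), "regions analysed\n")
  for (rg in names(x$regions)) {
    r <- x$regions[[rg]]
    cat(sprintf("  %s: n=%d, q=%d, median group rates: %s\n", rg,
                r$alignment$n, r$pca$q,
                paste(sprintf("%s=%.3g", colnames(r$rates),
                              apply(r$rates, 2, median)), collapse = ", ")))
  }
  invisible(x)
}
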