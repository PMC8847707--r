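# pipeline driver: chain the stages on in-memory tables with one seed
# and a provenance record, so a full run is reproducible end to end.

#' Run the niche-modelling pipeline
#'
#' Chains the analysis stages on already-loaded tables: gradient
#' rescaling and collinearity screen, HOF niche-optimum estimation,
#' correlation-network grouping and PCA, and (when a tree is supplied)
#' the phylogenetic-signal profile.  Each stage can be switched off;
#' downstream stages that need a disabled stage's output error
#' informatively.
#'
#' @param env site-by-variable table of raw gradient values.
#' @param abundance wide taxon-by-site table of (fractional) counts.
#' @param tree optional ultrametric `phylo` over the retained taxa for
#'   the signal stage.
#' @param stages character vector of stages to run, a subset of
#'   `c("environment", "hof", "network", "ordination", "signal")`.
#' @param min_sites prevalence filter threshold.
#' @param n_bootstrap bootstrap resamples per HOF selection.
#' @param rho_cutoff Spearman cutoff of the network stage.
#' @param n_perm permutations of the signal stage.
#' @param seed integer seed governing every stochastic stage.
#' @return list with the per-stage results and a `provenance` record
#'   (package version, parameters, seed, configuration hash).
#' @export
run_niche_pipeline <- function(env, abundance, tree = NULL,
                               stages = c("environment", "hof", "network",
                                          "ordination", "signal"),
                               min_sites = 25, n_bootstrap = 50,
                               rho_cutoff = 0.85, n_perm = 99, seed = 1L) {
  stages <- match.arg(stages, several.ok = TRUE)
  out <- list()

  if ("environment" %in% stages) {
    out$env_rescaled <- rescale_env(env)
    out$collinearity <- glance(correlation_screen(env))
  }

  if ("hof" %in% stages) {
    if (is.null(out$env_rescaled)) {
      abort("the hof stage needs the environment stage")
    }
    filtered <- prevalence_filter(abundance, min_sites)
    out$optima <- optimum_matrix(filtered, out$env_rescaled,
                                 totals = colSums(table_to_matrix(abundance)),
                                 min_sites = min_sites,
                                 n_bootstrap = n_bootstrap, seed = seed)
    out$optima_wide <- pivot_optima(out$optima)
  }

  if ("network" %in% stages) {
    if (is.null(out$optima_wide)) abort("the network stage needs hof optima")
    net <- suppressWarnings(spearman_network(out$optima_wide, rho_cutoff))
    out$groups <- detect_groups(net, seed = seed)
    out$network <- net
  }

  if ("ordination" %in% stages) {
    if (is.null(out$optima_wide)) abort("the ordination stage needs hof optima")
    out$pca <- pca_ordination(out$optima_wide)
  }

  if ("signal" %in% stages) {
    if (is.null(tree)) abort("the signal stage needs a tree")
    if (is.null(out$optima_wide)) abort("the signal stage needs hof optima")
    keep <- intersect(tree$tip.label, out$optima_wide$otu)
    if (length(keep) < 4) abort("fewer than 4 taxa shared with the tree")
    tr <- ape::keep.tip(tree, keep)
    out$signal <- phylo_signal_profile(
      tr, out$optima_wide[out$optima_wide$otu %in% keep, ],
      n_perm = n_perm, seed = seed)
  }

  cfg <- list(stages = stages, min_sites = min_sites,
              n_bootstrap = n_bootstrap, rho_cutoff = rho_cutoff,
              n_perm = n_perm, seed = seed)
  out$provenance <- list(
    package = "nicheoptima",
    version = as.character(utils::packageVersion("nicheoptima")),
    timestamp = format(Sys.time(), tz = "UTC"),
    config = cfg,
    config_hash = rlang::hash(cfg))
  out
}
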