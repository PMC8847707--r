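# synthetic-data module: every input of the pipeline can be generated with
# known ground truth, so downstream stages are testable without field data.

#' Reference ranges for 41 grassland environmental variables
#'
#' Observed minimum/maximum of the 41 gradients measured across the 150
#' grassland plots (soil physicochemistry, microbial biomass, plant and
#' soil-fauna descriptors, land-use intensity).  Used as the default
#' variable specification of [sim_env()].
#'
#' @return tibble with columns `variable`, `min`, `max`, `unit`.
#' @export
grassland_env_ranges <- function() {
  tibble::tribble(
    ~variable,            ~min,  ~max,   ~unit,
    "BM_grassland",          3,   436,   "g m-2",
    "LUI",                 0.6,   3.4,   "index",
    "pH",                  4.6,   7.5,   "pH in CaCl2",
    "C_i",                   0,  78.5,   "g kg-1 soil",
    "C_o",                12.2, 359.5,   "g kg-1 soil",
    "CN_ratio",              9,  14.6,   "ratio",
    "BM_roots_F",          0.1,  53.4,   "g cm-3",
    "BM_roots_C",            0,   6.8,   "g cm-3",
    "PL_N",                1.2,   3.6,   "%",
    "PL_C",               42.7,  46.1,   "%",
    "PL_P",                0.1,   0.4,   "%",
    "PL_K",                0.6,   3.8,   "%",
    "PL_Ca",               0.2,   1.4,   "%",
    "PL_Mg",               0.1,   0.5,   "%",
    "Sand",                0.8,  84.6,   "g kg-1 soil",
    "Silt",                7.2,  86.8,   "g kg-1 soil",
    "Clay",                4.1,  70.8,   "g kg-1 soil",
    "NH4",                 2.3,  51.7,   "ug N g-1",
    "NO3",                   0,  68.8,   "ug N g-1",
    "N_min",               4.4, 112.3,   "ug N g-1",
    "Roots_CN",           17.8,  98.1,   "ratio",
    "Roots_C",            28.8,  48.5,   "%",
    "Roots_N",             0.5,   2.4,   "%",
    "Paur",                  0, 16270,   "ind m-2",
    "Lumb",                  0,  1019,   "ind m-2",
    "Dipl",                  0,   207,   "ind m-2",
    "Soil_H2O",            3.2, 208.5,   "%",
    "C_mic",               116,  1521,   "ug C g-1 soil",
    "P_mic",               3.5,  81.9,   "mg kg-1",
    "Cmic_Nmic",           4.8,  10.4,   "ratio",
    "Shannon",             0.9,   3.2,   "index",
    "Evenness",            0.4,   0.9,   "index",
    "COV_legumes",           0,  60.5,   "%",
    "COV_vasc_pl",        36.5, 244.7,   "%",
    "NR_vasc_pl",           12,    64,   "count",
    "COV_bryoph",            0,    90,   "%",
    "COV_litter",            0,    97,   "%",
    "COV_bare_soil",         0,    40,   "%",
    "NR_legumes",            0,    11,   "count",
    "BM_roots_total",      0.1,  57.1,   "g cm-3",
    "N_mic",                15,   231,   "ug N g-1 soil")
}

#' Simulate a site-by-variable environment table
#'
#' Draws each variable independently and uniformly over its declared
#' range.  Uniform sampling maximises gradient coverage, which is what
#' the response-model tests need; real soils are of course correlated.
#'
#' @param n_sites number of sites (rows).
#' @param ranges variable specification, a data frame with columns
#'   `variable`, `min`, `max`; defaults to [grassland_env_ranges()].
#' @param seed optional integer seed.
#' @return tibble with a `site` id column and one raw-scale column per
#'   variable.
#' @export
sim_env <- function(n_sites, ranges = grassland_env_ranges(), seed = NULL) {
  if (!is_count(n_sites)) abort("n_sites must be a positive integer")
  stopifnot(all(c("variable", "min", "max") %in% names(ranges)))
  if (any(ranges$min >= ranges$max)) abort("each variable needs min < max")
  with_seed_if(seed, {
    cols <- purrr::pmap(ranges[c("variable", "min", "max")],
                        function(variable, min, max) runif(n_sites, min, max))
    names(cols) <- ranges$variable
    dplyr::bind_cols(tibble(site = sprintf("S%03d", seq_len(n_sites))),
                     as_tibble(cols))
  })
}

#' Simulate per-taxon HOF ground truth along one gradient
#'
#' Assigns each taxon a response model and shape coefficients, recording
#' the true niche optimum on the `[1, 100]` scale.  Model IV optima are
#' placed uniformly in `optimum_range`; widths are controlled by the
#' slope coefficient drawn from `slope_range` (larger = narrower).
#' Model V curves are skewed by deforming a model IV draw; their true
#' optimum is located numerically on a fine grid.
#'
#' @param n_otus number of taxa.
#' @param models model type per taxon, recycled (any of `"I"`, `"II"`,
#'   `"IV"`, `"V"`).
#' @param optimum_range range of true optima for unimodal taxa.
#' @param slope_range range of the logistic slope coefficient.
#' @param peak peak expected proportion of a unimodal curve (before
#'   per-site renormalisation by [sim_reads()]).
#' @param flat_level expected proportion of flat (model I) taxa.
#' @param seed optional integer seed.
#' @return tibble with `otu`, `model`, coefficients `a`, `b`, `c`, `d`
#'   and the true `optimum` (`NA` for model I).
#' @export
sim_hof_truth <- function(n_otus, models = "IV", optimum_range = c(10, 90),
                          slope_range = c(20, 80), peak = 0.02,
                          flat_level = 0.005, seed = NULL) {
  if (!is_count(n_otus)) abort("n_otus must be a positive integer")
  models <- rep_len(models, n_otus)
  if (!all(models %in% c("I", "II", "IV", "V"))) {
    abort("truth models must be I, II, IV or V")
  }
  with_seed_if(seed, {
    h <- qlogis(1 - sqrt(peak))
    rows <- purrr::map(seq_len(n_otus), function(i) {
      m <- models[[i]]
      if (m == "I") {
        return(tibble(model = m, a = qlogis(1 - flat_level), b = NA_real_,
                      c = NA_real_, d = NA_real_, optimum = NA_real_))
      }
      if (m == "II") {
        b <- runif(1, slope_range[1], slope_range[2]) * sample(c(-1, 1), 1)
        a <- qlogis(1 - peak) - b * (if (b > 0) 0 else 1)
        return(tibble(model = m, a = a, b = b, c = NA_real_, d = NA_real_,
                      optimum = if (b > 0) 1 else 100))
      }
      u <- runif(1, optimum_range[1], optimum_range[2])
      x0 <- (u - 50.5) / 99
      b <- runif(1, slope_range[1], slope_range[2])
      if (m == "IV") {
        return(tibble(model = m, a = h - b * x0, b = b, c = h + b * x0,
                      d = NA_real_, optimum = u))
      }
      # model V: break the symmetry of the second logistic term
      d <- -b * runif(1, 0.4, 0.8)
      par <- c(h - b * x0, b, h + (-d) * x0, d)
      g <- seq(1, 100, by = 1e-3)
      u_true <- g[which.max(hof_response("V", par, g))]
      tibble(model = m, a = par[1], b = par[2], c = par[3], d = par[4],
             optimum = u_true)
    })
    dplyr::bind_cols(tibble(otu = sprintf("OTU%04d", seq_len(n_otus))),
                     dplyr::bind_rows(rows))
  })
}

#' Expected relative-abundance matrix from HOF ground truth
#'
#' Evaluates each taxon's true response curve at the sites' gradient
#' positions.  The driving variable is rescaled to `[1, 100]` from its
#' observed range before evaluation.
#'
#' @param env environment table from [sim_env()] (raw values).
#' @param truth ground-truth table from [sim_hof_truth()].
#' @param variable name of the driving environmental variable.
#' @return numeric matrix, sites x taxa, of expected proportions.
#' @export
sim_expected_abundance <- function(env, truth, variable = "pH") {
  x <- rescale_gradient(env[[variable]])
  m <- vapply(seq_len(nrow(truth)), function(i) {
    par <- as.numeric(truth[i, c("a", "b", "c", "d")])
    par <- par[seq_len(hof_n_par[[truth$model[i]]])]
    .hof_p_internal(truth$model[i], par, .to_internal(x))
  }, numeric(nrow(env)))
  dimnames(m) <- list(as.character(env[[1]]), truth$otu)
  m
}

#' Sample sequencing read counts from expected abundances
#'
#' Per site, the expected proportions are renormalised and `depth` reads
#' are drawn multinomially; optional Dirichlet-multinomial overdispersion
#' perturbs the proportions with concentration `overdispersion` (smaller
#' = noisier).
#'
#' @param expected sites x taxa matrix of non-negative expectations
#'   (e.g. from [sim_expected_abundance()]).
#' @param depth reads per site.
#' @param overdispersion optional Dirichlet concentration parameter.
#' @param seed optional integer seed.
#' @return wide abundance tibble: first column `otu`, one column per site.
#' @export
sim_reads <- function(expected, depth = 1e4, overdispersion = NULL,
                      seed = NULL) {
  if (!is_count(depth)) abort("depth must be a positive integer")
  if (any(expected < 0)) abort("expected abundances must be non-negative")
  with_seed_if(seed, {
    counts <- apply(expected, 1, function(p) {
      if (sum(p) <= 0) abort("a site has all-zero expectation")
      p <- p / sum(p)
      if (!is.null(overdispersion)) {
        g <- rgamma(length(p), shape = overdispersion * p, rate = 1)
        p <- if (sum(g) > 0) g / sum(g) else p
      }
      rmultinom(1, depth, p)[, 1]
    })
    # apply() returns taxa x sites
    rownames(counts) <- colnames(expected)
    colnames(counts) <- rownames(expected)
    matrix_to_table(counts, "otu")
  })
}

#' Simulate an ultrametric phylogeny
#'
#' Constant-rate pure-birth tree rescaled to unit root-to-tip height.
#'
#' @param n_tips number of tips (>= 2).
#' @param birth_rate speciation rate of the birth process.
#' @param seed optional integer seed.
#' @return an `ape::phylo` object, ultrametric with height 1.
#' @export
sim_tree <- function(n_tips, birth_rate = 1, seed = NULL) {
  if (!is_count(n_tips) || n_tips < 2) abort("n_tips must be >= 2")
  with_seed_if(seed, {
    tr <- ape::rphylo(n_tips, birth = birth_rate, death = 0)
    depth <- max(ape::node.depth.edgelength(tr))
    tr$edge.length <- tr$edge.length / depth
    tr
  })
}

#' Simulate tip traits on a phylogeny
#'
#' Brownian motion (variance `sigma^2` per unit branch length),
#' Ornstein-Uhlenbeck (strength `alpha` pulling towards `root`), or white
#' noise that ignores the tree entirely.
#'
#' @param tree ultrametric `phylo`.
#' @param process `"BM"`, `"OU"` or `"white"`.
#' @param sigma diffusion (BM/OU) or standard deviation (white noise).
#' @param alpha OU restoring strength.
#' @param root root state.
#' @param seed optional integer seed.
#' @return named numeric vector of tip values.
#' @export
sim_trait <- function(tree, process = c("BM", "OU", "white"), sigma = 1,
                      alpha = 1, root = 0, seed = NULL) {
  process <- match.arg(process)
  with_seed_if(seed, {
    if (process == "white") {
      return(setNames(rnorm(length(tree$tip.label), root, sigma),
                      tree$tip.label))
    }
    if (process == "BM") {
      if (sigma == 0) {
        return(setNames(rep(root, length(tree$tip.label)), tree$tip.label))
      }
      return(ape::rTraitCont(tree, model = "BM", sigma = sigma,
                             ancestor = FALSE, root.value = root))
    }
    ape::rTraitCont(tree, model = "OU", sigma = sigma, alpha = alpha,
                    theta = root, ancestor = FALSE, root.value = root)
  })
}

#' Plant taxon optima with ecological group structure
#'
#' Each group gets a centre vector of optima drawn uniformly on
#' `[1, 100]`; members scatter around it with Gaussian noise.  The
#' resulting table is the fixture for the correlation-network stage, in
#' which groups of taxa with similar optimum vectors should be
#' recoverable.
#'
#' @param n_otus total number of taxa, split as evenly as possible.
#' @param n_groups number of planted groups.
#' @param n_variables number of environmental variables.
#' @param noise_sd within-group standard deviation (scaled units).
#' @param seed optional integer seed.
#' @return list with `optima` (wide tibble, first column `otu`) and
#'   `groups` (tibble `otu`, `group`).
#' @export
sim_optima_groups <- function(n_otus = 200, n_groups = 4, n_variables = 41,
                              noise_sd = 3, seed = NULL) {
  if (n_groups > n_otus) abort("more groups than taxa")
  with_seed_if(seed, {
    grp <- rep_len(seq_len(n_groups), n_otus)
    centres <- matrix(runif(n_groups * n_variables, 1, 100),
                      nrow = n_groups)
    vals <- centres[grp, , drop = FALSE] +
      matrix(rnorm(n_otus * n_variables, 0, noise_sd), nrow = n_otus)
    vals <- pmin(pmax(vals, 1), 100)
    dimnames(vals) <- list(sprintf("OTU%04d", seq_len(n_otus)),
                           sprintf("V%02d", seq_len(n_variables)))
    list(optima = matrix_to_table(vals, "otu"),
         groups = tibble(otu = rownames(vals),
                         group = sprintf("G%d", grp)))
  })
}

#' Plant coupled trait matrices with group structure and missingness
#'
#' Two species-by-trait matrices coded 1/2/3 share the same planted group
#' labels: within a group species tend to carry the group's trait
#' profile, across matrices the *labels* coincide while the profiles are
#' drawn independently.  Ordinations of the two matrices are therefore
#' concordant exactly through the group structure.  Entries are deleted
#' completely at random with probability `missing_fraction`.
#'
#' @param n_species number of species.
#' @param n_traits traits per matrix.
#' @param n_groups planted groups.
#' @param noise probability an entry deviates from its group profile.
#' @param missing_fraction fraction of entries set to `NA`, in `[0, 1)`.
#' @param seed optional integer seed.
#' @return list with tibbles `a` and `b` (first column `species`) and
#'   `groups`.
#' @export
sim_trait_matrices <- function(n_species = 30, n_traits = 20, n_groups = 3,
                               noise = 0.1, missing_fraction = 0.1,
                               seed = NULL) {
  if (missing_fraction < 0 || missing_fraction >= 1) {
    abort("missing_fraction must be in [0, 1)")
  }
  if (n_groups > n_species) abort("more groups than species")
  with_seed_if(seed, {
    grp <- rep_len(seq_len(n_groups), n_species)
    one <- function() {
      profile <- matrix(sample(1:3, n_groups * n_traits, replace = TRUE),
                        nrow = n_groups)
      m <- profile[grp, , drop = FALSE]
      flip <- matrix(runif(length(m)) < noise, nrow = n_species)
      m[flip] <- sample(1:3, sum(flip), replace = TRUE)
      if (missing_fraction > 0) {
        m[matrix(runif(length(m)) < missing_fraction,
                 nrow = n_species)] <- NA
      }
      dimnames(m) <- list(sprintf("sp%02d", seq_len(n_species)),
                          sprintf("T%02d", seq_len(n_traits)))
      matrix_to_table(m, "species")
    }
    list(a = one(), b = one(),
         groups = tibble(species = sprintf("sp%02d", seq_len(n_species)),
                         group = sprintf("G%d", grp)))
  })
}

#' Simulate terminal-clade pair data for the divergence regression
#'
#' Ecological divergence is generated as a linear function of 16S
#' dissimilarity (in percent) with subdivision-specific intercepts, a
#' common slope and Gaussian residuals.
#'
#' @param n_per_group pairs per subdivision.
#' @param intercepts named or unnamed vector of per-subdivision
#'   intercepts (ecological divergence at zero dissimilarity).
#' @param slope increase in ecological divergence per percent 16S
#'   dissimilarity; set `slope` to a vector for subdivision-specific
#'   slopes (an interaction).
#' @param dissim_range range of simulated dissimilarities, percent.
#' @param sigma residual standard deviation.
#' @param seed optional integer seed.
#' @return tibble with `pair`, `subdivision`, `dissimilarity` (percent)
#'   and `divergence`.
#' @export
sim_divergence_pairs <- function(n_per_group = 30,
                                 intercepts = c(SD1 = 76, SD3 = 150,
                                                SD4 = 149, SD6 = 236),
                                 slope = 22.6, dissim_range = c(0, 5),
                                 sigma = 60, seed = NULL) {
  groups <- names(intercepts) %||% paste0("SD", seq_along(intercepts))
  slopes <- rep_len(slope, length(intercepts))
  with_seed_if(seed, {
    purrr::map_dfr(seq_along(intercepts), function(g) {
      d <- runif(n_per_group, dissim_range[1], dissim_range[2])
      tibble(subdivision = groups[[g]], dissimilarity = d,
             divergence = intercepts[[g]] + slopes[[g]] * d +
               rnorm(n_per_group, 0, sigma))
    }) |>
      dplyr::mutate(pair = sprintf("P%03d", dplyr::row_number()),
                    .before = 1)
  })
}
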