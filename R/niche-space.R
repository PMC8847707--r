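# niche-space module: ecological distances, Spearman correlation networks,
# community detection, rho sweep, PCA ordination of the optimum matrix.

#' Euclidean ecological distance between two optimum vectors
#'
#' @param x1,x2 equal-length complete numeric vectors of niche optima.
#' @return non-negative scalar.  The theoretical maximum across 41
#'   variables on the 1-100 scale is `99 * sqrt(41)` (about 634).
#' @examples
#' ecological_distance(rep(1, 41), rep(100, 41))
#' @export
ecological_distance <- function(x1, x2) {
  if (length(x1) != length(x2)) abort("vectors differ in length")
  if (anyNA(x1) || anyNA(x2)) {
    abort("missing optima: restrict to shared complete variables first")
  }
  sqrt(sum((x1 - x2)^2))
}

#' Spearman correlation network over taxa
#'
#' Ranks each taxon's optimum vector and connects pairs whose Spearman
#' rho (pairwise-complete variables) reaches the cutoff.  Taxa with
#' fewer than 3 non-missing optima are excluded with a warning.
#'
#' @param optima wide optimum table: first column the taxon id, remaining
#'   columns per-variable optima (missing allowed).
#' @param rho_cutoff minimum Spearman rho for an edge.
#' @return object of class `eco_network`: the `igraph` graph (edge
#'   weights = rho) plus the edge tibble.
#' @export
spearman_network <- function(optima, rho_cutoff = 0.85) {
  if (nrow(optima) == 0) {
    return(structure(list(
      graph = igraph::make_empty_graph(0, directed = FALSE),
      edges = tibble(from = character(), to = character(), rho = numeric()),
      rho_cutoff = rho_cutoff), class = "eco_network"))
  }
  m <- table_to_matrix(optima, "optimum table")
  usable <- rowSums(is.finite(m)) >= 3
  if (any(!usable)) {
    warn(sprintf("excluding %d taxa with < 3 usable optima", sum(!usable)))
    m <- m[usable, , drop = FALSE]
  }
  r <- suppressWarnings(
    cor(t(m), method = "spearman", use = "pairwise.complete.obs"))
  r[!is.finite(r)] <- -Inf
  idx <- which(upper.tri(r) & r >= rho_cutoff, arr.ind = TRUE)
  edges <- tibble(from = rownames(m)[idx[, 1]],
                  to = rownames(m)[idx[, 2]],
                  rho = r[idx])
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = rownames(m))
  igraph::E(g)$weight <- edges$rho
  structure(list(graph = g, edges = edges, rho_cutoff = rho_cutoff),
            class = "eco_network")
}

#' @export
print.eco_network <- function(x, ...) {
  cat("ecological network:", igraph::vcount(x$graph), "taxa,",
      igraph::ecount(x$graph), "edges at rho >=", x$rho_cutoff, "\n")
  invisible(x)
}

#' Detect ecological groups by multi-level modularity optimisation
#'
#' Louvain community detection on the correlation network, deterministic
#' under `seed`.  Communities of a single taxon are not counted as
#' ecological groups and carry `NA` group labels.
#'
#' @param network an `eco_network` from [spearman_network()].
#' @param seed optional integer seed fixing the algorithm's randomness.
#' @return tibble `otu`, `group` (NA for singletons), with the achieved
#'   `modularity` and the number of (size >= 2) groups as attributes.
#' @export
detect_groups <- function(network, seed = NULL) {
  stopifnot(inherits(network, "eco_network"))
  g <- network$graph
  if (igraph::vcount(g) == 0) {
    out <- tibble(otu = character(), group = character())
    attr(out, "modularity") <- NA_real_
    attr(out, "n_groups") <- 0L
    return(out)
  }
  cl <- with_seed_if(seed, igraph::cluster_louvain(g))
  memb <- igraph::membership(cl)
  sizes <- table(memb)
  keep <- as.integer(names(sizes)[sizes >= 2])
  lab <- ifelse(memb %in% keep,
                sprintf("G%03d", match(memb, sort(keep))), NA_character_)
  out <- tibble(otu = names(memb), group = lab)
  attr(out, "modularity") <- igraph::modularity(cl)
  attr(out, "n_groups") <- length(keep)
  out
}

#' Sweep the correlation cutoff of the ecological network
#'
#' Rebuilds the network and re-detects groups across a grid of rho
#' cutoffs, tabulating how many groups (of size >= 2) exist and how many
#' taxa they absorb.  The default grid is the one explored for choosing
#' the 0.85 working cutoff.
#'
#' @inheritParams spearman_network
#' @param rho_grid cutoffs to evaluate, each in (0, 1).
#' @param seed optional integer seed for community detection.
#' @return tibble `rho`, `n_groups`, `n_otus_in_groups`, `fraction`.
#' @export
rho_sweep <- function(optima,
                      rho_grid = c(0.4, 0.5, 0.6, 0.7, 0.725, 0.75, 0.775,
                                   0.8, 0.825, 0.85, 0.875, 0.8875, 0.9,
                                   0.9125, 0.925, 0.9375, 0.95, 0.96,
                                   0.975, 0.98, 0.99),
                      seed = NULL) {
  if (any(rho_grid <= 0 | rho_grid >= 1)) abort("rho_grid must lie in (0, 1)")
  n_total <- nrow(optima)
  purrr::map_dfr(sort(rho_grid), function(rho) {
    net <- suppressWarnings(spearman_network(optima, rho))
    grp <- detect_groups(net, seed = seed)
    in_grp <- sum(!is.na(grp$group))
    tibble(rho = rho, n_groups = attr(grp, "n_groups"),
           n_otus_in_groups = in_grp, fraction = in_grp / n_total)
  })
}

#' PCA ordination of the optimum matrix
#'
#' Column-centred singular value decomposition.  Missing optima are
#' mean-imputed per variable first (the same rule the trait module
#' uses).
#'
#' @param optima wide optimum table (first column the taxon id).
#' @return object of class `pca_ordination` with `scores` (tibble),
#'   `explained` (variance fractions summing to 1) and the `prcomp` fit.
#' @export
pca_ordination <- function(optima) {
  m <- table_to_matrix(optima, "optimum table")
  if (nrow(m) < 2) abort("need at least two taxa")
  for (j in seq_len(ncol(m))) {
    miss <- !is.finite(m[, j])
    if (all(miss)) abort(sprintf("variable %s is entirely missing",
                                 colnames(m)[j]))
    m[miss, j] <- mean(m[, j], na.rm = TRUE)
  }
  fit <- prcomp(m, center = TRUE, scale. = FALSE)
  expl <- fit$sdev^2 / sum(fit$sdev^2)
  structure(list(scores = matrix_to_table(fit$x, "otu"),
                 explained = expl, prcomp = fit),
            class = "pca_ordination")
}

#' @export
print.pca_ordination <- function(x, ...) {
  cat("PCA ordination:", nrow(x$scores), "taxa;",
      "PC1-3 explain", paste0(round(100 * head(x$explained, 3), 1), "%",
                              collapse = ", "), "\n")
  invisible(x)
}

#' @describeIn pca_ordination scatter of the first two components,
#'   optionally coloured by a group table (`otu`, `group`).
#' @param object a `pca_ordination`.
#' @param groups optional tibble with `otu` and `group`.
#' @param ... unused.
#' @export
autoplot.pca_ordination <- function(object, groups = NULL, ...) {
  d <- object$scores
  if (!is.null(groups)) d <- dplyr::left_join(d, groups, by = "otu")
  aes <- if (is.null(groups)) {
    ggplot2::aes(x = .data$PC1, y = .data$PC2)
  } else {
    ggplot2::aes(x = .data$PC1, y = .data$PC2, colour = .data$group)
  }
  ggplot2::ggplot(d, aes) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::labs(
      x = sprintf("PC1 (%.1f%%)", 100 * object$explained[1]),
      y = sprintf("PC2 (%.1f%%)", 100 * object$explained[2])) +
    ggplot2::theme_minimal()
}

#' @describeIn rho_sweep plot groups and taxon coverage against rho.
#' @param data a tibble returned by [rho_sweep()].
#' @export
plot_rho_sweep <- function(data) {
  long <- tidyr::pivot_longer(data, c("n_groups", "fraction"),
                              names_to = "measure")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$rho, y = .data$value)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::facet_wrap(~measure, scales = "free_y") +
    ggplot2::theme_minimal()
}
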