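test_that("ecological distance is the Euclidean metric on optimum vectors", {
  expect_equal(ecological_distance(rep(1, 41), rep(100, 41)), 99 * sqrt(41))
  expect_equal(round(ecological_distance(rep(1, 41), rep(100, 41))), 634)
  expect_equal(ecological_distance(1:41, 1:41), 0)
  expect_equal(ecological_distance(rep(0, 41), rep(1, 41)), sqrt(41))

  # metric axioms on random complete vectors
  withr::with_seed(3, {
    for (i in 1:5) {
      a <- runif(10); b <- runif(10); c <- runif(10)
      expect_equal(ecological_distance(a, b), ecological_distance(b, a))
      expect_lte(ecological_distance(a, c),
                 ecological_distance(a, b) + ecological_distance(b, c) + 1e-12)
    }
  })
  expect_error(ecological_distance(c(1, NA), c(1, 2)), "missing")
  expect_error(ecological_distance(1:3, 1:4), "length")
})

test_that("the Spearman network links taxa with concordant optima", {
  g <- sim_optima_groups(40, n_groups = 2, n_variables = 20, noise_sd = 2,
                         seed = 5)
  net <- spearman_network(g$optima, rho_cutoff = 0.85)
  edges <- dplyr::left_join(net$edges, g$groups, by = c(from = "otu")) |>
    dplyr::left_join(g$groups, by = c(to = "otu"), suffix = c("_a", "_b"))
  expect_true(all(edges$group_a == edges$group_b))   # no between-group edges
  expect_gt(nrow(edges), 0)

  # identical vectors correlate perfectly; anti-correlated never link
  opt <- tibble::tibble(otu = c("a", "b", "c"),
                        V1 = c(1, 1, 20), V2 = c(5, 5, 15),
                        V3 = c(9, 9, 10), V4 = c(13, 13, 5))
  n2 <- spearman_network(opt, rho_cutoff = 0.99)
  expect_equal(nrow(n2$edges), 1)
  expect_equal(n2$edges$rho, 1)
  n3 <- spearman_network(opt, rho_cutoff = 0.5)
  expect_false(any(n3$edges$from == "a" & n3$edges$to == "c"))

  # too-sparse taxa are excluded with a warning
  sparse <- opt
  sparse[3, c("V1", "V2", "V3")] <- NA
  expect_warning(spearman_network(sparse, 0.5), "excluding")
})

test_that("community detection recovers planted and degenerate structures", {
  # two disconnected cliques
  edges <- dplyr::bind_rows(
    tidyr::expand_grid(from = paste0("a", 1:4), to = paste0("a", 1:4)),
    tidyr::expand_grid(from = paste0("b", 1:4), to = paste0("b", 1:4))) |>
    dplyr::filter(from < to) |>
    dplyr::mutate(rho = 0.9)
  g <- igraph::graph_from_data_frame(edges, directed = FALSE)
  igraph::E(g)$weight <- edges$rho
  net <- structure(list(graph = g, edges = edges, rho_cutoff = 0.85),
                   class = "eco_network")
  grp <- detect_groups(net, seed = 1)
  expect_equal(attr(grp, "n_groups"), 2)
  expect_equal(length(unique(grp$group[startsWith(grp$otu, "a")])), 1)

  # a single clique is one community with zero modularity
  e1 <- edges[edges$from < "b", ]
  g1 <- igraph::graph_from_data_frame(e1, directed = FALSE)
  igraph::E(g1)$weight <- e1$rho
  net1 <- structure(list(graph = g1, edges = e1, rho_cutoff = 0.85),
                    class = "eco_network")
  grp1 <- detect_groups(net1, seed = 1)
  expect_equal(attr(grp1, "n_groups"), 1)
  expect_equal(attr(grp1, "modularity"), 0)

  # empty network
  net0 <- spearman_network(tibble::tibble(otu = character(),
                                          V1 = numeric(), V2 = numeric(),
                                          V3 = numeric()), 0.9)
  grp0 <- detect_groups(net0)
  expect_equal(nrow(grp0), 0)
  expect_equal(attr(grp0, "n_groups"), 0)
})

test_that("the rho sweep tabulates groups over the cutoff grid", {
  g <- sim_optima_groups(60, n_groups = 4, n_variables = 30, noise_sd = 2,
                         seed = 8)
  sw <- rho_sweep(g$optima, rho_grid = c(0.3, 0.5, 0.7, 0.85, 0.95),
                  seed = 2)
  expect_equal(nrow(sw), 5)
  # the tight planted fixture keeps its 4 groups over a wide rho plateau
  expect_true(all(sw$n_groups[sw$rho %in% c(0.5, 0.7, 0.85)] == 4))

  # taxa carrying at least one edge can only drop as rho rises
  n_linked <- vapply(sw$rho, function(r) {
    net <- spearman_network(g$optima, r)
    sum(igraph::degree(net$graph) > 0)
  }, numeric(1))
  expect_true(all(diff(n_linked) <= 0))

  expect_error(rho_sweep(g$optima, rho_grid = c(0.5, 1)), "rho_grid")
})

test_that("PCA ordination matches its eigen-decomposition dual", {
  g <- sim_optima_groups(30, n_groups = 3, n_variables = 12, seed = 12)
  p <- pca_ordination(g$optima)
  expect_equal(sum(p$explained), 1)

  m <- as.matrix(g$optima[, -1])
  ev <- eigen(stats::cov(m), symmetric = TRUE)
  expect_equal(sort(p$prcomp$sdev^2), sort(ev$values), tolerance = 1e-8)

  # full-dimensional scores reproduce pairwise Euclidean distances
  expect_equal(as.matrix(dist(as.matrix(p$scores[, -1]))),
               unname(as.matrix(dist(m))), tolerance = 1e-8,
               ignore_attr = TRUE)

  # rank-1 data: one component carries everything
  r1 <- tibble::tibble(otu = paste0("o", 1:5), V1 = 1:5 * 2, V2 = 1:5 * 3)
  p1 <- pca_ordination(r1)
  expect_equal(p1$explained[1], 1)

  # missing entries are mean-imputed, not dropped
  gm <- g$optima
  gm[1, 2] <- NA
  expect_silent(pca_ordination(gm))
})
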