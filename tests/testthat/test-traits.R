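test_that("sparsity pruning removes poorly covered species and traits", {
  full <- sim_trait_matrices(n_species = 10, n_traits = 10,
                             missing_fraction = 0, seed = 1)$a
  expect_identical(sparsity_prune(full), full)

  # one species at 60% completeness, everything else complete
  m <- full
  m[3, 2:5] <- NA                      # 6 of 10 traits observed
  pruned <- sparsity_prune(m, row_min = 0.70, col_min = 0.50)
  expect_setequal(pruned$species, full$species[-3])
  expect_equal(ncol(pruned), ncol(full))

  # fixed point: pruning twice equals pruning once, thresholds hold
  again <- sparsity_prune(pruned)
  expect_identical(again, pruned)
  frac_row <- rowMeans(!is.na(as.matrix(pruned[, -1])))
  expect_true(all(frac_row >= 0.7))

  empty <- full
  empty[, -1] <- NA_real_
  expect_error(sparsity_prune(empty), "removed everything")
})

test_that("optimum imputation drops hopeless species and fills the rest", {
  g <- sim_optima_groups(10, n_groups = 2, n_variables = 41, seed = 2)
  opt <- g$optima
  opt[1, 2:3] <- NA        # two missing: retained and imputed
  opt[2, 2:6] <- NA        # five missing: dropped
  res <- impute_mean_optima(opt, max_missing = 2)
  expect_equal(res$dropped, opt$otu[2])
  expect_false(anyNA(res$optima))
  expect_equal(nrow(res$optima), 9)
  col_mean <- mean(opt[[2]][-c(1, 2)])
  expect_equal(res$optima[[2]][1], col_mean)

  # no missing values: identity
  res0 <- impute_mean_optima(g$optima)
  expect_identical(res0$optima, g$optima)
  expect_length(res0$dropped, 0)
})

test_that("Bray-Curtis omits pairwise-incomplete traits from both sums", {
  d <- tibble::tibble(species = c("x", "y", "z"),
                      t1 = c(1, 3, 1), t2 = c(1, 3, NA), t3 = c(1, 3, 2))
  bc <- as.matrix(bray_curtis(d))
  expect_equal(bc["x", "y"], 6 / 12)
  # z vs x uses only t1 and t3
  expect_equal(bc["x", "z"], (0 + 1) / (2 + 3))
  expect_equal(bc["x", "x"], 0)

  dup <- tibble::tibble(species = c("a", "b"), t1 = c(2, 2), t2 = c(3, 3))
  expect_equal(as.numeric(bray_curtis(dup)), 0)

  # agreement with the community-ecology reference implementation
  m <- sim_trait_matrices(n_species = 12, n_traits = 15,
                          missing_fraction = 0.1, seed = 5)$a
  ours <- as.matrix(bray_curtis(m))
  ref <- as.matrix(vegan::vegdist(as.matrix(m[, -1]), method = "bray",
                                  na.rm = TRUE))
  expect_equal(unname(ours), unname(ref), tolerance = 1e-12)

  disjoint <- tibble::tibble(species = c("p", "q"),
                             t1 = c(1, NA), t2 = c(NA, 2))
  expect_error(bray_curtis(disjoint), "no observed trait")
})

test_that("NMDS embeds low-dimensional configurations with near-zero stress", {
  pts <- withr::with_seed(3, matrix(rnorm(20 * 3), ncol = 3))
  rownames(pts) <- paste0("s", 1:20)
  d <- dist(pts)
  nm <- nmds_ordination(d, k = 3, n_starts = 10, seed = 4)
  expect_lt(nm$stress, 0.01)
  expect_equal(colnames(nm$scores)[-1], paste0("NMDS", 1:3))
  # scores are centred
  expect_equal(colMeans(as.matrix(nm$scores[, -1])), rep(0, 3),
               tolerance = 1e-8, ignore_attr = TRUE)

  # coincident points stay together
  pts2 <- rbind(pts, s21 = pts[1, ])
  nm2 <- nmds_ordination(dist(pts2), k = 2, n_starts = 10, seed = 5)
  sc <- as.matrix(nm2$scores[, -1])
  expect_lt(sqrt(sum((sc[1, ] - sc[21, ])^2)), 0.05 * max(dist(sc)))

  expect_error(nmds_ordination(d, k = 19), "smaller")
})

test_that("Procrustes protest recognises identical and rotated configurations", {
  sc <- withr::with_seed(6, matrix(rnorm(25 * 4), ncol = 4,
                                   dimnames = list(paste0("s", 1:25), NULL)))
  self <- procrustes_protest(sc, sc, n_perm = 199, n_repeat = 3, seed = 1)
  expect_equal(self$correlation, 1, tolerance = 1e-10)
  expect_equal(self$p_value, 1 / 200, tolerance = 1e-12)

  # rotation + uniform scaling + translation leaves the correlation at 1
  th <- 0.7
  rot <- diag(4); rot[1:2, 1:2] <- matrix(c(cos(th), sin(th),
                                            -sin(th), cos(th)), 2)
  sc2 <- sweep(3.2 * sc %*% rot, 2, c(1, -2, 0.5, 4), "+")
  rotated <- procrustes_protest(sc, sc2, n_perm = 199, n_repeat = 3, seed = 2)
  expect_equal(rotated$correlation, 1, tolerance = 1e-10)

  expect_error(procrustes_protest(sc, sc[1:10, ]), "different species")
})

test_that("concordance tables compare every pair of ordinations", {
  tm <- sim_trait_matrices(n_species = 20, n_traits = 25,
                           missing_fraction = 0, seed = 7)
  n1 <- nmds_ordination(bray_curtis(tm$a), k = 2, n_starts = 6, seed = 1)
  n2 <- nmds_ordination(bray_curtis(tm$b), k = 2, n_starts = 6, seed = 2)
  rnd <- withr::with_seed(8, matrix(rnorm(20 * 2), ncol = 2,
                                    dimnames = list(tm$a$species, NULL)))
  ct <- concordance_table(list(a = n1, b = n2, null = rnd),
                          n_perm = 199, n_repeat = 3, seed = 3)
  expect_equal(nrow(ct), 3)
  expect_true(all(ct$correlation >= 0 & ct$correlation <= 1))
  # the coupled matrices agree better than either does with noise
  ab <- ct$correlation[ct$a == "a" & ct$b == "b"]
  expect_gt(ab, max(ct$correlation[ct$b == "null"]))
})
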