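test_that("terminal pairs are the cherries under the dissimilarity ceiling", {
  tr <- balanced_4tip()
  d <- matrix(0.02, 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  diag(d) <- 0
  tp <- terminal_pairs(tr, d)
  expect_equal(nrow(tp), 2)
  expect_setequal(paste(tp$otu1, tp$otu2), c("A B", "C D"))
  expect_false(any(tp$polytomy))

  # a cherry above the ceiling is excluded
  d2 <- d
  d2["A", "B"] <- d2["B", "A"] <- 0.06
  expect_equal(nrow(terminal_pairs(tr, d2)), 1)

  # polytomies: every within-polytomy pair, flagged
  poly <- ape::read.tree(text = "((A:1,B:1,C:1):1,D:2);")
  dp <- matrix(0.01, 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  tpp <- terminal_pairs(poly, dp)
  expect_equal(nrow(tpp), 3)
  expect_true(all(tpp$polytomy))
})

test_that("pair enumeration matches brute force on random trees", {
  for (s in 1:3) {
    tr <- sim_tree(50, seed = s)
    n <- length(tr$tip.label)
    d <- matrix(0.01, n, n, dimnames = list(tr$tip.label, tr$tip.label))
    tp <- terminal_pairs(tr, d, max_dissim = 0.05)
    # oracle: enumerate internal nodes whose two children are both tips
    parents <- tr$edge[tr$edge[, 2] <= n, 1]
    expect_equal(nrow(tp), sum(table(parents) == 2))
  }
})

test_that("noise-free divergence data are recovered exactly", {
  pr <- sim_divergence_pairs(n_per_group = 10,
                             intercepts = c(SD1 = 80, SD3 = 150, SD6 = 240),
                             slope = 20, sigma = 0, seed = 2)
  fit <- fit_divergence_models(pr)
  expect_equal(glance(fit)$slope, 20, tolerance = 1e-9)
  ic <- subdivision_intercepts(fit)
  expect_equal(ic$intercept, c(80, 150, 240), tolerance = 1e-8)

  # nested models: the interaction fit can never do worse
  pr2 <- sim_divergence_pairs(seed = 3)
  f2 <- fit_divergence_models(pr2)
  expect_lte(sum(residuals(f2$interaction)^2),
             sum(residuals(f2$additive)^2) + 1e-8)

  # invariance to subdivision label encoding
  pr3 <- dplyr::mutate(pr2,
                       subdivision = factor(subdivision,
                                            levels = c("SD6", "SD3",
                                                       "SD4", "SD1")))
  f3 <- fit_divergence_models(pr3)
  expect_equal(f3$anova$f_statistic, f2$anova$f_statistic, tolerance = 1e-9)
  expect_equal(sort(subdivision_intercepts(f3)$intercept),
               sort(subdivision_intercepts(f2)$intercept), tolerance = 1e-9)

  expect_error(fit_divergence_models(pr[pr$subdivision == "SD1", ]),
               "two subdivisions")
})

test_that("model comparison detects slope heterogeneity when present", {
  hits <- vapply(1:40, function(s) {
    pr <- sim_divergence_pairs(n_per_group = 30,
                               intercepts = c(a = 100, b = 150, c = 120,
                                              d = 180),
                               slope = c(5, 20, 35, 50), sigma = 30,
                               seed = 500 + s)
    f <- fit_divergence_models(pr)
    f$aic$aic[2] < f$aic$aic[1]
  }, logical(1))
  expect_gt(mean(hits), 0.9)
})

test_that("group contrasts control the family of intercept comparisons", {
  pr <- sim_divergence_pairs(n_per_group = 25, seed = 6)
  fit <- fit_divergence_models(pr)
  gc <- group_contrasts(fit)
  expect_equal(nrow(gc), choose(4, 2))
  expect_true(all(gc$p_adj >= 0 & gc$p_adj <= 1))

  # a 10-SD separation flags every contrast
  big <- sim_divergence_pairs(n_per_group = 20,
                              intercepts = c(a = 0, b = 500, c = 1000),
                              sigma = 10, seed = 7)
  gb <- group_contrasts(fit_divergence_models(big))
  expect_true(all(gb$p_adj < 1e-4))

  # two groups: the adjusted p equals the plain two-sided t-test p
  two <- sim_divergence_pairs(n_per_group = 20,
                              intercepts = c(a = 100, b = 130),
                              sigma = 40, seed = 8)
  ft <- fit_divergence_models(two)
  g2 <- group_contrasts(ft)
  p_lm <- tidy(ft)$p_value[tidy(ft)$term == "subdivisionb"]
  expect_equal(g2$p_adj, p_lm, tolerance = 1e-6)
})

test_that("prediction bands follow ordinary-least-squares geometry", {
  pr <- sim_divergence_pairs(n_per_group = 30, seed = 9)
  fit <- fit_divergence_models(pr)

  # at a subdivision's mean dissimilarity the prediction is its fitted mean
  for (g in levels(fit$data$subdivision)) {
    sub <- fit$data[fit$data$subdivision == g, ]
    pred <- predict(fit$additive,
                    tibble::tibble(subdivision = factor(g, levels(fit$data$subdivision)),
                                   dissimilarity = mean(sub$dissimilarity)))
    expect_equal(unname(pred), mean(fitted(fit$additive)[fit$data$subdivision == g]),
                 tolerance = 1e-9)
  }

  bands <- predict_with_ci(fit, n_sim_per_group = 50, seed = 4)
  expect_equal(nrow(bands), 4 * 50)
  expect_true(all(bands$lwr <= bands$fit & bands$fit <= bands$upr))

  # confidence bands tighten with more data
  small <- fit_divergence_models(sim_divergence_pairs(n_per_group = 10,
                                                      seed = 11))
  large <- fit_divergence_models(sim_divergence_pairs(n_per_group = 100,
                                                      seed = 11))
  ws <- predict_with_ci(small, seed = 5)
  wl <- predict_with_ci(large, seed = 5)
  expect_lt(mean(wl$upr - wl$lwr), mean(ws$upr - ws$lwr))
})
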