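test_that("the flat model recovers a constant proportion exactly", {
  x <- grad_150()
  d <- tibble::tibble(x = x, y = round(0.004 * 5000), n = 5000)
  f <- fit_hof(d, x, y, n, model = "I")
  expect_equal(unname(hof_response("I", f$coef, 50)), 0.004, tolerance = 1e-9)
  expect_error(fit_hof(tibble::tibble(x = x, y = 0, n = 100), x, y, n, "I"),
               "zero")
})

test_that("likelihoods respect the model nesting hierarchy", {
  x <- grad_150()
  for (s in 1:3) {
    y <- sim_counts_from_curve("IV", iv_par(40), seed = s)
    d <- tibble::tibble(x = x, y = y, n = 1e4)
    ll <- vapply(c("I", "II", "III", "IV", "V"), function(m) {
      fit_hof(d, x, y, n, model = m)$log_lik
    }, numeric(1))
    expect_gte(ll[["II"]], ll[["I"]] - 1e-6)
    expect_gte(ll[["III"]], ll[["II"]] - 1e-6)
    expect_gte(ll[["IV"]], ll[["II"]] - 1e-6)
    expect_gte(ll[["V"]], ll[["IV"]] - 1e-6)
  }
})

test_that("model IV fits recover the generating curve closely", {
  x <- grad_150()
  par <- iv_par(62, b = 35)
  grid <- seq(1, 100, length.out = 1000)
  truth_curve <- hof_response("IV", par, grid)
  rmse <- vapply(1:20, function(s) {
    y <- sim_counts_from_curve("IV", par, seed = 100 + s)
    f <- fit_hof(tibble::tibble(x = x, y = y, n = 1e4), x, y, n, "IV")
    sqrt(mean((hof_response("IV", f$coef, grid) - truth_curve)^2))
  }, numeric(1))
  expect_lt(median(rmse), 0.005)
})

test_that("model selection is stable, seeded, and breaks ties to parsimony", {
  x <- grad_150()
  y <- sim_counts_from_curve("IV", iv_par(30, b = 50), seed = 7)
  d <- tibble::tibble(x = x, y = y, n = 1e4)
  s1 <- select_hof(d, x, y, n, seed = 5)
  s2 <- select_hof(d, x, y, n, seed = 5)
  expect_identical(s1$model, s2$model)
  expect_identical(s1$bootstrap_table, s2$bootstrap_table)
  expect_true(s1$model %in% c("IV", "V"))
  expect_gt(s1$bootstrap_support, 0.5)

  # AICc ties go to the simpler model (hierarchy order)
  tie <- c(I = 10, II = 10, III = 12, IV = 12, V = 30)
  expect_identical(nicheoptima:::.hof_pick(tie, tol = 0), "I")
  expect_identical(nicheoptima:::.hof_pick(c(II = 5, IV = 5), tol = 0), "II")
  # the parsimony band prefers a simpler model that is nearly as good
  expect_identical(nicheoptima:::.hof_pick(c(I = 11.5, II = 10), tol = 2), "I")
})

test_that("optimum extraction follows the per-model rules", {
  x <- grad_150()
  # flat: undefined
  yI <- sim_counts_from_curve("I", qlogis(1 - 0.005), seed = 1)
  fI <- fit_hof(tibble::tibble(x = x, y = yI, n = 1e4), x, y, n, "I")
  expect_true(is.na(extract_optimum(fI)$optimum))
  expect_error(niche_width(fI), "undefined")

  # symmetric: a = c puts the peak at the midpoint 50.5
  fIV <- structure(list(model = "IV", coef = c(a = 4, b = 30, c = 4),
                        bootstrap_support = NULL),
                   class = "hof_fit")
  res <- extract_optimum(fIV)
  expect_equal(res$optimum, 50.5)
  # ... with a symmetric inner niche interval
  expect_equal(res$optimum - res$niche_lo, res$niche_hi - res$optimum,
               tolerance = 1e-6)

  # monotone shapes: favoured gradient end by the sign of b
  fII <- structure(list(model = "II", coef = c(a = 0, b = -10),
                        bootstrap_support = NULL), class = "hof_fit")
  expect_equal(extract_optimum(fII)$optimum, 100)
  fII$coef["b"] <- 10
  expect_equal(extract_optimum(fII)$optimum, 1)

  # model V: numeric argmax agrees with a fine grid scan
  parV <- c(a = -10, b = 25, c = -2, d = -18)
  fV <- structure(list(model = "V", coef = parV, bootstrap_support = NULL),
                  class = "hof_fit")
  g <- seq(1, 100, by = 1e-3)
  grid_opt <- g[which.max(hof_response("V", parV, g))]
  expect_equal(extract_optimum(fV)$optimum, grid_opt, tolerance = 1e-2)

  # V: width bounds match a grid scan
  w <- niche_width(fV)
  pv <- hof_response("V", parV, g)
  thr <- exp(-0.5) * max(pv)
  expect_equal(w[1], min(g[pv >= thr]), tolerance = 1e-2)
  expect_equal(w[2], max(g[pv >= thr]), tolerance = 1e-2)
})

test_that("narrow niches are narrower than broad ones", {
  f_narrow <- structure(list(model = "IV", coef = c(a = -20, b = 60, c = 40),
                             bootstrap_support = NULL), class = "hof_fit")
  f_broad <- structure(list(model = "IV", coef = c(a = -5, b = 15, c = 10),
                            bootstrap_support = NULL), class = "hof_fit")
  wn <- niche_width(f_narrow)
  wb <- niche_width(f_broad)
  expect_lt(diff(wn), diff(wb))
})

test_that("optimum_matrix bookkeeping: one row per taxon and variable", {
  env <- sim_env(150, seed = 41)
  truth <- sim_hof_truth(6, models = c("IV", "I"), seed = 41)
  ex <- sim_expected_abundance(env, truth, "pH")
  ab <- sim_reads(ex, depth = 5e3, seed = 41)
  envr <- rescale_env(env[, c("site", "pH", "Sand")])

  om <- optimum_matrix(ab, envr, n_bootstrap = 10, min_sites = 25, seed = 3)
  expect_equal(nrow(om), 6 * 2)
  expect_true(all(is.na(om$optimum[om$model == "I"])))
  expect_true(all(!is.na(om$optimum[om$model %in% c("II", "III", "IV", "V")])))

  # site order must not matter (same seed stream)
  perm <- withr::with_seed(9, sample(150))
  ab_perm <- ab[, c(1, 1 + perm)]
  om_perm <- optimum_matrix(ab_perm, envr, n_bootstrap = 10,
                            min_sites = 25, seed = 3)
  expect_equal(om_perm$optimum, om$optimum, tolerance = 1e-6)

  wide <- pivot_optima(om)
  expect_equal(dim(wide), c(6, 3))
})
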