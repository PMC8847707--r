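#' Evaluate a HOF response curve
#'
#' Computes the expected proportional response of a Huisman-Olff-Fresco
#' model at gradient positions on the common `[1, 100]` scale.  The shape
#' coefficients are those of the internal `[0, 1]` parameterisation used
#' by [fit_hof()].
#'
#' @param model model type, one of `"I"`, `"II"`, `"III"`, `"IV"`, `"V"`.
#' @param par numeric vector of shape coefficients `a`, `b`, `c`, `d`
#'   (length 1, 2, 3, 3 or 4 depending on `model`).
#' @param x gradient positions on the `[1, 100]` scale.
#' @return numeric vector of expected proportions in `[0, 1]`.
#' @examples
#' x <- seq(1, 100, length.out = 5)
#' hof_response("IV", c(5, 30, 5), x)  # a = c: symmetric peak at x = 50.5
#' @export
hof_response <- function(model, par, x) {
  model <- match.arg(model, hof_model_types)
  if (length(par) != hof_n_par[[model]]) {
    abort(sprintf("model %s needs %d shape coefficients, got %d",
                  model, hof_n_par[[model]], length(par)))
  }
  .hof_p_internal(model, par, .to_internal(x))
}

#' Fit a single HOF model to binomial count data
#'
#' Maximises the binomial log-likelihood of per-site counts given per-site
#' read totals, with the expected proportion following the requested HOF
#' shape along the gradient.  Optimisation is bounded (L-BFGS-B) with
#' analytic gradients from a deterministic grid of starting values.
#'
#' @param data data frame with one row per site.
#' @param x,counts,totals bare column names: the rescaled gradient
#'   (`[1, 100]`), the per-site counts for the focal taxon, and the
#'   per-site read totals (binomial trials).
#' @param model HOF model type, `"I"` to `"V"`.
#' @return an object of class `hof_fit` with the fitted shape
#'   coefficients, log-likelihood and small-sample corrected AIC.
#' @seealso [select_hof()] for model selection, [extract_optimum()] for
#'   the niche optimum.
#' @export
fit_hof <- function(data, x, counts, totals, model = "IV") {
  model <- match.arg(model, hof_model_types)
  x <- dplyr::pull(data, {{ x }})
  y <- dplyr::pull(data, {{ counts }})
  n <- dplyr::pull(data, {{ totals }})
  new_hof_fit(x, y, n, model)
}

# shared constructor used by fit_hof() and select_hof()
new_hof_fit <- function(x, y, n, model, extra = list()) {
  keep <- is.finite(x) & is.finite(y) & is.finite(n)
  x <- x[keep]; y <- y[keep]; n <- n[keep]
  if (length(x) < 3) abort("need at least 3 sites with complete data")
  if (any(n <= 0)) abort("read totals must be positive")
  if (all(y == 0)) abort("all counts are zero: no signal to model")
  xi <- .to_internal(x)
  f <- .hof_fit_engine(model, xi, y, n)
  if (!f$converged) abort(sprintf("model %s failed to converge", model))
  par <- setNames(f$par, c("a", "b", "c", "d")[seq_along(f$par)])
  structure(
    c(list(model = model, coef = par, log_lik = f$log_lik,
           aicc = .aicc(f$log_lik, hof_n_par[[model]], length(x)),
           n_sites = length(x), data = tibble(x = x, counts = y, totals = n)),
      extra),
    class = "hof_fit")
}

#' Select the best-supported HOF model with bootstrap stabilisation
#'
#' All five model types are fitted to the full data and ranked by
#' small-sample corrected AIC; the simplest model within `aicc_tol` units
#' of the best is taken (models that close in AICc are treated as equally
#' well supported, and parsimony decides).  The choice is then stabilised
#' by refitting on `n_bootstrap` site-resamples: if the modal bootstrap
#' choice differs from the full-data choice, the modal choice wins.
#' Bootstrap ties are resolved by lower full-data AICc, then by fewer
#' parameters.
#'
#' @inheritParams fit_hof
#' @param n_bootstrap number of bootstrap resamples of sites.
#' @param aicc_tol AICc equivalence band for the parsimony rule; `0`
#'   restores a strict lowest-AICc choice.
#' @param seed optional integer seed making the bootstrap deterministic.
#' @return an `hof_fit` for the selected model, with components
#'   `bootstrap_support` (fraction of resamples choosing the selected
#'   model), `bootstrap_table` and `candidates` (per-model AICc).
#' @export
select_hof <- function(data, x, counts, totals, n_bootstrap = 50,
                       aicc_tol = 2, seed = NULL) {
  x <- dplyr::pull(data, {{ x }})
  y <- dplyr::pull(data, {{ counts }})
  n <- dplyr::pull(data, {{ totals }})
  select_hof_engine(x, y, n, n_bootstrap, aicc_tol, seed)
}

select_hof_engine <- function(x, y, n, n_bootstrap = 50, aicc_tol = 2,
                              seed = NULL) {
  keep <- is.finite(x) & is.finite(y) & is.finite(n) & n > 0
  x <- x[keep]; y <- y[keep]; n <- n[keep]
  if (all(y == 0)) abort("all counts are zero: no signal to model")
  xi <- .to_internal(x)
  ns <- length(x)

  fits <- lapply(hof_model_types, function(m) .hof_fit_engine(m, xi, y, n))
  names(fits) <- hof_model_types
  aiccs <- vapply(hof_model_types, function(m) {
    .aicc(fits[[m]]$log_lik, hof_n_par[[m]], ns)
  }, numeric(1))
  full_choice <- .hof_pick(aiccs, aicc_tol)

  boot_choice <- rep(NA_character_, n_bootstrap)
  if (n_bootstrap > 0) {
    boot_choice <- with_seed_if(seed, {
      vapply(seq_len(n_bootstrap), function(b) {
        idx <- sample.int(ns, replace = TRUE)
        ba <- vapply(hof_model_types, function(m) {
          f <- .hof_fit_engine(m, xi[idx], y[idx], n[idx],
                               starts = list(fits[[m]]$par), maxit = 100L)
          if (!f$converged) return(NA_real_)
          .aicc(f$log_lik, hof_n_par[[m]], ns)
        }, numeric(1))
        if (all(is.na(ba))) NA_character_ else .hof_pick(ba[!is.na(ba)], aicc_tol)
      }, character(1))
    })
    if (mean(is.na(boot_choice)) > 0.5) {
      abort("optimisation failed in more than half of the bootstrap resamples")
    }
  }
  tab <- table(factor(boot_choice, levels = hof_model_types))
  if (n_bootstrap > 0 && any(tab > 0)) {
    modal_cand <- names(tab)[tab == max(tab)]
    modal <- modal_cand[order(aiccs[modal_cand], hof_n_par[modal_cand])][1]
    choice <- if (modal != full_choice) modal else full_choice
    support <- unname(tab[choice]) / n_bootstrap
  } else {
    choice <- full_choice
    support <- NA_real_
  }

  par <- setNames(fits[[choice]]$par,
                  c("a", "b", "c", "d")[seq_along(fits[[choice]]$par)])
  structure(
    list(model = choice, coef = par, log_lik = fits[[choice]]$log_lik,
         aicc = aiccs[[choice]], n_sites = ns,
         data = tibble(x = x, counts = y, totals = n),
         bootstrap_support = support,
         bootstrap_table = tab,
         candidates = tibble(model = hof_model_types,
                             aicc = unname(aiccs),
                             log_lik = vapply(fits, `[[`, 0, "log_lik"))),
    class = "hof_fit")
}

#' Predicted response of a fitted HOF model
#'
#' @param object an `hof_fit`.
#' @param newdata optional data frame with a column `x` (gradient on
#'   `[1, 100]`); defaults to the fitting sites.
#' @param ... unused.
#' @export
predict.hof_fit <- function(object, newdata = NULL, ...) {
  x <- if (is.null(newdata)) object$data$x else newdata$x
  hof_response(object$model, object$coef, x)
}

#' @export
print.hof_fit <- function(x, ...) {
  cat("HOF model", x$model, "fit on", x$n_sites, "sites\n")
  cat("  coefficients:",
      paste(names(x$coef), signif(x$coef, 4), sep = " = ", collapse = ", "), "\n")
  cat("  logLik", signif(x$log_lik, 6), " AICc", signif(x$aicc, 6), "\n")
  if (!is.null(x$bootstrap_support) && !is.na(x$bootstrap_support)) {
    cat("  bootstrap support", x$bootstrap_support, "\n")
  }
  invisible(x)
}

#' @export
tidy.hof_fit <- function(x, ...) {
  tibble(term = names(x$coef), estimate = unname(x$coef))
}

#' @export
glance.hof_fit <- function(x, ...) {
  opt <- extract_optimum(x)
  tibble(model = x$model, log_lik = x$log_lik, aicc = x$aicc,
         n_sites = x$n_sites,
         bootstrap_support = x$bootstrap_support %||% NA_real_,
         optimum = opt$optimum)
}

#' Extract the niche optimum from a fitted HOF model
#'
#' The gradient position where the modelled response peaks.  Undefined
#' (returned as `NA`) when the flat model I was selected; for the
#' monotone shapes II and III the optimum lies at the favoured gradient
#' end; for model IV it has the closed form `(c - a) / (2 b)` on the
#' internal scale; for model V it is located by golden-section search
#' (tolerance 1e-6 internal units).  Optima falling outside `[1, 100]`
#' are clamped and flagged.
#'
#' @param fit an `hof_fit`.
#' @param fraction peak fraction defining the inner niche interval passed
#'   to [niche_width()]; `NULL` skips the width computation.
#' @return one-row tibble with `model`, `optimum`, `niche_lo`,
#'   `niche_hi`, `clamped` and `bootstrap_support`.
#' @export
extract_optimum <- function(fit, fraction = exp(-0.5)) {
  stopifnot(inherits(fit, "hof_fit"))
  par <- fit$coef
  clamped <- FALSE
  opt <- switch(fit$model,
    I = NA_real_,
    II = ,
    III = if (par[["b"]] > 0) 1 else 100,
    IV = {
      u <- (par[["c"]] - par[["a"]]) / (2 * par[["b"]])
      .to_gradient(u)
    },
    V = {
      f <- function(xi) -.hof_p_internal("V", par, xi)
      o <- optimize(f, c(-0.5, 0.5), tol = 1e-6)
      # an interior stationary point can lose to a boundary maximum
      cand <- c(o$minimum, -0.5, 0.5)
      .to_gradient(cand[which.min(vapply(cand, f, numeric(1)))])
    })
  if (!is.na(opt) && (opt < 1 || opt > 100)) {
    opt <- min(max(opt, 1), 100)
    clamped <- TRUE
  }
  w <- c(NA_real_, NA_real_)
  if (!is.na(opt) && !is.null(fraction)) {
    w <- niche_width(fit, fraction)
  }
  tibble(model = fit$model, optimum = opt,
         niche_lo = w[[1]], niche_hi = w[[2]], clamped = clamped,
         bootstrap_support = fit$bootstrap_support %||% NA_real_)
}

#' Inner niche width of a fitted HOF model
#'
#' The gradient interval over which the predicted response stays at or
#' above `fraction` times the peak response, intersected with
#' `[1, 100]`.  Requires a defined optimum (models II-V).
#'
#' @inheritParams extract_optimum
#' @param fraction fraction of the peak response; the default
#'   `exp(-1/2)` mirrors the half-width convention of a Gaussian niche at
#'   one standard deviation.
#' @return numeric vector `c(lo, hi)`.
#' @export
niche_width <- function(fit, fraction = exp(-0.5)) {
  stopifnot(inherits(fit, "hof_fit"))
  if (fit$model == "I") abort("niche width is undefined for the flat model I")
  par <- fit$coef
  opt_row <- extract_optimum(fit, fraction = NULL)
  xo <- .to_internal(opt_row$optimum)
  p <- function(xi) .hof_p_internal(fit$model, par, xi)
  peak <- p(xo)
  thr <- fraction * peak
  g <- function(xi) p(xi) - thr
  lo <- -0.5
  if (xo > -0.5 && g(-0.5) < 0) lo <- uniroot(g, c(-0.5, xo), tol = 1e-8)$root
  hi <- 0.5
  if (xo < 0.5 && g(0.5) < 0) hi <- uniroot(g, c(xo, 0.5), tol = 1e-8)$root
  c(.to_gradient(lo), .to_gradient(hi))
}

#' Niche optima for every taxon-by-variable combination
#'
#' Runs HOF model selection for each taxon in an abundance table against
#' each environmental variable and extracts the niche optimum, inner
#' niche interval and bootstrap support.  Entries where the flat model
#' was selected carry `NA` optima.
#'
#' @param abundance wide abundance table: first column the taxon id,
#'   remaining columns per-site (fractional) read counts.  Per-site read
#'   totals for the binomial fits are the column sums of this table
#'   unless `totals` is given.
#' @param env environment table: first column the site id (matching the
#'   abundance columns), remaining columns *rescaled* gradients on
#'   `[1, 100]` (see [rescale_env()]).
#' @param variables variables to model; default all env columns.
#' @param totals optional named vector of per-site read totals.
#' @param min_sites taxa occurring (count > 0) in fewer sites are skipped.
#' @inheritParams select_hof
#' @param fraction peak fraction for the inner niche interval.
#' @return long tibble with one row per taxon x variable: `otu`,
#'   `variable`, `model`, `optimum`, `niche_lo`, `niche_hi`,
#'   `bootstrap_support`.
#' @export
optimum_matrix <- function(abundance, env, variables = NULL, totals = NULL,
                           min_sites = 25, n_bootstrap = 50, aicc_tol = 2,
                           fraction = exp(-0.5), seed = NULL) {
  counts <- table_to_matrix(abundance, "abundance table")
  sites <- as.character(env[[1]])
  missing_sites <- setdiff(colnames(counts), sites)
  if (length(missing_sites) > 0) {
    abort(sprintf("sites absent from environment table: %s",
                  paste(head(missing_sites, 5), collapse = ", ")))
  }
  env_m <- table_to_matrix(env, "environment table")
  variables <- variables %||% colnames(env_m)
  tot <- totals %||% colSums(counts)
  tot <- tot[colnames(counts)]
  # canonical site order so results do not depend on column order
  ord <- order(colnames(counts))
  counts <- counts[, ord, drop = FALSE]
  tot <- tot[ord]

  prevalent <- rowSums(counts > 0) >= min_sites
  otus <- rownames(counts)[prevalent]

  grid <- tidyr::expand_grid(otu = otus, variable = variables)
  seeds <- with_seed_if(seed %||% 1L,
                        sample.int(.Machine$integer.max, nrow(grid)))
  purrr::pmap_dfr(
    list(grid$otu, grid$variable, seeds),
    function(o, v, s) {
      x <- env_m[colnames(counts), v]
      fit <- tryCatch(
        select_hof_engine(x, counts[o, ], tot, n_bootstrap = n_bootstrap,
                          aicc_tol = aicc_tol, seed = s),
        error = function(e) NULL)
      if (is.null(fit)) {
        return(tibble(otu = o, variable = v, model = NA_character_,
                      optimum = NA_real_, niche_lo = NA_real_,
                      niche_hi = NA_real_, bootstrap_support = NA_real_))
      }
      res <- extract_optimum(fit, fraction)
      tibble(otu = o, variable = v, model = res$model,
             optimum = res$optimum, niche_lo = res$niche_lo,
             niche_hi = res$niche_hi,
             bootstrap_support = res$bootstrap_support)
    })
}

#' Pivot a long optimum table to the wide taxon-by-variable form
#'
#' @param optima long tibble from [optimum_matrix()].
#' @return wide tibble, first column `otu`, one column per variable.
#' @export
pivot_optima <- function(optima) {
  tidyr::pivot_wider(optima[, c("otu", "variable", "optimum")],
                     names_from = "variable", values_from = "optimum")
}

#' @describeIn fit_hof plot the observed proportions and fitted curve.
#' @param object an `hof_fit`.
#' @export
autoplot.hof_fit <- function(object, ...) {
  obs <- dplyr::mutate(object$data, proportion = .data$counts / .data$totals)
  grid <- tibble(x = seq(1, 100, length.out = 400))
  grid$fit <- predict(object, grid)
  ggplot2::ggplot(obs, ggplot2::aes(x = .data$x, y = .data$proportion)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_line(data = grid, ggplot2::aes(y = .data$fit),
                       colour = "grey30", linewidth = 1) +
    ggplot2::labs(x = "rescaled gradient (1-100)",
                  y = "relative abundance",
                  title = paste("HOF model", object$model)) +
    ggplot2::theme_minimal()
}
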