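# divergence module: terminal-clade pair selection and the ecological
# divergence ~ 16S dissimilarity regressions with subdivision structure.

#' Terminal-clade (cherry) pairs under a dissimilarity ceiling
#'
#' Finds tip pairs that share an immediate ancestor and whose sequence
#' dissimilarity does not exceed `max_dissim`.  At a polytomy every tip
#' pair within it is considered a cherry and flagged.
#'
#' @param tree a `phylo`.
#' @param dissimilarity square matrix or `dist` of pairwise sequence
#'   dissimilarities (fractions), labelled by tip.
#' @param max_dissim ceiling, default 0.05 (5% 16S dissimilarity).
#' @return tibble `otu1`, `otu2`, `dissimilarity`, `polytomy`.
#' @export
terminal_pairs <- function(tree, dissimilarity, max_dissim = 0.05) {
  d <- as.matrix(dissimilarity)
  if (!all(tree$tip.label %in% rownames(d))) {
    abort("dissimilarity matrix lacks some tips")
  }
  tip_parent <- tree$edge[tree$edge[, 2] <= ape::Ntip(tree), ]
  by_parent <- split(tip_parent[, 2], tip_parent[, 1])
  rows <- purrr::map_dfr(by_parent, function(tips) {
    if (length(tips) < 2) return(NULL)
    labs <- tree$tip.label[tips]
    cmb <- combn(labs, 2)
    tibble(otu1 = cmb[1, ], otu2 = cmb[2, ],
           polytomy = length(tips) > 2)
  })
  if (nrow(rows) == 0) {
    return(tibble(otu1 = character(), otu2 = character(),
                  dissimilarity = numeric(), polytomy = logical()))
  }
  rows$dissimilarity <- d[cbind(rows$otu1, rows$otu2)]
  out <- rows[rows$dissimilarity <= max_dissim,
              c("otu1", "otu2", "dissimilarity", "polytomy")]
  tibble::remove_rownames(out)
}

#' Fit the divergence-versus-dissimilarity linear models
#'
#' Ordinary least squares of ecological divergence on sequence
#' dissimilarity and subdivision, without interaction (common slope,
#' per-subdivision intercepts) and with interaction (per-subdivision
#' slopes).  The two fits are compared by an ANOVA F-test on the
#' interaction terms and by AIC; when they are equivalent the simpler,
#' common-slope model is the one to interpret.
#'
#' @param pairs data frame with columns `divergence`, `dissimilarity`
#'   and `subdivision` (any additional columns ignored).  Keep
#'   `dissimilarity` in percent if the slope should read as "divergence
#'   per percent change".
#' @return object of class `divergence_fit` with components `additive`,
#'   `interaction` (the `lm` fits), `anova` and `aic`; see
#'   [tidy.divergence_fit()] and [glance.divergence_fit()].
#' @export
fit_divergence_models <- function(pairs) {
  stopifnot(all(c("divergence", "dissimilarity", "subdivision") %in%
                  names(pairs)))
  pairs <- dplyr::mutate(pairs, subdivision = factor(.data$subdivision))
  if (nlevels(pairs$subdivision) < 2) abort("need at least two subdivisions")
  counts <- table(pairs$subdivision)
  if (any(counts < 3)) abort("need at least 3 pairs per subdivision")
  m0 <- lm(divergence ~ dissimilarity + subdivision, data = pairs)
  m1 <- lm(divergence ~ dissimilarity * subdivision, data = pairs)
  if (any(!is.finite(coef(m1)))) abort("rank-deficient interaction design")
  an <- anova(m0, m1)
  structure(list(
    additive = m0, interaction = m1, data = pairs,
    anova = tibble(f_statistic = an$F[2], df = an$Df[2],
                   df_resid = an$Res.Df[2], p_value = an$`Pr(>F)`[2]),
    aic = tibble(model = c("additive", "interaction"),
                 aic = c(AIC(m0), AIC(m1)))),
    class = "divergence_fit")
}

#' @export
print.divergence_fit <- function(x, ...) {
  cat("divergence ~ dissimilarity + subdivision",
      sprintf("(AIC %.1f) vs * (AIC %.1f)\n", x$aic$aic[1], x$aic$aic[2]))
  cat(sprintf("  interaction F = %.3f on %d df, p = %.3g\n",
              x$anova$f_statistic, x$anova$df, x$anova$p_value))
  invisible(x)
}

#' @describeIn fit_divergence_models coefficient table; `model` selects
#'   `"additive"` (default) or `"interaction"`.
#' @param x a `divergence_fit`.
#' @param model which fit to tidy.
#' @param ... unused.
#' @export
tidy.divergence_fit <- function(x, model = c("additive", "interaction"),
                                ...) {
  model <- match.arg(model)
  fit <- x[[model]]
  s <- summary(fit)$coefficients
  tibble(term = rownames(s), estimate = unname(s[, 1]),
         std_error = unname(s[, 2]), statistic = unname(s[, 3]),
         p_value = unname(s[, 4]))
}

#' @describeIn fit_divergence_models one-row model comparison summary.
#' @export
glance.divergence_fit <- function(x, ...) {
  s <- summary(x$additive)
  tibble(slope = coef(x$additive)[["dissimilarity"]],
         r_squared = s$r.squared,
         f_statistic = s$fstatistic[[1]],
         aic_additive = x$aic$aic[1], aic_interaction = x$aic$aic[2],
         interaction_f = x$anova$f_statistic,
         interaction_p = x$anova$p_value)
}

#' Subdivision intercepts of the additive model
#'
#' Per-subdivision intercepts (divergence expected at zero
#' dissimilarity) implied by the common-slope fit.
#'
#' @param fit a `divergence_fit`.
#' @return tibble `subdivision`, `intercept`.
#' @export
subdivision_intercepts <- function(fit) {
  stopifnot(inherits(fit, "divergence_fit"))
  cf <- coef(fit$additive)
  levs <- levels(fit$data$subdivision)
  base <- cf[["(Intercept)"]]
  off <- vapply(levs, function(l) {
    nm <- paste0("subdivision", l)
    if (nm %in% names(cf)) cf[[nm]] else 0
  }, numeric(1))
  tibble(subdivision = levs, intercept = unname(base + off))
}

#' Simultaneous pairwise subdivision contrasts
#'
#' All pairwise comparisons of subdivision intercepts from the additive
#' model, with familywise error controlled by the single-step max-|t|
#' method over the joint multivariate-t distribution of the contrast
#' estimates (Holm adjustment available as a fallback).
#'
#' @param fit a `divergence_fit`.
#' @param adjust `"single-step"` or `"holm"`.
#' @return tibble `contrast`, `estimate`, `std_error`, `statistic`,
#'   `p_adj`.
#' @export
group_contrasts <- function(fit, adjust = c("single-step", "holm")) {
  stopifnot(inherits(fit, "divergence_fit"))
  adjust <- match.arg(adjust)
  gl <- multcomp::glht(fit$additive,
                       linfct = multcomp::mcp(subdivision = "Tukey"))
  s <- summary(gl, test = multcomp::adjusted(type = adjust))
  tibble(contrast = names(s$test$coefficients),
         estimate = as.numeric(s$test$coefficients),
         std_error = as.numeric(s$test$sigma),
         statistic = as.numeric(s$test$tstat),
         p_adj = as.numeric(s$test$pvalues))
}

#' Predicted divergence with confidence bands from simulated dissimilarities
#'
#' For each subdivision, draws `n_sim_per_group` dissimilarity values
#' uniformly over that subdivision's observed range and returns the
#' additive model's pointwise prediction with a 95% confidence band.
#'
#' @param fit a `divergence_fit`.
#' @param n_sim_per_group simulated dissimilarities per subdivision.
#' @param level confidence level.
#' @param seed optional integer seed.
#' @return tibble `subdivision`, `dissimilarity`, `fit`, `lwr`, `upr`.
#' @export
predict_with_ci <- function(fit, n_sim_per_group = 50, level = 0.95,
                            seed = NULL) {
  stopifnot(inherits(fit, "divergence_fit"))
  with_seed_if(seed, {
    newdata <- purrr::map_dfr(levels(fit$data$subdivision), function(l) {
      r <- range(fit$data$dissimilarity[fit$data$subdivision == l])
      tibble(subdivision = factor(l, levels(fit$data$subdivision)),
             dissimilarity = sort(runif(n_sim_per_group, r[1], r[2])))
    })
    pr <- predict(fit$additive, newdata, interval = "confidence",
                  level = level)
    dplyr::bind_cols(newdata, as_tibble(pr))
  })
}

#' @describeIn fit_divergence_models scatter with per-subdivision
#'   prediction bands.
#' @param object a `divergence_fit`.
#' @export
autoplot.divergence_fit <- function(object, ...) {
  band <- predict_with_ci(object, seed = 1)
  ggplot2::ggplot(object$data,
                  ggplot2::aes(x = .data$dissimilarity, y = .data$divergence,
                               colour = .data$subdivision)) +
    ggplot2::geom_ribbon(
      data = band,
      ggplot2::aes(y = .data$fit, ymin = .data$lwr, ymax = .data$upr,
                   fill = .data$subdivision), alpha = 0.2, colour = NA) +
    ggplot2::geom_line(data = band, ggplot2::aes(y = .data$fit)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::labs(x = "16S dissimilarity", y = "ecological divergence") +
    ggplot2::theme_minimal()
}
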