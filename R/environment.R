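# environment module: gradient rescaling, land-use intensity, collinearity

#' Rescale a gradient to the common 1-100 scale
#'
#' Affine map sending the observed minimum to 1 and the observed maximum
#' to 100: `x' = 1 + 99 (x - min) / (max - min)`.  Missing values are
#' propagated.
#'
#' @param x numeric vector with at least two distinct finite values.
#' @param range optional `c(min, max)` to rescale against instead of the
#'   observed range.
#' @return numeric vector on `[1, 100]` (values outside `range`, if one
#'   was supplied, fall outside).
#' @examples
#' rescale_gradient(c(4.6, 7.2, 7.5))  # pH: 1, 89.76, 100
#' @export
rescale_gradient <- function(x, range = NULL) {
  r <- range %||% suppressWarnings(c(min(x, na.rm = TRUE), max(x, na.rm = TRUE)))
  if (!all(is.finite(r)) || r[1] >= r[2]) {
    abort("gradient is constant or empty: cannot rescale a zero range")
  }
  1 + 99 * (x - r[1]) / (r[2] - r[1])
}

#' Rescale every variable of an environment table
#'
#' Applies [rescale_gradient()] to each numeric column; the first column
#' is taken as the site identifier and left untouched.
#'
#' @param env site-by-variable table, first column the site id.
#' @return tibble of the same shape with variables on `[1, 100]`.
#' @export
rescale_env <- function(env) {
  out <- as_tibble(env)
  for (v in names(out)[-1]) out[[v]] <- rescale_gradient(out[[v]])
  out
}

#' Land-use intensity index
#'
#' Combines mowing frequency, grazing intensity and fertilisation level
#' into `LUI = sqrt(m / mean(m) + g / mean(g) + f / mean(f))`, each
#' component standardised by its mean over all plots.  A component whose
#' mean is zero (a management type absent everywhere) contributes 0.
#'
#' @param data data frame with one row per plot.
#' @param mowing,grazing,fertilization bare column names of the three
#'   non-negative management components.
#' @return the input with an added `lui` column.
#' @export
compute_lui <- function(data, mowing, grazing, fertilization) {
  m <- dplyr::pull(data, {{ mowing }})
  g <- dplyr::pull(data, {{ grazing }})
  f <- dplyr::pull(data, {{ fertilization }})
  if (any(c(m, g, f) < 0, na.rm = TRUE)) {
    abort("management components must be non-negative")
  }
  term <- function(x) {
    mu <- mean(x, na.rm = TRUE)
    if (!is.finite(mu) || mu == 0) rep(0, length(x)) else x / mu
  }
  dplyr::mutate(data, lui = sqrt(term(m) + term(g) + term(f)))
}

#' Pairwise collinearity screen of environmental variables
#'
#' Pearson correlation for every unordered pair of variables (pairwise
#' complete observations), with the summary used to judge whether
#' collinearity is a concern: the mean absolute correlation and the
#' number of pairs exceeding an absolute threshold.
#'
#' @param env site-by-variable table, first column the site id.
#' @param threshold absolute correlation flagged as high.
#' @return object of class `correlation_screen`; [tidy()] gives the pair
#'   table (`var1`, `var2`, `r`), [glance()] the summary (`n_variables`,
#'   `n_pairs`, `mean_abs_r`, `n_high`).
#' @export
correlation_screen <- function(env, threshold = 0.7) {
  m <- table_to_matrix(env, "environment table")
  if (ncol(m) < 2 || nrow(m) < 3) abort("need >= 2 variables and >= 3 sites")
  sds <- apply(m, 2, sd, na.rm = TRUE)
  if (any(!is.finite(sds) | sds == 0)) {
    abort(sprintf("constant variable(s): %s",
                  paste(colnames(m)[!is.finite(sds) | sds == 0], collapse = ", ")))
  }
  r <- cor(m, use = "pairwise.complete.obs")
  idx <- which(upper.tri(r), arr.ind = TRUE)
  pairs <- tibble(var1 = colnames(m)[idx[, 1]],
                  var2 = colnames(m)[idx[, 2]],
                  r = r[idx])
  structure(list(pairs = pairs, matrix = r, threshold = threshold),
            class = "correlation_screen")
}

#' @export
tidy.correlation_screen <- function(x, ...) x$pairs

#' @export
glance.correlation_screen <- function(x, ...) {
  tibble(n_variables = ncol(x$matrix),
         n_pairs = nrow(x$pairs),
         mean_abs_r = mean(abs(x$pairs$r)),
         n_high = sum(abs(x$pairs$r) > x$threshold))
}

#' @export
print.correlation_screen <- function(x, ...) {
  g <- glance(x)
  cat(g$n_pairs, "variable pairs from", g$n_variables, "variables;",
      "mean |r| =", signif(g$mean_abs_r, 3), ";",
      g$n_high, "pairs with |r| >", x$threshold, "\n")
  invisible(x)
}
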