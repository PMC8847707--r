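# phylogenetic-signal module: Blomberg's K with permutation significance,
# and phylogenetic signal-representation (PSR) curves from phylogenetic
# eigenvector regression.

#' Blomberg's K with permutation test
#'
#' K compares the observed similarity of tip values among relatives to
#' the Brownian-motion expectation: with `V` the phylogenetic covariance
#' (shared root-to-node path lengths) and `a_hat` the GLS estimate of the
#' root state,
#' `K = (MSE0 / MSE) / ((tr(V) - n / sum(V^-1)) / (n - 1))`, where
#' `MSE0` is the ordinary mean squared deviation from `a_hat` and `MSE`
#' the `V^-1`-weighted one.  K equals 1 under Brownian motion, is below 1
#' when relatives resemble each other less than expected (overdispersion,
#' convergent evolution), above 1 when more.  Significance comes from
#' permuting tip values: the p-value is the fraction of permutations
#' whose variance of phylogenetically independent contrasts is at most
#' the observed one (lower contrast variance = stronger signal), with the
#' usual +1 correction.
#'
#' @param tree ultrametric `phylo`.
#' @param trait named numeric vector of tip values (names matching
#'   `tree$tip.label`); must not be constant.
#' @param n_perm number of tip-label permutations (0 skips the test).
#' @param seed optional integer seed.
#' @return one-row tibble `K`, `p_value`, `n_perm`.
#' @export
blomberg_k <- function(tree, trait, n_perm = 999, seed = NULL) {
  y <- align_trait(tree, trait)
  if (sd(y) == 0) abort("trait is constant: K undefined")
  n <- length(y)
  V <- ape::vcv(tree)
  R <- chol(V)                       # V = R'R, solves via triangular backsolve
  iV1 <- backsolve(R, forwardsolve(t(R), rep(1, n)))
  sum_iV <- sum(iV1)
  a_hat <- sum(iV1 * y) / sum_iV
  e <- y - a_hat
  mse0 <- sum(e^2) / (n - 1)
  w <- backsolve(R, forwardsolve(t(R), e))
  mse <- sum(e * w) / (n - 1)
  expected <- (sum(diag(V)) - n / sum_iV) / (n - 1)
  K <- (mse0 / mse) / expected

  p <- NA_real_
  if (n_perm > 0) {
    obs <- pic_variance(tree, y)
    hits <- with_seed_if(seed, {
      sum(vapply(seq_len(n_perm), function(i) {
        pic_variance(tree, setNames(sample(y), names(y))) <= obs
      }, logical(1)))
    })
    p <- (1 + hits) / (1 + n_perm)
  }
  tibble(K = K, p_value = p, n_perm = as.integer(n_perm))
}

pic_variance <- function(tree, y) {
  var(ape::pic(y, tree))
}

align_trait <- function(tree, trait) {
  if (is.null(names(trait))) {
    if (length(trait) != length(tree$tip.label)) {
      abort("unnamed trait must have one value per tip")
    }
    return(setNames(trait, tree$tip.label))
  }
  if (!all(tree$tip.label %in% names(trait))) {
    abort("trait values missing for some tips")
  }
  trait[tree$tip.label]
}

#' Phylogenetic signal-representation (PSR) curve and area
#'
#' Phylogenetic eigenvector regression decomposes the tree into
#' orthogonal eigenvectors and regresses the trait on more and more of
#' them (ordered by eigenvalue); plotting the cumulative `R^2` against
#' the cumulative eigenvalue fraction gives the PSR curve.  Under
#' Brownian motion the curve follows the 45-degree diagonal; the signed
#' area between curve and diagonal (trapezoidal rule, with the origin
#' prepended) is negative for traits that evolved faster than Brownian
#' motion (weaker signal) and positive for slower, more conserved traits.
#'
#' The eigenvectors come from Gower double-centring of `-D/2`, `D` the
#' patristic distance matrix; on an ultrametric tree this equals the
#' centred phylogenetic covariance, which is what makes the
#' Brownian-motion expectation of the curve exactly the diagonal.
#' Eigenvalues below `1e-10` of the largest are truncated.
#'
#' @inheritParams blomberg_k
#' @return object of class `psr_curve`: tibble `curve` with
#'   `eigen_frac` and `r_squared`, plus the scalar `area`.
#' @export
psr_area <- function(tree, trait) {
  y <- align_trait(tree, trait)
  if (length(y) < 4) abort("need at least 4 tips")
  if (sd(y) == 0) abort("trait is constant")
  dec <- phylo_eigen(tree)
  yc <- y[rownames(dec$vectors)] - mean(y)
  r2 <- cumsum(as.vector(crossprod(dec$vectors, yc))^2) / sum(yc^2)
  xf <- cumsum(dec$values) / sum(dec$values)
  curve <- tibble(eigen_frac = c(0, xf), r_squared = c(0, r2))
  dx <- diff(curve$eigen_frac)
  mid_curve <- (head(curve$r_squared, -1) + tail(curve$r_squared, -1)) / 2
  mid_diag <- (head(curve$eigen_frac, -1) + tail(curve$eigen_frac, -1)) / 2
  structure(list(curve = curve, area = sum(dx * (mid_curve - mid_diag))),
            class = "psr_curve")
}

# eigenbasis of the Gower-centred -D/2 (equivalently, centred vcv);
# cached nowhere -- callers looping variables should precompute via
# phylo_signal_profile()
phylo_eigen <- function(tree) {
  D <- cophenetic(tree)
  n <- nrow(D)
  A <- -D / 2
  A <- sweep(A, 1, rowMeans(A))
  A <- sweep(A, 2, colMeans(A))
  e <- eigen(A, symmetric = TRUE)
  keep <- e$values > 1e-10 * max(e$values)
  v <- e$vectors[, keep, drop = FALSE]
  rownames(v) <- rownames(D)
  list(values = e$values[keep], vectors = v)
}

#' @export
print.psr_curve <- function(x, ...) {
  cat("PSR curve over", nrow(x$curve) - 1, "eigenvectors; area =",
      signif(x$area, 4), "\n")
  invisible(x)
}

#' @describeIn psr_area plot the PSR curve against the diagonal.
#' @param object a `psr_curve`.
#' @param ... unused.
#' @export
autoplot.psr_curve <- function(object, ...) {
  ggplot2::ggplot(object$curve,
                  ggplot2::aes(x = .data$eigen_frac, y = .data$r_squared)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey60") +
    ggplot2::geom_line() +
    ggplot2::labs(x = "cumulative eigenvalue fraction",
                  y = expression(R^2),
                  title = sprintf("PSR area = %.3f", object$area)) +
    ggplot2::theme_minimal()
}

#' Phylogenetic signal of every environmental variable
#'
#' Loops [blomberg_k()] and [psr_area()] over the columns of a wide
#' optimum table whose rows are tree tips, sharing the eigendecomposition
#' across variables.
#'
#' @param tree ultrametric `phylo` whose tips are taxa.
#' @param optima wide optimum table (first column the taxon id); rows are
#'   matched to tips.  For each variable, tips with a missing optimum
#'   (flat responders) are pruned before computing the statistics; a
#'   variable retaining fewer than 4 tips gets an `NA` row.
#' @inheritParams blomberg_k
#' @return tibble `variable`, `n_tips`, `K`, `p_value`, `psr_area`.
#' @export
phylo_signal_profile <- function(tree, optima, n_perm = 999, seed = NULL) {
  m <- table_to_matrix(optima, "optimum table")
  if (!all(tree$tip.label %in% rownames(m))) {
    abort("optimum table lacks rows for some tips")
  }
  m <- m[tree$tip.label, , drop = FALSE]
  dec_full <- phylo_eigen(tree)
  seeds <- with_seed_if(seed %||% 1L,
                        sample.int(.Machine$integer.max, ncol(m)))
  purrr::map_dfr(seq_len(ncol(m)), function(j) {
    ok <- is.finite(m[, j]) & !is.na(m[, j])
    if (sum(ok) < 4 || sd(m[ok, j]) == 0) {
      return(tibble(variable = colnames(m)[j], n_tips = sum(ok),
                    K = NA_real_, p_value = NA_real_, psr_area = NA_real_))
    }
    if (all(ok)) {
      tr <- tree
      dec <- dec_full
    } else {
      tr <- ape::keep.tip(tree, rownames(m)[ok])
      dec <- phylo_eigen(tr)
    }
    y <- setNames(m[ok, j], rownames(m)[ok])
    k <- blomberg_k(tr, y, n_perm = n_perm, seed = seeds[[j]])
    yc <- y[rownames(dec$vectors)] - mean(y)
    r2 <- cumsum(as.vector(crossprod(dec$vectors, yc))^2) / sum(yc^2)
    xf <- cumsum(dec$values) / sum(dec$values)
    x0 <- c(0, xf); r0 <- c(0, r2)
    area <- sum(diff(x0) * ((head(r0, -1) + tail(r0, -1)) / 2 -
                              (head(x0, -1) + tail(x0, -1)) / 2))
    tibble(variable = colnames(m)[j], n_tips = sum(ok), K = k$K,
           p_value = k$p_value, psr_area = area)
  })
}
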