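# traits module: cultivated-species comparison -- sparsity pruning, mean
# imputation of optima, pairwise-complete Bray-Curtis, NMDS, Procrustes.

#' Iterative sparsity pruning of a trait matrix
#'
#' Alternately removes species (rows) with information on less than
#' `row_min` of the traits and traits (columns) with information for
#' less than `col_min` of the species, rows first, until both thresholds
#' hold.  Pruning an already-pruned matrix is a no-op.
#'
#' @param data wide trait table, first column the species id, `NA` for
#'   missing entries.
#' @param row_min minimum completeness per species.
#' @param col_min minimum completeness per trait.
#' @return pruned tibble; errors if nothing survives.
#' @export
sparsity_prune <- function(data, row_min = 0.70, col_min = 0.50) {
  m <- table_to_matrix(data, "trait matrix")
  repeat {
    ok_rows <- rowMeans(!is.na(m)) >= row_min
    m <- m[ok_rows, , drop = FALSE]
    if (nrow(m) == 0) break
    ok_cols <- colMeans(!is.na(m)) >= col_min
    m <- m[, ok_cols, drop = FALSE]
    if (ncol(m) == 0) break
    if (all(rowMeans(!is.na(m)) >= row_min) &&
        all(colMeans(!is.na(m)) >= col_min)) break
  }
  if (nrow(m) == 0 || ncol(m) == 0) {
    abort(sprintf(
      "pruning at row_min = %.2f, col_min = %.2f removed everything (started %d x %d)",
      row_min, col_min, nrow(data), ncol(data) - 1))
  }
  matrix_to_table(m, names(data)[[1]])
}

#' Impute missing niche optima by per-variable means
#'
#' Species missing more than `max_missing` optima are dropped (their
#' niches are too poorly determined to rescue); remaining gaps are filled
#' with the mean optimum of the respective variable over the retained
#' species.
#'
#' @param optima wide optimum table, first column the species id.
#' @param max_missing maximum number of missing variables a retained
#'   species may have.
#' @return list: `optima` (completed tibble) and `dropped` (ids).
#' @export
impute_mean_optima <- function(optima, max_missing = 2) {
  m <- table_to_matrix(optima, "optimum table")
  n_miss <- rowSums(is.na(m))
  dropped <- rownames(m)[n_miss > max_missing]
  m <- m[n_miss <= max_missing, , drop = FALSE]
  for (j in seq_len(ncol(m))) {
    miss <- is.na(m[, j])
    if (all(miss)) {
      abort(sprintf("variable %s has no observed optimum", colnames(m)[j]))
    }
    m[miss, j] <- mean(m[, j], na.rm = TRUE)
  }
  list(optima = matrix_to_table(m, names(optima)[[1]]), dropped = dropped)
}

#' Bray-Curtis dissimilarity with pairwise-complete traits
#'
#' `BC(i, j) = sum |x_it - x_jt| / sum (x_it + x_jt)` over the traits
#' `t` observed in both species; traits missing in either member of a
#' pair are omitted from both sums for that pair only.
#'
#' @param data wide trait table (non-negative values; first column the
#'   species id).
#' @return a `dist` object.
#' @export
bray_curtis <- function(data) {
  m <- table_to_matrix(data, "trait matrix")
  if (any(m < 0, na.rm = TRUE)) abort("Bray-Curtis needs non-negative data")
  n <- nrow(m)
  out <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      ok <- !is.na(m[i, ]) & !is.na(m[j, ])
      if (!any(ok)) {
        abort(sprintf("species %s and %s share no observed trait",
                      rownames(m)[i], rownames(m)[j]))
      }
      denom <- sum(m[i, ok] + m[j, ok])
      out[i, j] <- out[j, i] <-
        if (denom == 0) 0 else sum(abs(m[i, ok] - m[j, ok])) / denom
    }
  }
  as.dist(out)
}

#' Non-metric multidimensional scaling of a dissimilarity matrix
#'
#' Kruskal stress-1 NMDS (isotonic regression, iterative majorisation)
#' with multiple random starts, keeping the best solution; scores are
#' centred and rotated to principal axes.
#'
#' @param d a `dist` or square dissimilarity matrix.
#' @param k target dimensionality (must be below n - 1).
#' @param n_starts random starts.
#' @param seed optional integer seed.
#' @return object of class `nmds_ordination` with `scores` (tibble,
#'   first column `species`), `stress` (in `[0, 1]`) and `converged`.
#' @export
nmds_ordination <- function(d, k = 6, n_starts = 20, seed = NULL) {
  d <- as.dist(d)
  n <- attr(d, "Size")
  if (k >= n - 1) abort("k must be smaller than n - 1")
  fit <- with_seed_if(seed, {
    vegan::metaMDS(d, k = k, try = n_starts, trymax = n_starts,
                   autotransform = FALSE, wascores = FALSE, trace = 0)
  })
  sc <- vegan::scores(fit)
  colnames(sc) <- paste0("NMDS", seq_len(ncol(sc)))
  structure(list(scores = matrix_to_table(sc, "species"),
                 stress = fit$stress, converged = fit$converged > 0,
                 engine = fit),
            class = "nmds_ordination")
}

#' @export
print.nmds_ordination <- function(x, ...) {
  cat("NMDS in", ncol(x$scores) - 1, "dimensions; stress =",
      signif(x$stress, 3), "\n")
  invisible(x)
}

#' @describeIn nmds_ordination scatter of the first two NMDS axes.
#' @param object an `nmds_ordination`.
#' @param ... unused.
#' @export
autoplot.nmds_ordination <- function(object, ...) {
  ggplot2::ggplot(object$scores,
                  ggplot2::aes(x = .data$NMDS1, y = .data$NMDS2)) +
    ggplot2::geom_point() +
    ggplot2::labs(caption = sprintf("stress = %.3f", object$stress)) +
    ggplot2::theme_minimal()
}

#' Procrustes concordance of two ordinations with repeated protest
#'
#' Symmetric Procrustes rotation of two score configurations over the
#' same species; the correlation is `sqrt(1 - m2)` with `m2` the
#' minimised sum of squares.  Significance comes from a row-permutation
#' test, and because a permutation p-value is itself noisy the test is
#' repeated `n_repeat` times independently and the mean p reported.
#'
#' @param a,b score tables (first column the species id) or matrices
#'   with matching row sets.
#' @param n_perm permutations per protest run.
#' @param n_repeat independent protest repetitions.
#' @param seed optional integer seed.
#' @return one-row tibble `correlation`, `p_value`, `n_perm`,
#'   `n_repeat`.
#' @export
procrustes_protest <- function(a, b, n_perm = 999, n_repeat = 100,
                               seed = NULL) {
  ma <- score_matrix(a)
  mb <- score_matrix(b)
  if (!setequal(rownames(ma), rownames(mb))) {
    abort("the two configurations cover different species")
  }
  mb <- mb[rownames(ma), , drop = FALSE]
  with_seed_if(seed, {
    ps <- vapply(seq_len(n_repeat), function(i) {
      pr <- vegan::protest(ma, mb, permutations = n_perm)
      c(pr$t0, pr$signif)
    }, numeric(2))
    tibble(correlation = ps[1, 1], p_value = mean(ps[2, ]),
           n_perm = as.integer(n_perm), n_repeat = as.integer(n_repeat))
  })
}

score_matrix <- function(x) {
  if (is.matrix(x)) {
    if (is.null(rownames(x))) rownames(x) <- seq_len(nrow(x))
    return(x)
  }
  if (inherits(x, "nmds_ordination")) return(score_matrix(x$scores))
  if (inherits(x, "pca_ordination")) return(score_matrix(x$scores))
  table_to_matrix(x, "score table")
}

#' Pairwise concordance table of several ordinations
#'
#' Runs [procrustes_protest()] for every pair of named score
#' configurations, the usual way of relating a niche-based ordination to
#' ordinations of independent phenotype matrices.
#'
#' @param scores named list of score tables / matrices / ordination
#'   objects over the same species.
#' @inheritParams procrustes_protest
#' @return tibble `a`, `b`, `correlation`, `p_value`.
#' @export
concordance_table <- function(scores, n_perm = 999, n_repeat = 100,
                              seed = NULL) {
  stopifnot(is.list(scores), length(scores) >= 2, !is.null(names(scores)))
  cmb <- combn(names(scores), 2)
  seeds <- with_seed_if(seed %||% 1L,
                        sample.int(.Machine$integer.max, ncol(cmb)))
  purrr::map_dfr(seq_len(ncol(cmb)), function(i) {
    res <- procrustes_protest(scores[[cmb[1, i]]], scores[[cmb[2, i]]],
                              n_perm = n_perm, n_repeat = n_repeat,
                              seed = seeds[[i]])
    dplyr::bind_cols(tibble(a = cmb[1, i], b = cmb[2, i]),
                     res[c("correlation", "p_value")])
  })
}
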