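# Internal engine for Huisman-Olff-Fresco (HOF) response models I-V.
#
# The gradient enters on the [1, 100] scale used throughout the package and
# is mapped to [0, 1] internally for optimiser conditioning.  The expected
# proportion p(x) is a product of at most two logistic terms with maximum
# attainable response M fixed at 1 (responses are relative abundances):
#
#   I   p = 1 / (1 + e^a)                           flat
#   II  p = 1 / (1 + e^(a + bx))                    monotone sigmoid
#   III p = 1 / ((1 + e^(a + bx)) (1 + e^c))        sigmoid with plateau
#   IV  p = 1 / ((1 + e^(a + bx)) (1 + e^(c - bx))) symmetric unimodal
#   V   p = 1 / ((1 + e^(a + bx)) (1 + e^(c + dx))) skewed unimodal
#
# Counts are modelled as binomial draws with the per-site read totals as
# trials; fitting maximises the binomial log-likelihood with analytic
# gradients under box constraints (L-BFGS-B), from several deterministic
# starts.  The bimodal extensions (VI, VII) are intentionally absent.

hof_model_types <- c("I", "II", "III", "IV", "V")
hof_n_par <- c(I = 1L, II = 2L, III = 3L, IV = 3L, V = 4L)

# numerically stable 1 / (1 + e^u)
.sig <- function(u) plogis(-u)

# internal scale is centred on the gradient midpoint, [-0.5, 0.5], so that
# a symmetric model IV with a = c peaks at 50.5
.to_internal <- function(x) (x - 50.5) / 99
.to_gradient <- function(xi) 50.5 + 99 * xi

.hof_p_internal <- function(model, par, xi) {
  switch(model,
    I   = rep(.sig(par[1]), length(xi)),
    II  = .sig(par[1] + par[2] * xi),
    III = .sig(par[1] + par[2] * xi) * .sig(par[3]),
    IV  = .sig(par[1] + par[2] * xi) * .sig(par[3] - par[2] * xi),
    V   = .sig(par[1] + par[2] * xi) * .sig(par[3] + par[4] * xi),
    abort(sprintf("unknown HOF model type '%s'", model)))
}

.hof_eps <- 1e-10

.hof_nll <- function(par, model, xi, y, n) {
  p <- pmin(pmax(.hof_p_internal(model, par, xi), .hof_eps), 1 - .hof_eps)
  -sum(y * log(p) + (n - y) * log1p(-p))
}

.hof_ngrad <- function(par, model, xi, y, n) {
  p <- pmin(pmax(.hof_p_internal(model, par, xi), .hof_eps), 1 - .hof_eps)
  w <- (y - n * p) / (p * (1 - p))
  g <- switch(model,
    I = {
      s <- .sig(par[1])
      sum(w * s * (1 - s))
    },
    II = {
      s <- .sig(par[1] + par[2] * xi)
      d <- s * (1 - s)
      c(sum(w * d), sum(w * d * xi))
    },
    III = {
      s1 <- .sig(par[1] + par[2] * xi)
      s2 <- .sig(par[3])
      d1 <- s1 * (1 - s1) * s2
      c(sum(w * d1), sum(w * d1 * xi), sum(w * s1 * s2 * (1 - s2)))
    },
    IV = {
      s1 <- .sig(par[1] + par[2] * xi)
      s2 <- .sig(par[3] - par[2] * xi)
      da <- s1 * (1 - s1) * s2
      db <- -s1 * s2 * xi * (s1 - s2)
      dc <- s1 * s2 * (1 - s2)
      c(sum(w * da), sum(w * db), sum(w * dc))
    },
    V = {
      s1 <- .sig(par[1] + par[2] * xi)
      s2 <- .sig(par[3] + par[4] * xi)
      da <- s1 * (1 - s1) * s2
      dc <- s1 * s2 * (1 - s2)
      c(sum(w * da), sum(w * da * xi), sum(w * dc), sum(w * dc * xi))
    })
  g  # gradient of the *negative* ll: d(-ll)/dpar = sum(w * dp/dpar) * (-1)...
}

# The sign bookkeeping above: dp/da = -s(1-s)*<rest>, so
# d(-ll)/da = -sum(w * dp/da) = +sum(w * s(1-s) * <rest>), which is what
# each branch returns.

.hof_bounds <- function(model) {
  lo <- switch(model,
    I   = -100,
    II  = c(-200, -400),
    III = c(-200, -400, -100),
    IV  = c(-200, -400, -200),
    V   = c(-200, -400, -200, -400))
  list(lower = lo, upper = -lo)
}

# Deterministic multi-starts from a coarse grid of curve positions/widths.
.hof_starts <- function(model, y, n) {
  ph <- sum(y) / sum(n)
  a0 <- qlogis(1 - min(max(ph, 1e-6), 1 - 1e-6))            # .sig(a0) == ph
  pk <- max(y / pmax(n, 1))
  h0 <- qlogis(1 - min(max(sqrt(pk), 1e-6), 1 - 1e-6))      # .sig(h0)^2 == pk
  switch(model,
    I   = list(a0),
    II  = lapply(c(-30, -8, 8, 30), function(b) c(a0, b)),
    III = lapply(c(-30, -8, 8, 30), function(b) c(a0, b, 0)),
    IV  = {
      st <- list()
      for (x0 in c(-0.35, -0.15, 0, 0.15, 0.35)) {
        for (b in c(15, 60)) st[[length(st) + 1L]] <- c(h0 - b * x0, b, h0 + b * x0)
      }
      st
    },
    V   = {
      st <- list()
      for (x0 in c(-0.3, 0, 0.3)) {
        for (b in c(15, 60)) st[[length(st) + 1L]] <- c(h0 - b * x0, b, h0 + b * x0, -b)
      }
      st
    })
}

# Maximum-likelihood fit of one model type; extra_starts are appended to
# the deterministic grid (used to warm-start bootstrap refits).
.hof_fit_engine <- function(model, xi, y, n, extra_starts = NULL,
                            starts = NULL, maxit = 200L) {
  if (model == "I") {
    ph <- min(max(sum(y) / sum(n), 1e-9), 1 - 1e-9)
    par <- qlogis(1 - ph)
    return(list(par = par, log_lik = -.hof_nll(par, "I", xi, y, n),
                converged = TRUE))
  }
  b <- .hof_bounds(model)
  sts <- c(starts %||% .hof_starts(model, y, n), extra_starts)
  best <- NULL
  any_ok <- FALSE
  for (st in sts) {
    o <- tryCatch(
      optim(st, fn = .hof_nll, gr = .hof_ngrad, model = model,
            xi = xi, y = y, n = n, method = "L-BFGS-B",
            lower = b$lower, upper = b$upper,
            control = list(maxit = maxit)),
      error = function(e) NULL)
    if (is.null(o) || !is.finite(o$value)) next
    any_ok <- TRUE
    if (is.null(best) || o$value < best$value) best <- o
  }
  if (!any_ok) {
    return(list(par = sts[[1]], log_lik = -Inf, converged = FALSE))
  }
  list(par = best$par, log_lik = -best$value, converged = TRUE)
}

.aicc <- function(log_lik, k, n) {
  -2 * log_lik + 2 * k + 2 * k * (k + 1) / max(n - k - 1, 1)
}

# simplest model whose AICc is within `tol` of the best; ties at equal
# parameter count resolved by AICc, hierarchy order I < II < III < IV < V
.hof_pick <- function(aicc_values, tol = 2) {
  k <- hof_n_par[names(aicc_values)]
  ok <- is.finite(aicc_values) & aicc_values <= min(aicc_values) + tol
  cand <- names(aicc_values)[ok]
  cand[order(k[cand], aicc_values[cand])][1]
}
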