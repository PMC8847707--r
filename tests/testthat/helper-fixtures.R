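# shared fixtures, all generated in code

grad_150 <- function() seq(1, 100, length.out = 150)

# binomial counts from a single HOF curve along a gradient
sim_counts_from_curve <- function(model, par, x = grad_150(), depth = 1e4,
                                  seed = 1) {
  withr::with_seed(seed, rbinom(length(x), depth, hof_response(model, par, x)))
}

# symmetric model IV shape coefficients with peak `pk` at gradient u
iv_par <- function(u, b = 40, pk = 0.02) {
  x0 <- (u - 50.5) / 99
  h <- qlogis(1 - sqrt(pk))
  c(h - b * x0, b, h + b * x0)
}

# toy reference set: 4 near-identical references plus one distant
toy_refs <- function() {
  base <- paste(rep(c("ACGT"), 50), collapse = "")          # 200 bp
  mutate_at <- function(s, pos, to) {
    substr(s, pos, pos) <- to
    s
  }
  tibble::tibble(
    otu = paste0("R", 1:5),
    sequence = c(base,
                 mutate_at(base, 10, "A"),   # base has C at 10
                 mutate_at(base, 50, "G"),   # base has C at 50
                 mutate_at(base, 90, "T"),   # base has C at 90
                 paste(rep("ACCGGTTA", 25), collapse = "")))
}

balanced_4tip <- function() ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
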