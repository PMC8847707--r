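# internal helpers shared across modules

# Run `expr` under a fixed RNG seed when one is given, leaving the global
# RNG state untouched; with seed = NULL the current RNG stream is used.
with_seed_if <- function(seed, expr) {
  if (is.null(seed)) expr else withr::with_seed(as.integer(seed), expr)
}

# First column of a wide table is the row identifier; remaining columns
# must be numeric. Returns a numeric matrix with rownames.
table_to_matrix <- function(data, what = "table") {
  stopifnot(is.data.frame(data), ncol(data) >= 2)
  ids <- as.character(data[[1]])
  if (anyDuplicated(ids)) {
    abort(sprintf("duplicate identifiers in %s: %s", what,
                  paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  m <- as.matrix(data[, -1, drop = FALSE])
  if (!is.numeric(m)) abort(sprintf("non-numeric values in %s", what))
  rownames(m) <- ids
  m
}

matrix_to_table <- function(m, id_name) {
  out <- as_tibble(m, rownames = id_name)
  out
}

is_count <- function(x) length(x) == 1L && is.numeric(x) && !is.na(x) &&
  x == floor(x) && x > 0
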