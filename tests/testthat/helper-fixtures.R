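# Shared fixtures: random plausible map sets and an independent scalar oracle.

# Random map set with physiologically plausible positive ranges (T1/T2 in ms,
# PD in arbitrary units), fixed by seed.
random_map_set <- function(shape = c(8, 8, 8), seed = 1L, grid = NULL) {
  set.seed(seed)
  n <- prod(shape)
  if (is.null(grid)) grid <- ms_grid(shape)
  map_set(
    quantitative_map("T1", array(runif(n, 200, 5000), shape), grid, units = "ms"),
    quantitative_map("T2", array(runif(n, 20, 2000), shape), grid, units = "ms"),
    quantitative_map("PD", array(runif(n, 0.1, 1), shape), grid, units = "arbitrary"))
}

# Independent scalar oracle: evaluates the *equation text* with base R's own
# parser and evaluator on scalar values, bypassing the package's AST path
# entirely. The equation language is a subset of R expression syntax, so the
# text is valid R.
oracle_scalar <- function(eq_text, values) {
  eval(parse(text = eq_text)[[1]], envir = as.list(values), enclos = baseenv())
}

# Brute-force per-voxel evaluation of a model over a map set using the scalar
# oracle, with the same invalid-voxel rule (any required map <= 0 or
# non-finite -> 0).
oracle_volume <- function(model, maps, params = model_defaults(model)) {
  eq_text <- deparse_equation(model$equation)
  shape <- maps$grid$shape
  out <- array(0, dim = shape)
  for (idx in seq_len(prod(shape))) {
    vals <- lapply(maps$maps[model$maps], function(m) m$values[[idx]])
    if (any(!vapply(vals, function(v) is.finite(v) && v > 0, logical(1)))) next
    vals <- c(vals, as.list(unclass(params)))
    out[[idx]] <- oracle_scalar(eq_text, vals)
  }
  out
}

rel_err <- function(a, b) {
  denom <- pmax(abs(a), abs(b))
  err <- abs(a - b)
  err[denom > 0] <- err[denom > 0] / denom[denom > 0]
  max(err)
}

# Small evaluated volume for I/O tests.
small_volume <- function(model_name = "FLAIR", shape = c(16, 16, 8), seed = 3L) {
  ph <- generate_phantom(phantom_spec(shape = shape, seed = seed))
  evaluate_model(builtin_presets()[[model_name]], ph$maps)
}

# JSON objects are unordered: compare parameter tables irrespective of order.
sort_params <- function(p) p[sort(names(p), method = "radix")]
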