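# Internal helpers shared across modules.

# Deterministic seed derivation: every source of randomness in the package
# draws from a seed computed from the root seed plus integer stream labels,
# so cohorts are reproducible trial-by-trial regardless of evaluation order.
# Arithmetic stays exact in doubles (< 2^53) and the result is < 2^31.
derive_seed <- function(root, ...) {
  h <- as.double(root) %% 2147483647
  for (v in c(...)) {
    h <- (h * 69069 + as.double(v) + 1) %% 2147483647
  }
  as.integer(h)
}

# Evaluate `expr` under a local RNG state seeded with `seed`, restoring the
# caller's RNG state afterwards.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopifnot_scalar_pos <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    stop(sprintf("`%s` must be a single positive finite number", name),
         call. = FALSE)
  }
  invisible(x)
}
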