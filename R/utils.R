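# Internal helpers shared across modules.

# Deterministic child seeds from a master seed. Exact in double arithmetic
# (operands stay below 2^53) and always below 2^31, so they are valid R seeds.
derive_seed <- function(master, key) {
  stopifnot(is.numeric(master), length(master) == 1L)
  s <- (abs(master) %% 2147483629)
  for (k in c(key, 0)) {
    s <- (s * 69069 + k * 9973 + 12345) %% 2147483629
  }
  as.integer(s)
}

# Evaluate `expr` with a local RNG state seeded from `seed`, restoring the
# caller's state afterwards.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(expr)
}

clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Shannon entropy (natural log) of a probability vector; 0 * log(0) = 0.
entropy_nat <- function(q) {
  q <- q[q > 0]
  -sum(q * log(q))
}

sem <- function(x) stats::sd(x) / sqrt(length(x))

`%||%` <- function(x, y) if (is.null(x)) y else x

abort_if <- function(cond, msg, class = "tastedyn_error") {
  if (cond) rlang::abort(msg, class = class)
  invisible(NULL)
}
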