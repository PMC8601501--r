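#' @keywords internal
"_PACKAGE"

# Evaluate expr with a temporary RNG state seeded from `seed`, restoring the
# caller's .Random.seed afterwards so package functions never disturb the
# user's RNG stream.
with_seed <- function(seed, expr) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a reproducible child seed below 2^31 from a base seed and an index.
child_seed <- function(seed, i) {
  as.integer((as.double(seed) * 48271 + 104729 * as.double(i)) %% 2147483629)
}

clamp <- function(x, lo, hi) pmin(hi, pmax(lo, x))

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_cropsens <- function(..., class) {
  stop(structure(class = c(class, "cropsens_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}
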