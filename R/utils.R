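# Internal helpers shared across modules.

# Evaluate expr with a locally set RNG seed, restoring the caller's RNG
# state afterwards so package functions never perturb the global stream.
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
  eval.parent(substitute(expr))
}

# Deterministic fold assignment: samples 1..n distributed over n_folds in
# a seed-fixed random order.
make_folds <- function(n, n_folds, seed) {
  if (n_folds < 2L || n_folds > n)
    stop("n_folds must be between 2 and the number of samples")
  idx <- with_seed(seed, sample.int(n))
  fold <- rep_len(seq_len(n_folds), n)
  split(idx, fold)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
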