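#' Evaluate an expression under a temporary RNG seed
#'
#' Restores the caller's RNG state afterwards, so seeded internals never
#' disturb the global random stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  expr
}

#' Derive a stage-specific sub-seed from a global seed
#'
#' Combines the global seed with a short stage tag by a small polynomial
#' string hash, so every stochastic stage of the pipeline gets its own
#' reproducible stream. The result is always in `[0, 2^31 - 1)`.
#'
#' @param global_seed integer.
#' @param tag character stage tag, e.g. `"scars"`.
#' @return integer sub-seed.
#' @export
derive_seed <- function(global_seed, tag) {
  h <- 0
  for (code in utf8ToInt(tag)) h <- (h * 31 + code) %% 2147483647
  as.integer((as.numeric(global_seed) %% 2147483647 * 1000003 + h) %% 2147483647)
}
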