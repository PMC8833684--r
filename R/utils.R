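# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed without disturbing the caller's
# RNG state. All stochastic operations in the package route through this,
# which is what makes selectors pure functions of (data, params, seed).
with_local_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = genv)
    } else if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
      rm(".Random.seed", envir = genv)
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

stop_efs <- function(..., class) {
  stop(errorCondition(paste0(...), class = c(class, "efsbench_error")))
}

assert_scalar_int <- function(x, name, min = 1L) {
  if (length(x) != 1L || !is.finite(x) || x != as.integer(x) || x < min) {
    stop_efs(name, " must be a single integer >= ", min, class = "parameter_error")
  }
  as.integer(x)
}
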