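`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a deterministic sub-seed from a root seed and a stream label
#'
#' All stochastic stages draw their RNG state from one root seed through this
#' function, so each stage is independently re-runnable and the full pipeline
#' is reproducible. The mapping is a small multiplicative hash of the label
#' folded into the root seed, reduced modulo 2^31 - 1.
#'
#' @param seed Integer root seed.
#' @param stream Character stream label, e.g. `"genotypes"`.
#' @return An integer in `[1, 2^31 - 2]` suitable for [set.seed()].
#' @export
derive_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stream))
  m <- 2147483647 # 2^31 - 1 (prime)
  h <- 0
  for (k in utf8ToInt(stream)) h <- (h * 131 + k) %% m
  s <- (abs(as.numeric(seed)) %% m)
  out <- (s * 48271 + h * 69621 + 1) %% m
  as.integer(max(1, out))
}

# Evaluate `code` under a local RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards.
with_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = env)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  force(code)
}

stop_mr <- function(...) stop(..., call. = FALSE)

check_counts <- function(y) {
  if (any(is.na(y)) || any(y < 0))
    stop_mr("counts must be nonnegative and complete")
  if (any(y != round(y)))
    stop_mr("counts must be integers (found non-integer values)")
  invisible(y)
}

check_offset <- function(t) {
  if (any(is.na(t)) || any(t <= 0))
    stop_mr("person-years offset must be strictly positive")
  invisible(t)
}
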