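# Internal helpers shared across modules.

# Run `expr` under a local RNG stream seeded with `seed`, restoring the
# caller's .Random.seed afterwards so no global state leaks.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("`seed` must be a single integer", call. = FALSE)
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a distinct child seed from a parent seed, kept inside 32-bit range.
child_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 48271 + k * 1299721) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_mm <- function(...) stop(sprintf(...), call. = FALSE)

# Stable log-sum-exp.
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

check_tip_match <- function(tree, y) {
  if (is.null(names(y))) stop_mm("tip data must be named by tip label")
  miss <- setdiff(tree$tip.label, names(y))
  if (length(miss))
    stop_mm("tip data missing for tip(s): %s",
            paste(utils::head(miss, 5L), collapse = ", "))
  y[tree$tip.label]
}
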