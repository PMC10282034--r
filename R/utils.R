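# Internal helpers shared across modules.

#' @keywords internal
#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate `expr` under a local RNG stream seeded with `seed`, restoring the
# caller's .Random.seed afterwards so library code never perturbs user RNG.
#' @keywords internal
#' @noRd
with_local_seed <- function(seed, expr) {
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

# Deterministic per-trait seed derived from a master seed; kept within the
# 32-bit signed integer range R requires of set.seed().
#' @keywords internal
#' @noRd
derive_seed <- function(base_seed, index) {
  as.integer((as.numeric(base_seed) * 1000003 + 7919 * as.numeric(index)) %%
               2147483629)
}

#' @keywords internal
#' @noRd
is_binary_flag <- function(x) {
  is.logical(x) && length(x) == 1L && !is.na(x)
}

# Two-sided normal p-value from an estimate and its standard error, floored
# at the smallest positive double so extreme signals never underflow to an
# invariant-violating exact zero.
#' @keywords internal
#' @noRd
z_pval <- function(beta, se) {
  pmax(2 * stats::pnorm(-abs(beta / se)), .Machine$double.xmin)
}
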