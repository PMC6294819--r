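#' @keywords internal
"_PACKAGE"

#' @importFrom stats ar.burg coef complete.cases cor fft lm.fit median na.omit
#'   pnorm pt quantile rbinom rnorm runif sd setNames var
#' @importFrom utils head read.delim tail write.table
NULL

# Descriptive standard deviation: sample convention (divide by n - 1), one
# convention pipeline-wide, matching the defaults of the tools this kind of
# analysis is usually run with (Praat, Matlab's std).
sd_desc <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) < 2L) return(NA_real_)
  stats::sd(x)
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`; the caller's
# .Random.seed is restored afterwards so library code never clobbers user RNG.
with_seed <- function(seed, expr) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env) else if (exists(".Random.seed", envir = env, inherits = FALSE)) rm(".Random.seed", envir = env)
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a child seed from a master seed; kept strictly below 2^31.
derive_seed <- function(master, k) {
  (as.double(master) * 7919 + as.double(k) * 104729) %% 2147483629
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopifnot_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
  invisible(x)
}
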