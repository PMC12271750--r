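# Internal helpers shared across modules.

# Error function; base R exposes it only through pnorm.
erf <- function(z) 2 * stats::pnorm(z * sqrt(2)) - 1

check_family <- function(family) {
  match.arg(family, c("gaussian", "lorentzian"))
}

check_scalar <- function(x, name, lower = -Inf, upper = Inf,
                         strict_lower = FALSE, integer = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  if (integer && x != round(x))
    stop(sprintf("`%s` must be an integer", name), call. = FALSE)
  if (x < lower || (strict_lower && x <= lower) || x > upper)
    stop(sprintf("`%s` = %g is outside its admissible range", name, x),
         call. = FALSE)
  invisible(x)
}

# Evaluate an RNG-consuming expression under a fixed seed, restoring the
# caller's RNG state afterwards so simulations do not perturb user code.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
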