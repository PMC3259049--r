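# Classed conditions so callers (and the CLI) can distinguish bad input from
# a design that genuinely cannot meet its error limits.

stop_invalid <- function(msg, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c("csr_invalid_parameter", "error"),
                      call = call))
}

stop_infeasible <- function(msg, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c("csr_design_infeasible", "error"),
                      call = call))
}

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         strict_lower = FALSE, strict_upper = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_invalid(sprintf("'%s' must be a single finite number", name))
  lo_ok <- if (strict_lower) x > lower else x >= lower
  hi_ok <- if (strict_upper) x < upper else x <= upper
  if (!lo_ok || !hi_ok)
    stop_invalid(sprintf("'%s' = %g is outside its allowed range %s%g, %g%s",
                         name, x,
                         if (strict_lower) "(" else "[", lower, upper,
                         if (strict_upper) ")" else "]"))
  x
}

check_count <- function(x, name, lower = 0L, upper = Inf) {
  check_number(x, name, lower = lower, upper = upper)
  if (x != round(x))
    stop_invalid(sprintf("'%s' must be an integer, got %g", name, x))
  as.integer(x)
}

# Run code under a given seed without disturbing the caller's RNG state.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit(
      if (is.null(old)) {
        if (exists(".Random.seed", globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv()),
      add = TRUE)
    set.seed(seed)
  }
  force(code)
}
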