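# Internal helpers shared across the package.

#' Evaluate an expression with a temporary RNG state
#'
#' Saves and restores `.Random.seed` so that seeded sampling inside the
#' package never disturbs the caller's random number stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, expr) {
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had_seed) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(as.integer(seed))
  expr
}

# Error constructors.  The CLI maps these classes to exit codes, so every
# user-facing failure should go through one of them.
stop_definition <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("retromra_definition_error", "retromra_error")))
}

stop_config <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("retromra_config_error", "retromra_error")))
}

stop_numerical <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("retromra_numerical_error", "retromra_error")))
}

stop_domain <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("retromra_domain_error", "retromra_error")))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

is_named_numeric <- function(x) {
  is.numeric(x) && !is.null(names(x)) && all(nzchar(names(x)))
}

# greatest common divisor of an integer vector (for scaling conservation laws)
vec_gcd <- function(x) {
  g2 <- function(a, b) if (b == 0) a else g2(b, a %% b)
  x <- abs(x[x != 0])
  if (!length(x)) return(1)
  Reduce(g2, x)
}
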