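#' @keywords internal
"_PACKAGE"

# Run expr under a temporary RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards.  All exported generators and stochastic
# solvers route their randomness through this, which is what makes the
# "same seed => bit-identical output" contract hold without clobbering the
# user's session RNG.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

stop_field <- function(field, msg) {
  stop(sprintf("invalid `%s`: %s", field, msg), call. = FALSE)
}

check_count <- function(x, field, min = 1L) {
  if (length(x) != 1L || !is.numeric(x) || is.na(x) || x != floor(x) || x < min) {
    stop_field(field, sprintf("must be a single integer >= %d", min))
  }
  as.integer(x)
}

check_number <- function(x, field, lower = -Inf, upper = Inf,
                         open_lower = FALSE, open_upper = FALSE) {
  ok <- length(x) == 1L && is.numeric(x) && !is.na(x) &&
    (if (open_lower) x > lower else x >= lower) &&
    (if (open_upper) x < upper else x <= upper)
  if (!ok) {
    stop_field(field, sprintf("must be a single number in %s%g, %g%s",
                              if (open_lower) "(" else "[", lower, upper,
                              if (open_upper) ")" else "]"))
  }
  as.numeric(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
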