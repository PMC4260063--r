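# Internal helpers shared across modules.

# Classed error so callers can condition on failure modes
# (invalid_region, invalid_spec, invalid_parameter, incompatible_grids,
# parse_error, empty_input, ...).
abort_appdens <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "appdens_error")))
}

# Run `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
      abort_appdens("`seed` must be a single integer", "invalid_parameter")
    }
    has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (has_old) {
        assign(".Random.seed", old, envir = globalenv())
      } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

check_prob <- function(p, name) {
  if (!is.numeric(p) || length(p) != 1L || is.na(p) || p < 0 || p > 1) {
    abort_appdens(sprintf("`%s` must be a probability in [0, 1]", name),
                  "invalid_parameter")
  }
  invisible(p)
}

check_positive <- function(x, name, class = "invalid_parameter") {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x <= 0) {
    abort_appdens(sprintf("`%s` must be a single positive number", name), class)
  }
  invisible(x)
}

# Canonical number formatting: %g with 6 significant digits.  Idempotent
# under write -> read -> write, which is what makes file round-trips
# byte-identical.
fmt_num <- function(x) {
  out <- formatC(x, format = "g", digits = 6)
  out[is.na(x)] <- ""
  gsub(" ", "", out, fixed = TRUE)
}

euclid <- function(x0, y0, x, y) sqrt((x - x0)^2 + (y - y0)^2)
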