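# Internal helpers shared across modules.

# Classed errors so callers (and tests) can distinguish bad input from bad
# files from I/O failures.
cn_stop <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "complnet_error")))
}

cn_validation_error <- function(msg) cn_stop(msg, "complnet_validation_error")
cn_format_error <- function(msg) cn_stop(msg, "complnet_format_error")
cn_io_error <- function(msg) cn_stop(msg, "complnet_io_error")

`%||%` <- function(a, b) if (is.null(a)) b else a

# Half-up rounding to match how clinical tables print percentages
# (base round() is banker's rounding).
round_half_up <- function(x, digits = 1) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x >= 0 && x == floor(x)
}

is_probability <- function(x) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x >= 0 && x <= 1
}

# Seeded evaluation that never clobbers the caller's RNG state.
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
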