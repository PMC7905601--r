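# Internal helpers shared across modules.

# Run code with a local RNG state so generators are deterministic without
# disturbing the caller's random stream.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    ss_stop("invalid_argument", "seed must be a single finite number")
  }
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
  force(code)
}

# Classed conditions so callers can distinguish failure modes programmatically.
ss_stop <- function(class, message, data = list()) {
  cond <- structure(
    class = c(paste0("seasong_", class), "seasong_error", "error", "condition"),
    c(list(message = message, call = sys.call(-1)), data)
  )
  stop(cond)
}

ss_warn <- function(class, message) {
  warning(structure(
    class = c(paste0("seasong_", class), "seasong_warning", "warning", "condition"),
    list(message = message, call = sys.call(-1))
  ))
}

rms <- function(x) sqrt(mean(x^2))

# Amplitude (linear) to decibels relative to full scale (1.0).
amp_to_db <- function(a) 20 * log10(pmax(a, .Machine$double.xmin))

db_to_amp <- function(db) 10^(db / 20)

is_count <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) && x == round(x)

`%||%` <- function(a, b) if (is.null(a)) b else a
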