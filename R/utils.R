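# internal helpers

# Evaluate `code` under a fixed RNG seed without disturbing the caller's
# random stream.
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         strict_lower = FALSE, strict_upper = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x))
    stop(sprintf("`%s` must be a single number", name), call. = FALSE)
  ok_lo <- if (strict_lower) x > lower else x >= lower
  ok_hi <- if (strict_upper) x < upper else x <= upper
  if (!ok_lo || !ok_hi)
    stop(sprintf("`%s` = %g is outside its valid range", name, x),
         call. = FALSE)
  x
}

check_count <- function(x, name, lower = 0L) {
  check_number(x, name, lower = lower)
  if (x != as.integer(x))
    stop(sprintf("`%s` must be an integer count", name), call. = FALSE)
  as.integer(x)
}

euclid <- function(a, b) sqrt(sum((a - b)^2))

# empty prototypes for the tabular containers used across modules
empty_detections <- function() {
  data.frame(frame = integer(), det_id = integer(),
             x = numeric(), y = numeric())
}

empty_points <- function() {
  data.frame(fragment_id = integer(), frame = integer(),
             x = numeric(), y = numeric())
}
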