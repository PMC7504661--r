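# Internal helpers shared across modules.

# Derive a reproducible child seed from a base seed and a stage offset.
# Kept below 2^31 so it is always a valid R integer seed.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 48271 + offset) %% 2147483647L)
}

assert_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != as.integer(x)) {
    stop(sprintf("'%s' must be an integer >= %d", name, min), call. = FALSE)
  }
  as.integer(x)
}

assert_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    stop(sprintf("'%s' must be a probability in [0, 1]", name), call. = FALSE)
  }
  as.numeric(x)
}

assert_pos <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x <= 0) {
    stop(sprintf("'%s' must be a positive number", name), call. = FALSE)
  }
  as.numeric(x)
}

# A length-2 integer range c(lo, hi) with lo <= hi.
assert_range <- function(x, name, min = 1L) {
  if (length(x) == 1L) x <- c(x, x)
  if (length(x) != 2L || any(x < min) || x[1] > x[2]) {
    stop(sprintf("'%s' must be a range c(lo, hi) with lo <= hi, lo >= %d", name, min),
         call. = FALSE)
  }
  as.integer(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# sample() without the length-1 surprise: always samples from the elements
# of x, even when x is a single number.
resample <- function(x, ...) x[sample.int(length(x), ...)]
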