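# Internal helpers shared across modules.

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Truncated-normal draw with a lower bound only (inverse-CDF method).
# sd = 0 degenerates to the mean (no truncation applied).
rnorm_lower <- function(n, mean, sd, lower) {
  if (sd <= 0) return(rep(mean, n))
  plo <- pnorm((lower - mean) / sd)
  qnorm(runif(n, plo, 1)) * sd + mean
}

# Stable 31-bit hash of a character scalar, used to derive per-subject random
# substreams that depend on the subject id, not its position in the cohort.
string_seed <- function(id) {
  codes <- utf8ToInt(as.character(id))
  h <- 0
  for (k in codes) h <- (h * 31 + k) %% 2147483647L
  as.integer(h)
}

# Derive a child seed below 2^31 from a parent seed and an offset.
child_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(offset)) %% 2147483647)
}

stop_ <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x) length(x) == 1L && is.numeric(x) && !is.na(x) &&
  x == round(x) && x >= 0

sem <- function(x) {
  n <- length(x)
  if (n < 2L) return(0)
  sd(x) / sqrt(n)
}
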