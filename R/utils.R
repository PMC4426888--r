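`%||%` <- function(a, b) if (is.null(a)) b else a

clamp <- function(x, lo = 0, hi = 1) pmin(hi, pmax(lo, x))

#' Combine a base probability with multiplicative modifiers
#'
#' Scenario and zone effects enter the model as multipliers on neutral base
#' probabilities. The effective probability is `min(1, base * prod(modifiers))`;
#' the order of the modifiers is irrelevant.
#'
#' @param base Base probability in `[0, 1]`.
#' @param modifiers Numeric vector of non-negative multipliers (possibly empty).
#' @return A single probability in `[0, 1]`.
#' @examples
#' effective_probability(0.2, 0.5)        # 0.1
#' effective_probability(0.8, 2)          # clamped to 1
#' @export
effective_probability <- function(base, modifiers = numeric()) {
  if (!is.numeric(base) || length(base) != 1L || is.na(base) ||
      base < 0 || base > 1) {
    stop("`base` must be a single probability in [0, 1]", call. = FALSE)
  }
  if (length(modifiers) && (!is.numeric(modifiers) || anyNA(modifiers) ||
                            any(modifiers < 0))) {
    stop("`modifiers` must be non-negative multipliers", call. = FALSE)
  }
  min(1, base * prod(modifiers))
}

# Deterministic 32-bit integer mix of (seed, replicate, year) used to derive
# independent RNG sub-streams. Plain integer arithmetic in double space; the
# result is always a valid positive R integer seed.
mix_seed <- function(seed, replicate = 0L, year = 0L) {
  h <- as.double(seed) %% 2147483647
  for (k in c(as.double(replicate), as.double(year))) {
    h <- (h * 48271 + k * 16807 + 12345) %% 2147483647
  }
  as.integer(h %% 2147483562 + 1)
}

# squared Euclidean distance between point (x0, y0) and vectors x, y
dist2 <- function(x0, y0, x, y) (x - x0)^2 + (y - y0)^2

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

is_flag <- function(x) is.logical(x) && length(x) == 1L && !is.na(x)
is_prob <- function(x) is.numeric(x) && all(!is.na(x)) & all(x >= 0 & x <= 1)
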