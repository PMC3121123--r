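#' Round half away from zero
#'
#' Conventional "half-up" rounding at a fixed number of decimals, used when
#' comparing computed measures against values printed in publication tables
#' (R's \code{round()} rounds half to even, which disagrees at e.g. 0.645).
#'
#' @param x numeric vector.
#' @param digits decimal places (default 2).
#' @return numeric vector rounded half away from zero.
#' @examples
#' roundHalfUp(0.645)       # 0.65
#' round(0.645, 2)          # 0.64 under banker's rounding
#' @export
roundHalfUp <- function(x, digits = 2L) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5 + 1e-9) / m
}

# derive a stream-specific 32-bit seed from a base seed; keeps independent
# randomness sources (undersampling, folds, tuning) decoupled
.substream_seed <- function(seed, offset) {
  (as.integer(seed) + 1000003L * as.integer(offset)) %% 2147483647L
}

.stop_if <- function(cond, ...) if (cond) stop(..., call. = FALSE)

# labels arrive as {0,1} or {-1,+1}; normalise to +1/-1 integer
.as_pm1 <- function(labels) {
  u <- unique(labels)
  .stop_if(!all(u %in% c(-1, 0, 1)),
           "labels must be coded 0/1 or -1/+1")
  out <- as.integer(labels)
  out[out == 0L] <- -1L
  out
}
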