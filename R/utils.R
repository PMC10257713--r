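## Internal helpers shared across modules.

#' Derive a stage seed from a master seed
#'
#' Every stochastic stage of the pipeline draws its seed deterministically
#' from one master seed, so that a single integer reproduces a whole run
#' while stages remain independently re-runnable.
#'
#' @param seed Master seed (integer).
#' @param offset Stage offset (small integer, one per stage).
#' @return An integer seed in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, offset = 0L) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  m <- 2147483647 # 2^31 - 1, Mersenne prime; keeps seeds in 32-bit range
  s <- (abs(as.numeric(seed)) %% m) + 1
  for (i in seq_len(offset + 1L)) s <- (48271 * s) %% m
  as.integer(s)
}

## stopifnot-style check with a readable message
check_that <- function(ok, msg) {
  if (!isTRUE(ok)) abort(msg)
  invisible(TRUE)
}

check_prob <- function(x, name) {
  check_that(is.numeric(x) && all(is.finite(x)) && all(x >= 0) && all(x <= 1),
             paste0("`", name, "` must be probabilities in [0, 1]."))
}

check_count <- function(x, name, min = 1L) {
  check_that(is.numeric(x) && length(x) == 1L && is.finite(x) &&
               x == as.integer(x) && x >= min,
             paste0("`", name, "` must be a whole number >= ", min, "."))
}

## Sample skewness (type 2, bias-corrected) via e1071
sample_skewness <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) < 3L || sd(x) == 0) return(NA_real_)
  e1071::skewness(x, type = 2)
}
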