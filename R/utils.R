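#' @importFrom stats cor lm.fit median p.adjust phyper pnorm prcomp pt pwilcox
#' @importFrom stats quantile rbeta rbinom rlnorm rnbinom rnorm runif sd setNames
#' @importFrom stats as.dist cutree hclust var model.matrix
#' @importFrom utils combn head read.delim write.table
#' @importFrom methods as is
NULL

#' Derive a reproducible child seed from a root seed and a stream name
#'
#' All randomness in the package flows from one root seed; each stage or
#' bootstrap replicate uses a named substream so that partial re-runs are
#' reproducible. The derivation is a simple deterministic hash kept below
#' 2^31 so the result is always a valid R integer seed.
#'
#' @param seed Integer root seed.
#' @param key Character stream name, e.g. `"bootstrap:17"`.
#' @return A single integer seed.
#' @export
derive_seed <- function(seed, key) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(key))
  codes <- utf8ToInt(key)
  h <- 0
  for (co in codes) h <- (h * 131 + co) %% 2147483629
  as.integer((abs(as.numeric(seed)) * 48271 + h) %% 2147483629)
}

# run expr under a temporary RNG seed, restoring global RNG state afterwards
with_seed <- function(seed, expr) {
  withr::with_seed(as.integer(seed), expr)
}

# stop() with a class so callers/tests can condition on the failure kind
stop_sncnm <- function(msg, class) {
  stop(structure(
    class = c(class, "sncnm_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

# x must be a single number in [lo, hi]
check_scalar <- function(x, name, lo = -Inf, hi = Inf, integer = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lo || x > hi ||
      (integer && x != round(x))) {
    stop_sncnm(sprintf("`%s` must be a %s in [%s, %s], got: %s",
                       name, if (integer) "whole number" else "number",
                       format(lo), format(hi), paste(format(x), collapse = ",")),
               "sncnm_invalid_design")
  }
  invisible(TRUE)
}

# population (n-denominator) standard deviation
sd_pop <- function(x) {
  n <- length(x)
  if (n == 0L) return(NA_real_)
  sqrt(sum((x - mean(x))^2) / n)
}
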