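# internal numeric helpers

# cumulative trapezoid integral of y over x, same length as x, starts at 0
cumtrapz <- function(x, y) {
  n <- length(x)
  c(0, cumsum(diff(x) * (y[-1] + y[-n]) / 2))
}

#' Round half away from zero
#'
#' Decimal rounding with ties going away from zero (the convention of most
#' printed tables), unlike [round()] which rounds half to even.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return `x` rounded to `digits` decimals.
#' @export
#' @examples
#' round_half_up(0.125, 2) # 0.13, where round() gives 0.12
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  # the epsilon absorbs binary representation error in decimal halves
  # (1.005 * 100 is stored just below 100.5)
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

#' Small-sample corrected Akaike information criterion
#'
#' @param logL log-likelihood at the optimum.
#' @param k number of free parameters.
#' @param n sample size (for birth-death fits, the number of branching times).
#' @return AICc value; falls back to plain AIC when `n <= k + 1`.
#' @export
aicc <- function(logL, k, n) {
  out <- -2 * logL + 2 * k
  if (n > k + 1) out <- out + 2 * k * (k + 1) / (n - k - 1)
  out
}

#' Likelihood-ratio test between two nested fits
#'
#' @param logL0,logL1 log-likelihoods of the constrained and the full model.
#' @param df degrees of freedom (parameter-count difference).
#' @param boundary if `TRUE` and `df == 1`, use the 50:50 chi-squared 0/1
#'   mixture appropriate when the constrained value lies on the boundary of
#'   the parameter space (e.g. testing extinction = 0).
#' @return list with the test statistic and p-value.
#' @export
lrt <- function(logL0, logL1, df, boundary = FALSE) {
  stat <- max(0, 2 * (logL1 - logL0))
  if (boundary && df == 1) {
    p <- if (stat == 0) 1 else 0.5 * pchisq(stat, df = 1, lower.tail = FALSE)
  } else {
    p <- pchisq(stat, df = df, lower.tail = FALSE)
  }
  list(statistic = stat, df = df, p.value = p, boundary = boundary)
}

# deterministic polynomial hash of a deparsed R object (provenance only);
# modulus keeps the accumulator in exact double-precision integer range
config_hash <- function(x) {
  bytes <- utf8ToInt(paste(deparse(x), collapse = "\n"))
  h <- 17
  for (b in bytes) h <- (h * 8191 + b) %% 2147483647
  sprintf("%08x", h)
}

# multi-start bounded minimiser: returns best nlminb result over starts
multi_start <- function(obj, starts, lower, upper) {
  best <- NULL
  for (s in seq_len(nrow(starts))) {
    res <- tryCatch(
      nlminb(starts[s, ], obj, lower = lower, upper = upper,
             control = list(iter.max = 500, eval.max = 1000)),
      error = function(e) NULL)
    if (is.null(res) || !is.finite(res$objective)) next
    if (is.null(best) || res$objective < best$objective) best <- res
  }
  if (is.null(best)) stop("optimization failed for every start")
  best
}
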