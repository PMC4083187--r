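#' Modified Thompson tau outlier rejection
#'
#' Iteratively removes at most one observation per pass: compute the mean
#' and sample SD of the current values, locate the single point with the
#' largest absolute deviation, and remove it if that deviation exceeds
#' `tau * SD`, where `tau = t * (n - 1) / (sqrt(n) * sqrt(n - 2 + t^2))`
#' and `t` is the two-sided Student-t critical value at level `alpha` on
#' `n - 2` degrees of freedom. Stops when the extreme point is retained.
#'
#' @param values Numeric vector.
#' @param alpha Significance level in (0, 1); default 0.05 mirrors the
#'   assay's 95% convention.
#' @return A list with `retained` (surviving values, original order
#'   preserved), `removed_idx` (indices into `values`, in removal order)
#'   and `removed` (the rejected values).
#' @examples
#' thompson_tau_filter(c(9.8, 10.0, 10.2, 10.5, 35.0))$removed
#' @export
thompson_tau_filter <- function(values, alpha = 0.05) {
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 1)
    stop("'alpha' must lie in (0, 1)", call. = FALSE)
  if (!is.numeric(values)) stop("'values' must be numeric", call. = FALSE)
  if (anyNA(values)) stop("'values' must not contain NA", call. = FALSE)
  keep <- rep(TRUE, length(values))
  removed_idx <- integer(0)
  if (length(values) < 3L) {
    warning("fewer than 3 values: outlier test undefined, nothing removed",
            call. = FALSE)
    return(list(retained = values, removed_idx = removed_idx,
                removed = values[0]))
  }
  repeat {
    idx <- which(keep)
    n <- length(idx)
    if (n < 3L) break
    x <- values[idx]
    s <- stats::sd(x)
    if (s == 0) break
    dev <- abs(x - mean(x))
    i_max <- which.max(dev)
    tcrit <- stats::qt(1 - alpha / 2, df = n - 2L)
    tau <- tcrit * (n - 1) / (sqrt(n) * sqrt(n - 2 + tcrit^2))
    if (dev[i_max] > tau * s) {
      removed_idx <- c(removed_idx, idx[i_max])
      keep[idx[i_max]] <- FALSE
    } else break
  }
  list(retained = values[keep], removed_idx = removed_idx,
       removed = values[removed_idx])
}

# Critical tau values for sample sizes 1..n_max (NA below n = 3).
tau_critical <- function(n_max, alpha) {
  k <- seq_len(n_max)
  tc <- suppressWarnings(stats::qt(1 - alpha / 2, df = k - 2L))
  tau <- tc * (k - 1) / (sqrt(k) * sqrt(k - 2 + tc^2))
  tau[k < 3L] <- NA_real_
  tau
}

# Trimmed mean of a sorted vector under the modified Thompson tau rule.
# The extreme deviation is always at an end of the sorted vector, so each
# removal is O(1) via running sums. Matches the iterative reference up to
# tie-breaks between the two ends.
tau_trimmed_mean_sorted <- function(xs, taus) {
  n <- length(xs)
  if (n < 3L) return(mean(xs))
  lo <- 1L; hi <- n
  s <- sum(xs); ss <- sum(xs * xs)
  while (hi - lo + 1L >= 3L) {
    k <- hi - lo + 1L
    mu <- s / k
    v <- (ss - k * mu * mu) / (k - 1)
    if (v <= 0) break
    dlo <- mu - xs[lo]; dhi <- xs[hi] - mu
    at_hi <- dhi >= dlo
    if (max(dlo, dhi) > taus[k] * sqrt(v)) {
      if (at_hi) { s <- s - xs[hi]; ss <- ss - xs[hi]^2; hi <- hi - 1L }
      else { s <- s - xs[lo]; ss <- ss - xs[lo]^2; lo <- lo + 1L }
    } else break
  }
  s / (hi - lo + 1L)
}
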