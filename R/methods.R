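#' @export
print.methylation_estimate <- function(x, digits = 2, ...) {
  cat(sprintf("Global CpG methylation estimate — sample '%s'%s\n",
              x$sample_id,
              if (is.na(x$condition)) "" else sprintf(" (%s)", x$condition)))
  cat(sprintf("  %% methylation: %.*f  [%.*f, %.*f] (%.0f%% percentile bootstrap, B = %d)\n",
              digits, x$pct_methylation, digits, x$ci_low, digits, x$ci_high,
              100 * x$ci_level, x$n_boot))
  if (x$pct_methylation < 0)
    cat("  note: negative estimate — control damage exceeds the digestion signal\n")
  invisible(x)
}

#' Summarise a methylation estimate
#'
#' @param object A `methylation_estimate`.
#' @param ... Unused.
#' @return The object, invisibly, after printing group sizes, outlier
#'   counts and bootstrap diagnostics.
#' @export
summary.methylation_estimate <- function(object, ...) {
  print(object)
  cat(sprintf("  comets retained: control %d, HpaII %d, MspI %d\n",
              object$n_control, object$n_hpaii, object$n_mspi))
  cat(sprintf("  outliers removed: control %d, HpaII %d, MspI %d (modified Thompson tau)\n",
              object$n_removed[["control"]], object$n_removed[["hpaii"]],
              object$n_removed[["mspi"]]))
  if (object$n_boot_discarded > 0)
    cat(sprintf("  bootstrap replicates discarded (zero MspI mean): %d\n",
                object$n_boot_discarded))
  if (!is.na(object$seed)) cat(sprintf("  seed: %d\n", object$seed))
  invisible(object)
}

#' @export
coef.methylation_estimate <- function(object, ...) {
  c(pct_methylation = object$pct_methylation)
}

#' Confidence interval of a methylation estimate
#'
#' Returns the percentile bootstrap interval stored in the estimate. The
#' interval was fixed at fit time; `level` must match the fit's
#' `ci_level`.
#'
#' @param object A `methylation_estimate`.
#' @param parm Ignored (single-parameter model).
#' @param level Must equal the estimate's `ci_level`.
#' @param ... Unused.
#' @return A 1 x 2 matrix with the interval bounds.
#' @export
confint.methylation_estimate <- function(object, parm, level = 0.95, ...) {
  if (!isTRUE(all.equal(level, object$ci_level)))
    stop(sprintf("interval was constructed at level %.2f; refit to change it",
                 object$ci_level), call. = FALSE)
  m <- matrix(c(object$ci_low, object$ci_high), nrow = 1,
              dimnames = list("pct_methylation",
                              sprintf("%.1f %%", 100 * c((1 - level) / 2,
                                                         1 - (1 - level) / 2))))
  m
}

#' Plot the bootstrap distribution of a methylation estimate
#'
#' Histogram of the bootstrap replicates with the point estimate and
#' percentile interval marked.
#'
#' @param x A `methylation_estimate`.
#' @param ... Passed to [graphics::hist()].
#' @export
plot.methylation_estimate <- function(x, ...) {
  graphics::hist(x$boot, breaks = 40, col = "grey85", border = "grey60",
                 main = sprintf("Bootstrap distribution - %s", x$sample_id),
                 xlab = "% CpG methylation", ...)
  graphics::abline(v = x$pct_methylation, col = "firebrick", lwd = 2)
  graphics::abline(v = c(x$ci_low, x$ci_high), col = "firebrick",
                   lty = 2)
  invisible(x)
}

#' @export
print.methylation_contrast <- function(x, digits = 2, ...) {
  cat("Methylation difference (untreated - treated)\n")
  cat(sprintf("  %.*f percentage points  [%.*f, %.*f] (%.0f%% bootstrap CI)\n",
              digits, x$difference, digits, x$ci_low, digits, x$ci_high,
              100 * x$ci_level))
  invisible(x)
}
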