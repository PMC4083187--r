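#' Treatment groups of per-comet tail intensities
#'
#' Bundles the three treatment groups of one methylation-sensitive comet
#' assay sample: undigested control, HpaII-digested and MspI-digested
#' nucleoids, each a vector of per-comet tail-intensity percentages.
#'
#' @param control,hpaii,mspi Numeric vectors of tail-intensity percentages
#'   in `[0, 100]`, one value per scored comet.
#' @param sample_id Sample label.
#' @param condition Optional condition label carried through to results.
#' @return An object of class `"comet_groups"`.
#' @export
comet_groups <- function(control, hpaii, mspi, sample_id = "sample",
                         condition = NA_character_) {
  g <- list(control = as.numeric(control), hpaii = as.numeric(hpaii),
            mspi = as.numeric(mspi), sample_id = sample_id,
            condition = condition)
  for (nm in c("control", "hpaii", "mspi")) {
    v <- g[[nm]]
    if (length(v) == 0L)
      stop(sprintf("treatment group '%s' is empty", nm), call. = FALSE)
    if (anyNA(v) || any(v < 0) || any(v > 100))
      stop(sprintf("tail intensities in group '%s' must lie in [0, 100]", nm),
           call. = FALSE)
  }
  class(g) <- "comet_groups"
  g
}

#' @export
print.comet_groups <- function(x, ...) {
  cat(sprintf("Comet assay sample '%s'%s\n", x$sample_id,
              if (is.na(x$condition)) "" else
                sprintf(" (%s)", x$condition)))
  for (nm in c("control", "hpaii", "mspi"))
    cat(sprintf("  %-8s n = %4d, mean tail = %6.2f%%\n", nm,
                length(x[[nm]]), mean(x[[nm]])))
  invisible(x)
}

#' Percentage CpG methylation from group mean tail intensities
#'
#' The assay's core statistic: global CCGG methylation inferred from the
#' ratio of mean tail DNA after HpaII versus MspI digestion, corrected for
#' pre-existing damage by subtracting the undigested-control mean:
#' `(100 - 100 * hpaii_mean / mspi_mean) - control_mean`. The value is not
#' clipped; negative estimates are legal and signal control damage
#' exceeding the digestion signal.
#'
#' @param hpaii_mean,mspi_mean,control_mean Mean percentage tail DNA of the
#'   HpaII, MspI and control groups.
#' @return Percentage CpG methylation (unclipped).
#' @examples
#' pct_cpg_methylation(40, 80, 5)  # 45
#' @export
pct_cpg_methylation <- function(hpaii_mean, mspi_mean, control_mean) {
  if (any(c(hpaii_mean, mspi_mean, control_mean) < 0))
    stop("group means must be non-negative", call. = FALSE)
  if (mspi_mean == 0)
    stop("MspI mean tail intensity is zero: ratio undefined (failed MspI digestion?)",
         call. = FALSE)
  (100 - 100 * hpaii_mean / mspi_mean) - control_mean
}

#' Estimate percentage CpG methylation with bootstrap confidence interval
#'
#' The full estimation pipeline for one sample: each treatment group is
#' filtered independently with [thompson_tau_filter()]; the point estimate
#' is [pct_cpg_methylation()] of the filtered group means; inference is by
#' nonparametric bootstrap of the whole estimator: each replicate
#' resamples comets within each original treatment group with replacement
#' (same size) and recomputes the full statistic, including tau
#' re-filtering of the resampled groups, so the interval reflects the
#' sampling variability of the trimmed estimator. The confidence interval
#' is the percentile interval of the replicates.
#'
#' @param groups A [comet_groups()] object (or a data.frame in the
#'   per-comet table schema; see [read_comet_csv()]).
#' @param alpha_tau Significance level for outlier rejection.
#' @param n_boot Bootstrap replications (the assay convention is 10,000).
#' @param ci_level Confidence level of the percentile interval.
#' @param seed Optional RNG seed; the estimate is fully reproducible given
#'   the seed.
#' @param ... Passed to methods.
#' @return An object of class `"methylation_estimate"` with elements
#'   `pct_methylation`, `ci_low`, `ci_high`, per-group retained sizes
#'   `n_control`/`n_hpaii`/`n_mspi`, `n_removed` (per group), `n_boot`,
#'   `n_boot_discarded` (replicates with a zero MspI resampled mean),
#'   `ci_level`, `seed`, `sample_id`, `condition` and the bootstrap
#'   replicate vector `boot`.
#' @examples
#' g <- comet_groups(control = c(1, 2, 1.5), hpaii = c(18, 22, 20),
#'                   mspi = c(38, 42, 40))
#' estimate_methylation(g, n_boot = 500, seed = 1)
#' @export
estimate_methylation <- function(groups, ...) UseMethod("estimate_methylation")

#' @rdname estimate_methylation
#' @export
estimate_methylation.comet_groups <- function(groups, alpha_tau = 0.05,
                                              n_boot = 10000L,
                                              ci_level = 0.95,
                                              seed = NULL, ...) {
  if (!is.numeric(n_boot) || n_boot < 1L)
    stop("'n_boot' must be at least 1", call. = FALSE)
  if (!is.numeric(ci_level) || ci_level <= 0 || ci_level >= 1)
    stop("'ci_level' must lie in (0, 1)", call. = FALSE)
  n_boot <- as.integer(n_boot)

  filt <- lapply(groups[c("control", "hpaii", "mspi")],
                 thompson_tau_filter, alpha = alpha_tau)
  ctrl <- filt$control$retained
  hpa <- filt$hpaii$retained
  msp <- filt$mspi$retained
  point <- pct_cpg_methylation(mean(hpa), mean(msp), mean(ctrl))

  grp <- groups[c("control", "hpaii", "mspi")]
  boot_stats <- with_seed(seed, {
    taus <- tau_critical(max(lengths(grp)), alpha_tau)
    bm <- function(x) {
      # n_boot tau-trimmed means of resamples of x
      n <- length(x)
      if (n == 1L) return(rep.int(as.numeric(x), n_boot))
      mu0 <- mean(x)
      xc <- x - mu0  # centred to keep the running sums well-conditioned
      vapply(seq_len(n_boot), function(b)
        tau_trimmed_mean_sorted(sort.int(sample(xc, n, replace = TRUE)),
                                taus) + mu0,
        numeric(1))
    }
    cb <- bm(grp$control); hb <- bm(grp$hpaii); mb <- bm(grp$mspi)
    keep <- mb > 0
    list(stat = (100 - 100 * hb[keep] / mb[keep]) - cb[keep],
         discarded = sum(!keep))
  })
  if (boot_stats$discarded > 0.01 * n_boot)
    stop(sprintf(
      "bootstrap unstable: %d of %d replicates had zero MspI resampled mean",
      boot_stats$discarded, n_boot), call. = FALSE)
  qs <- stats::quantile(boot_stats$stat,
                        c((1 - ci_level) / 2, 1 - (1 - ci_level) / 2),
                        names = FALSE)
  structure(list(
    pct_methylation = point,
    ci_low = qs[1], ci_high = qs[2],
    n_control = length(ctrl), n_hpaii = length(hpa), n_mspi = length(msp),
    n_removed = c(control = length(filt$control$removed_idx),
                  hpaii = length(filt$hpaii$removed_idx),
                  mspi = length(filt$mspi$removed_idx)),
    n_boot = n_boot, n_boot_discarded = boot_stats$discarded,
    ci_level = ci_level, seed = if (is.null(seed)) NA_integer_ else seed,
    sample_id = groups$sample_id, condition = groups$condition,
    boot = boot_stats$stat
  ), class = "methylation_estimate")
}

#' @rdname estimate_methylation
#' @export
estimate_methylation.data.frame <- function(groups, ...) {
  gl <- groups_from_table(groups)
  if (length(gl) != 1L)
    stop("data.frame contains more than one (sample_id, condition); ",
         "use estimate_all() or split first", call. = FALSE)
  estimate_methylation(gl[[1L]], ...)
}

#' Estimate methylation for every sample in a per-comet table
#'
#' @param tbl Per-comet measurement table (see [read_comet_csv()]).
#' @param ... Passed to [estimate_methylation()]. When a `seed` is given,
#'   sample `i` (in table order) uses `seed + i - 1` so samples remain
#'   independent yet reproducible.
#' @return A list of `methylation_estimate` objects, one per
#'   (sample_id, condition).
#' @export
estimate_all <- function(tbl, ...) {
  gl <- groups_from_table(tbl)
  dots <- list(...)
  out <- vector("list", length(gl))
  for (i in seq_along(gl)) {
    args <- dots
    if (!is.null(args$seed)) args$seed <- args$seed + i - 1L
    out[[i]] <- do.call(estimate_methylation, c(list(gl[[i]]), args))
  }
  names(out) <- names(gl)
  out
}

#' Contrast two methylation estimates
#'
#' Difference in percentage CpG methylation between two conditions
#' (typically untreated minus demethylating-agent-treated), with a
#' percentile bootstrap confidence interval obtained by differencing the
#' two estimates' independent bootstrap replicate streams.
#'
#' @param est_untreated,est_treated `methylation_estimate` objects built
#'   with the same `ci_level`.
#' @return An object of class `"methylation_contrast"` with `difference`,
#'   `ci_low`, `ci_high` and the two input estimates.
#' @examples
#' u <- estimate_methylation(comet_groups(0, 39.8, 100), n_boot = 10)
#' t <- estimate_methylation(comet_groups(0, 66.0, 100), n_boot = 10)
#' compare_conditions(u, t)$difference  # 26.2
#' @export
compare_conditions <- function(est_untreated, est_treated) {
  stopifnot(inherits(est_untreated, "methylation_estimate"),
            inherits(est_treated, "methylation_estimate"))
  if (!isTRUE(all.equal(est_untreated$ci_level, est_treated$ci_level)))
    stop("estimates were built with different confidence levels",
         call. = FALSE)
  diff_point <- est_untreated$pct_methylation - est_treated$pct_methylation
  k <- min(length(est_untreated$boot), length(est_treated$boot))
  if (length(est_untreated$boot) != length(est_treated$boot))
    warning("bootstrap streams of unequal length; pairing the first ",
            k, " replicates", call. = FALSE)
  dboot <- est_untreated$boot[seq_len(k)] - est_treated$boot[seq_len(k)]
  lvl <- est_untreated$ci_level
  qs <- stats::quantile(dboot, c((1 - lvl) / 2, 1 - (1 - lvl) / 2),
                        names = FALSE)
  structure(list(difference = diff_point, ci_low = qs[1], ci_high = qs[2],
                 ci_level = lvl,
                 untreated = est_untreated, treated = est_treated),
            class = "methylation_contrast")
}
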