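#' Expected tail intensity for a given number of strand breaks
#'
#' Saturating dose-response linking strand breaks per nucleoid to the
#' percentage of DNA migrating into the comet tail:
#' `100 * (1 - exp(-breaks / kappa))`. Monotone increasing in `breaks`,
#' bounded in `[0, 100)`, and approximately linear (`100 * breaks / kappa`)
#' when `breaks << kappa` — the regime in which the HpaII/MspI ratio
#' statistic tracks the methylated-site fraction.
#'
#' @param breaks Non-negative break count(s).
#' @param kappa Positive saturation constant (breaks).
#' @return Tail intensity percentage(s) in `[0, 100)`.
#' @examples
#' expected_tail_intensity(0, 1000)      # 0
#' expected_tail_intensity(1000, 1000)   # 100 * (1 - exp(-1)) ~ 63.2
#' @export
expected_tail_intensity <- function(breaks, kappa) {
  if (!is.numeric(kappa) || length(kappa) != 1L || is.na(kappa) || kappa <= 0)
    stop("parameter 'kappa' must be a single positive number", call. = FALSE)
  if (any(breaks < 0)) stop("'breaks' must be non-negative", call. = FALSE)
  100 * (1 - exp(-breaks / kappa))
}

# Integer site counts per susceptibility class; rounding keeps the three
# classes within S.
site_counts <- function(p) {
  n_hpa_full <- round(p$S * max(0, 1 - p$m - p$e - p$h))  # HpaII cuts at rate d
  n_hemi     <- round(p$S * p$h)                          # HpaII cuts at d * d_hemi_factor
  n_mspi     <- round(p$S * (1 - p$e))                    # MspI cuts at rate d
  list(hpa_full = n_hpa_full, hemi = n_hemi, mspi = n_mspi)
}

#' Simulate a per-cell comet population for one sample
#'
#' Draws per-cell strand-break counts for the three treatment groups of a
#' methylation-sensitive comet assay sample and converts them to tail
#' intensities. Per cell: baseline breaks `B0 ~ Poisson(lambda0)` (shared
#' damage model across groups); the MspI group adds
#' `Binomial(S * (1 - e), d)` enzyme cuts; the HpaII group adds
#' `Binomial(S * (1 - m - e - h), d) + Binomial(S * h, d * d_hemi_factor)`;
#' the undigested control has baseline breaks only. Tail intensity is
#' `clip(expected_tail_intensity(B, kappa) + Normal(0, sigma), 0, 100)`.
#'
#' @param params A [sim_params()] object.
#' @param sample_id Sample label written into the output table.
#' @param condition Experimental condition label (e.g. `"untreated"` or
#'   `"aza_treated"`).
#' @return A `data.frame` with columns `sample_id`, `condition`, `well`,
#'   `cell_id`, `treatment` (control/HpaII/MspI) and `tail_intensity`,
#'   containing `3 * n_wells * n_cells` rows. Deterministic given
#'   `params$seed`.
#' @examples
#' x <- simulate_cell_population(sim_params(m = 0.6, seed = 1), "s1")
#' table(x$treatment)
#' @export
simulate_cell_population <- function(params, sample_id,
                                     condition = "untreated") {
  validate_sim_params(params)
  with_seed(params$seed, {
    sc <- site_counts(params)
    n_per_group <- params$n_wells * params$n_cells
    draw_group <- function(extra_breaks_fun) {
      b0 <- stats::rpois(n_per_group, params$lambda0)
      b <- b0 + extra_breaks_fun(n_per_group)
      ti <- expected_tail_intensity(b, params$kappa) +
        stats::rnorm(n_per_group, 0, params$sigma)
      pmin(pmax(ti, 0), 100)
    }
    none <- function(n) 0L
    hpa <- function(n) stats::rbinom(n, sc$hpa_full, params$d) +
      stats::rbinom(n, sc$hemi, params$d * params$d_hemi_factor)
    msp <- function(n) stats::rbinom(n, sc$mspi, params$d)
    ti <- c(draw_group(none), draw_group(hpa), draw_group(msp))
    treatments <- rep(c("control", "HpaII", "MspI"), each = n_per_group)
    wells <- rep(rep(seq_len(params$n_wells), each = params$n_cells), 3L)
    cells <- rep(seq_len(params$n_cells), params$n_wells * 3L)
    data.frame(sample_id = sample_id,
               condition = condition,
               well = wells,
               cell_id = cells,
               treatment = treatments,
               tail_intensity = ti,
               stringsAsFactors = FALSE)
  })
}

#' Simulate a two-condition demethylation experiment
#'
#' Convenience wrapper generating one untreated and one
#' demethylating-agent-treated sample, differing only in their true
#' methylated-site fractions. Defaults emulate a hepatoma culture before and
#' after 24 h exposure to 5-azacytidine.
#'
#' @param m_untreated,m_treated True internal-cytosine methylation fractions
#'   for the two conditions.
#' @param seed RNG seed; the treated sample uses `seed + 1`.
#' @param ... Further arguments passed to [sim_params()].
#' @return A `data.frame` stacking both samples.
#' @export
simulate_experiment <- function(m_untreated = 0.6, m_treated = 0.35,
                                seed = NULL, ...) {
  s2 <- if (is.null(seed)) NULL else seed + 1L
  rbind(
    simulate_cell_population(sim_params(m = m_untreated, seed = seed, ...),
                             "untreated_1", condition = "untreated"),
    simulate_cell_population(sim_params(m = m_treated, seed = s2, ...),
                             "aza_treated_1", condition = "aza_treated")
  )
}

#' Simulate cytosine-extension-assay scintillation counts
#'
#' Radiolabel incorporation at enzyme-cut CCGG overhangs is proportional to
#' the expected number of cut sites, so counts are drawn as
#' `dpm = background + Poisson(scale_dpm * expected cut sites)` with the
#' same enzyme-susceptibility model as the comet simulator.
#'
#' @param params A [sim_params()] object (uses `m`, `h`, `e`, `S`, `d`,
#'   `d_hemi_factor`).
#' @param scale_dpm Positive counts-per-cut-site scale factor.
#' @param background_dpm Non-negative background count added to both
#'   reactions.
#' @param seed Optional RNG seed.
#' @return An object of class `"cea_sample"`: a list with `dpm_hpaii`,
#'   `dpm_mspi`, `dpm_background` and `dna_mass_mg` (0.5 mg, the assay's
#'   reference DNA mass).
#' @examples
#' simulate_cea_counts(sim_params(m = 0.6), scale_dpm = 10, seed = 1)
#' @export
simulate_cea_counts <- function(params, scale_dpm = 10,
                                background_dpm = 0, seed = NULL) {
  validate_sim_params(params)
  if (!is.numeric(scale_dpm) || length(scale_dpm) != 1L || scale_dpm <= 0)
    stop("parameter 'scale_dpm' must be a single positive number",
         call. = FALSE)
  if (!is.numeric(background_dpm) || background_dpm < 0)
    stop("parameter 'background_dpm' must be non-negative", call. = FALSE)
  with_seed(seed, {
    mu_mspi <- scale_dpm * params$S * (1 - params$e) * params$d
    mu_hpa <- scale_dpm * params$S *
      (1 - params$m - params$e - params$h +
         params$h * params$d_hemi_factor) * params$d
    cea_sample(
      dpm_hpaii = background_dpm + stats::rpois(1L, mu_hpa),
      dpm_mspi = background_dpm + stats::rpois(1L, mu_mspi),
      dpm_background = background_dpm,
      dna_mass_mg = 0.5
    )
  })
}

#' Analytic expectation of the methylation statistic under the simulator
#'
#' Closed-form expectation of each group's tail intensity under the
#' forward model (via the moment generating functions of the Poisson
#' baseline and binomial digestion counts), combined into the expected
#' value of the percentage-methylation statistic as the ratio of expected
#' group means. Exact for `sigma = 0`; with measurement noise the
#' clipping to `[0, 100]` makes it approximate.
#'
#' @param params A [sim_params()] object.
#' @return A list with `tail_control`, `tail_hpaii`, `tail_mspi` (expected
#'   tail intensities, %) and `statistic` (expected % CpG methylation).
#' @examples
#' p <- sim_params(m = 0.5, S = 200, d = 0.9, lambda0 = 0, sigma = 0,
#'                 kappa = 20000)
#' expected_methylation_statistic(p)$statistic  # close to 50
#' @export
expected_methylation_statistic <- function(params) {
  validate_sim_params(params)
  sc <- site_counts(params)
  z <- exp(-1 / params$kappa)
  mgf_pois <- exp(params$lambda0 * (z - 1))
  mgf_bin <- function(n, pr) (1 - pr + pr * z)^n
  e_tail <- function(mgf) 100 * (1 - mgf)
  tc <- e_tail(mgf_pois)
  th <- e_tail(mgf_pois * mgf_bin(sc$hpa_full, params$d) *
                 mgf_bin(sc$hemi, params$d * params$d_hemi_factor))
  tm <- e_tail(mgf_pois * mgf_bin(sc$mspi, params$d))
  list(tail_control = tc, tail_hpaii = th, tail_mspi = tm,
       statistic = pct_cpg_methylation(th, tm, tc))
}
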