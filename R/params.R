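#' Simulation parameters for a synthetic comet-assay sample
#'
#' Bundles the forward model's ground truth for one simulated cell
#' population. The model abstracts a nucleoid as `S` CCGG sites, each cut
#' independently with probability `d` when the digesting enzyme is active at
#' that site. HpaII is blocked when either cytosine of the CCGG is
#' methylated and cuts hemimethylated sites at a reduced rate; MspI is
#' blocked only by external-cytosine methylation.
#'
#' @param m Fraction of CCGG sites methylated at the internal cytosine
#'   (blocks HpaII, not MspI). In `[0, 1]`.
#' @param h Fraction of sites hemimethylated; HpaII cuts these at rate
#'   `d * d_hemi_factor`. Default 0.
#' @param e Fraction of sites methylated at the external cytosine (blocks
#'   both HpaII and MspI). Default 0.
#' @param S Effective CCGG site count per nucleoid (positive integer; an
#'   abstract, scaled genome — not a physical site census).
#' @param d Per-site cut probability for a susceptible site, in `[0, 1]`.
#' @param d_hemi_factor Multiplier on `d` for HpaII at hemimethylated sites,
#'   in `[0, 1]`. Default 0.5.
#' @param lambda0 Mean baseline strand breaks per cell (Poisson rate,
#'   shared by all three treatment groups of a sample).
#' @param kappa Saturation constant of the breaks-to-tail-intensity
#'   response, in breaks; must be positive. Tail intensity is
#'   `100 * (1 - exp(-breaks / kappa))`, linear for breaks well below
#'   `kappa`.
#' @param sigma Per-cell additive Gaussian measurement noise SD on the
#'   tail-intensity percentage scale; applied before clipping to `[0, 100]`.
#' @param n_cells Comets per treatment group per well.
#' @param n_wells Wells per sample (the physical assay uses a 12-well
#'   gasket; the study design scores at least nine wells per sample).
#' @param seed Optional RNG seed for reproducible simulation.
#'
#' @return An object of class `"sim_params"` (a validated list).
#' @examples
#' p <- sim_params(m = 0.6)
#' p
#' @export
sim_params <- function(m, h = 0, e = 0, S = 1000L, d = 0.8,
                       d_hemi_factor = 0.5, lambda0 = 50, kappa = 4000,
                       sigma = 5, n_cells = 50L, n_wells = 9L,
                       seed = NULL) {
  p <- list(m = m, h = h, e = e, S = as.integer(S), d = d,
            d_hemi_factor = d_hemi_factor, lambda0 = lambda0,
            kappa = kappa, sigma = sigma, n_cells = as.integer(n_cells),
            n_wells = as.integer(n_wells), seed = seed)
  class(p) <- "sim_params"
  validate_sim_params(p)
  p
}

validate_sim_params <- function(p) {
  chk_frac <- function(x, name) {
    if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1)
      stop(sprintf("parameter '%s' must be a single value in [0, 1]", name),
           call. = FALSE)
  }
  chk_frac(p$m, "m"); chk_frac(p$h, "h"); chk_frac(p$e, "e")
  chk_frac(p$d, "d"); chk_frac(p$d_hemi_factor, "d_hemi_factor")
  if (p$m + p$h + p$e > 1 + 1e-12)
    stop("parameters 'm' + 'h' + 'e' must not exceed 1", call. = FALSE)
  if (is.na(p$S) || p$S < 1L)
    stop("parameter 'S' must be a positive integer", call. = FALSE)
  if (!is.numeric(p$lambda0) || p$lambda0 < 0)
    stop("parameter 'lambda0' must be non-negative", call. = FALSE)
  if (!is.numeric(p$kappa) || p$kappa <= 0)
    stop("parameter 'kappa' must be positive", call. = FALSE)
  if (!is.numeric(p$sigma) || p$sigma < 0)
    stop("parameter 'sigma' must be non-negative", call. = FALSE)
  if (is.na(p$n_cells) || p$n_cells < 1L)
    stop("parameter 'n_cells' must be a positive integer", call. = FALSE)
  if (is.na(p$n_wells) || p$n_wells < 1L)
    stop("parameter 'n_wells' must be a positive integer", call. = FALSE)
  invisible(p)
}

#' @export
print.sim_params <- function(x, ...) {
  cat("Comet-assay simulation parameters\n")
  cat(sprintf("  methylation: m = %.3f, hemi h = %.3f, external e = %.3f\n",
              x$m, x$h, x$e))
  cat(sprintf("  digestion:   S = %d sites, d = %.3f, hemi factor = %.2f\n",
              x$S, x$d, x$d_hemi_factor))
  cat(sprintf("  response:    lambda0 = %.1f breaks, kappa = %.0f, sigma = %.1f%%\n",
              x$lambda0, x$kappa, x$sigma))
  cat(sprintf("  design:      %d wells x %d cells/group (%d comets/treatment)\n",
              x$n_wells, x$n_cells, x$n_wells * x$n_cells))
  if (!is.null(x$seed)) cat(sprintf("  seed:        %d\n", x$seed))
  invisible(x)
}

# Run expr with a locally seeded RNG, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
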