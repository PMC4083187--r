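#' Cytosine extension assay sample
#'
#' Scintillation counts for one CEA reaction set: [3H]dCTP incorporation
#' after HpaII digestion, after MspI digestion, and an undigested
#' background reaction, together with the DNA mass per reaction.
#'
#' @param dpm_hpaii,dpm_mspi,dpm_background Disintegrations per minute
#'   (non-negative). When duplicate counts are taken, average them first.
#' @param dna_mass_mg DNA mass per reaction in mg (positive); the assay
#'   reports incorporation relative to 0.5 mg.
#' @param sample_id,condition Optional labels.
#' @return An object of class `"cea_sample"`.
#' @export
cea_sample <- function(dpm_hpaii, dpm_mspi, dpm_background = 0,
                       dna_mass_mg = 0.5, sample_id = "sample",
                       condition = NA_character_) {
  if (any(c(dpm_hpaii, dpm_mspi, dpm_background) < 0))
    stop("dpm counts must be non-negative", call. = FALSE)
  if (!is.numeric(dna_mass_mg) || dna_mass_mg <= 0)
    stop("'dna_mass_mg' must be positive", call. = FALSE)
  structure(list(dpm_hpaii = dpm_hpaii, dpm_mspi = dpm_mspi,
                 dpm_background = dpm_background,
                 dna_mass_mg = dna_mass_mg, sample_id = sample_id,
                 condition = condition),
            class = "cea_sample")
}

#' @export
print.cea_sample <- function(x, ...) {
  cat(sprintf("CEA sample '%s': HpaII %.0f dpm, MspI %.0f dpm, background %.0f dpm (%g mg DNA)\n",
              x$sample_id, x$dpm_hpaii, x$dpm_mspi, x$dpm_background,
              x$dna_mass_mg))
  invisible(x)
}

#' Relative radiolabel incorporation per 0.5 mg DNA
#'
#' Rescales a dpm count to the assay's reference DNA mass:
#' `dpm * 0.5 / dna_mass_mg`.
#'
#' @param dpm Non-negative count (disintegrations per minute).
#' @param dna_mass_mg DNA mass of the reaction in mg (positive).
#' @return dpm per 0.5 mg DNA.
#' @examples
#' relative_incorporation(1200, 1.0)  # 600
#' @export
relative_incorporation <- function(dpm, dna_mass_mg) {
  if (any(dpm < 0)) stop("'dpm' must be non-negative", call. = FALSE)
  if (!is.numeric(dna_mass_mg) || any(dna_mass_mg <= 0))
    stop("'dna_mass_mg' must be positive", call. = FALSE)
  dpm * 0.5 / dna_mass_mg
}

#' Percentage CpG methylation from cytosine-extension-assay counts
#'
#' Background counts are subtracted from both enzyme reactions and the
#' incorporation is normalised to 0.5 mg DNA; methylation is then
#' `100 * (1 - H / M)` where `H` and `M` are the background-corrected
#' HpaII and MspI incorporations. A background-corrected HpaII count below
#' zero (counting noise) is floored at 0, with an attribute flag.
#'
#' @param sample A [cea_sample()] object.
#' @return Percentage CpG methylation; attribute `hpaii_floored` is `TRUE`
#'   when the HpaII count fell below background.
#' @examples
#' cea_methylation(cea_sample(2000, 5000))  # 60
#' @export
cea_methylation <- function(sample) {
  stopifnot(inherits(sample, "cea_sample"))
  h_raw <- sample$dpm_hpaii - sample$dpm_background
  m_raw <- sample$dpm_mspi - sample$dpm_background
  if (m_raw <= 0)
    stop("background-corrected MspI count is not positive: ratio undefined",
         call. = FALSE)
  floored <- h_raw < 0
  h <- relative_incorporation(max(h_raw, 0), sample$dna_mass_mg)
  m <- relative_incorporation(m_raw, sample$dna_mass_mg)
  structure(100 * (1 - h / m), hpaii_floored = floored)
}

#' Percentage change from control
#'
#' `100 * (treated - control) / control`, the convention used to report
#' CEA incorporation changes after demethylating treatment.
#'
#' @param value_treated,value_control Numeric; `value_control` non-zero.
#' @return Percentage change.
#' @examples
#' percent_change_from_control(1500, 1000)  # +50
#' @export
percent_change_from_control <- function(value_treated, value_control) {
  if (any(value_control == 0))
    stop("control value is zero: percentage change undefined", call. = FALSE)
  100 * (value_treated - value_control) / value_control
}
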