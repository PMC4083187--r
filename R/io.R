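COMET_COLUMNS <- c("sample_id", "condition", "well", "cell_id",
                   "treatment", "tail_intensity")
TREATMENTS <- c("control", "HpaII", "MspI")

canonical_treatment <- function(x) {
  idx <- match(tolower(x), tolower(TREATMENTS))
  out <- TREATMENTS[idx]
  out
}

#' Read a per-comet measurement table
#'
#' Reads and validates a comma-separated per-comet table (the schema
#' emulates the export of commercial comet-scoring software): columns
#' `sample_id`, `condition`, `well` (integer 1-12), `cell_id` (integer),
#' `treatment` (control / HpaII / MspI, case-insensitive) and
#' `tail_intensity` (0-100, decimal point separator). Validation failures
#' are reported with the offending file line numbers (header = line 1).
#'
#' @param path Path to a CSV file with a header row.
#' @return A validated `data.frame` in the schema above, with `treatment`
#'   canonicalised.
#' @seealso [groups_from_table()] to split into per-sample treatment
#'   groups, [estimate_all()] to run the estimator on every sample.
#' @export
read_comet_csv <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path),
                               call. = FALSE)
  tbl <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(COMET_COLUMNS, names(tbl))
  if (length(missing_cols))
    stop(sprintf("missing column(s): %s", paste(missing_cols, collapse = ", ")),
         call. = FALSE)
  tbl <- tbl[COMET_COLUMNS]
  line_no <- seq_len(nrow(tbl)) + 1L
  fail <- function(rows, what) {
    stop(sprintf("%s at line(s) %s of %s", what,
                 paste(utils::head(line_no[rows], 10L), collapse = ", "),
                 path), call. = FALSE)
  }
  if (anyNA(tbl)) fail(apply(is.na(tbl), 1L, any), "missing value")
  canon <- canonical_treatment(tbl$treatment)
  if (anyNA(canon)) fail(is.na(canon), "unknown treatment label")
  tbl$treatment <- canon
  bad_ti <- !is.finite(tbl$tail_intensity) | tbl$tail_intensity < 0 |
    tbl$tail_intensity > 100
  if (any(bad_ti)) fail(bad_ti, "tail_intensity outside [0, 100]")
  bad_well <- tbl$well != as.integer(tbl$well) | tbl$well < 1 | tbl$well > 12
  if (any(bad_well)) fail(bad_well, "well outside 1-12")
  tbl$well <- as.integer(tbl$well)
  tbl$cell_id <- as.integer(tbl$cell_id)
  tbl
}

#' Write a per-comet measurement table
#'
#' @param tbl Table in the per-comet schema (see [read_comet_csv()]).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_comet_csv <- function(tbl, path) {
  stopifnot(all(COMET_COLUMNS %in% names(tbl)))
  utils::write.csv(tbl[COMET_COLUMNS], path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Split a per-comet table into treatment groups per sample
#'
#' @param tbl Per-comet table (see [read_comet_csv()]).
#' @return A named list of [comet_groups()] objects, one per
#'   (sample_id, condition) with all three treatment groups present;
#'   samples missing a treatment group are dropped with a warning.
#' @export
groups_from_table <- function(tbl) {
  key <- interaction(tbl$sample_id, tbl$condition, drop = TRUE, sep = "|")
  out <- list()
  for (k in levels(key)) {
    sub <- tbl[key == k, ]
    have <- TREATMENTS %in% sub$treatment
    if (!all(have)) {
      warning(sprintf("sample '%s': missing treatment group(s) %s; skipped",
                      k, paste(TREATMENTS[!have], collapse = ", ")),
              call. = FALSE)
      next
    }
    out[[k]] <- comet_groups(
      control = sub$tail_intensity[sub$treatment == "control"],
      hpaii = sub$tail_intensity[sub$treatment == "HpaII"],
      mspi = sub$tail_intensity[sub$treatment == "MspI"],
      sample_id = sub$sample_id[1L], condition = sub$condition[1L])
  }
  out
}

RESULT_COLUMNS <- c("sample_id", "condition", "pct_methylation", "ci_low",
                    "ci_high", "n_control", "n_hpaii", "n_mspi",
                    "n_removed_control", "n_removed_hpaii",
                    "n_removed_mspi", "n_boot", "n_boot_discarded",
                    "ci_level", "seed")

estimate_row <- function(e) {
  data.frame(sample_id = e$sample_id, condition = e$condition,
             pct_methylation = e$pct_methylation, ci_low = e$ci_low,
             ci_high = e$ci_high, n_control = e$n_control,
             n_hpaii = e$n_hpaii, n_mspi = e$n_mspi,
             n_removed_control = unname(e$n_removed[["control"]]),
             n_removed_hpaii = unname(e$n_removed[["hpaii"]]),
             n_removed_mspi = unname(e$n_removed[["mspi"]]),
             n_boot = e$n_boot, n_boot_discarded = e$n_boot_discarded,
             ci_level = e$ci_level, seed = e$seed,
             stringsAsFactors = FALSE)
}

#' Write per-sample methylation results
#'
#' Serialises a list of `methylation_estimate` objects to CSV at full
#' precision (17 significant digits) with a fixed column order; estimates,
#' including negative ones, are written untransformed. The bootstrap
#' replicate vectors are not serialised.
#'
#' @param estimates A `methylation_estimate` or list of them.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_results <- function(estimates, path) {
  if (inherits(estimates, "methylation_estimate"))
    estimates <- list(estimates)
  rows <- if (length(estimates)) do.call(rbind, lapply(estimates, estimate_row))
  else stats::setNames(
    as.data.frame(matrix(nrow = 0, ncol = length(RESULT_COLUMNS))),
    RESULT_COLUMNS)
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste(RESULT_COLUMNS, collapse = ","), con)
  if (nrow(rows)) {
    fmt <- vapply(seq_len(nrow(rows)), function(i) {
      paste(vapply(rows[i, ], function(v) {
        if (is.numeric(v) && !is.integer(v)) format(v, digits = 17)
        else as.character(v)
      }, character(1)), collapse = ",")
    }, character(1))
    writeLines(fmt, con)
  }
  invisible(path)
}

#' Read a per-sample methylation results table
#'
#' Inverse of [write_results()]; numeric fields round-trip at full
#' precision.
#'
#' @param path CSV path written by [write_results()].
#' @return A `data.frame` with the result columns.
#' @export
read_results <- function(path) {
  tbl <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(identical(names(tbl), RESULT_COLUMNS))
  tbl
}

#' Read a cytosine-extension-assay counts table
#'
#' Expects columns `sample_id`, `condition`, `enzyme` (HpaII / MspI /
#' background, case-insensitive), `dpm` and `dna_mass_mg`. Duplicate
#' counts of the same reaction (repeated rows) are averaged, the assay's
#' convention for twice-counted samples.
#'
#' @param path CSV path.
#' @return A named list of [cea_sample()] objects, one per
#'   (sample_id, condition).
#' @export
read_cea_csv <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path),
                               call. = FALSE)
  tbl <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "condition", "enzyme", "dpm", "dna_mass_mg")
  missing_cols <- setdiff(need, names(tbl))
  if (length(missing_cols))
    stop(sprintf("missing column(s): %s", paste(missing_cols, collapse = ", ")),
         call. = FALSE)
  enz <- c("HpaII", "MspI", "background")
  canon <- enz[match(tolower(tbl$enzyme), tolower(enz))]
  if (anyNA(canon))
    stop(sprintf("unknown enzyme label at line(s) %s",
                 paste(which(is.na(canon)) + 1L, collapse = ", ")),
         call. = FALSE)
  tbl$enzyme <- canon
  key <- interaction(tbl$sample_id, tbl$condition, drop = TRUE, sep = "|")
  out <- list()
  for (k in levels(key)) {
    sub <- tbl[key == k, ]
    get_mean <- function(which_enz) {
      v <- sub$dpm[sub$enzyme == which_enz]
      if (!length(v))
        stop(sprintf("sample '%s': no %s reaction", k, which_enz),
             call. = FALSE)
      mean(v)
    }
    out[[k]] <- cea_sample(
      dpm_hpaii = get_mean("HpaII"), dpm_mspi = get_mean("MspI"),
      dpm_background = if (any(sub$enzyme == "background"))
        get_mean("background") else 0,
      dna_mass_mg = sub$dna_mass_mg[1L],
      sample_id = sub$sample_id[1L], condition = sub$condition[1L])
  }
  out
}

#' Write per-sample CEA methylation results
#'
#' @param samples Named list of [cea_sample()] objects (as returned by
#'   [read_cea_csv()]).
#' @param path Output CSV path.
#' @param control_condition Condition label used as the reference when
#'   computing percentage change in MspI-normalised HpaII incorporation;
#'   samples whose condition matches get `pct_change_from_control = 0`.
#' @return The results `data.frame`, invisibly; also written to `path`.
#' @export
write_cea_results <- function(samples, path,
                              control_condition = "untreated") {
  rows <- do.call(rbind, lapply(samples, function(s) {
    pm <- cea_methylation(s)
    data.frame(sample_id = s$sample_id, condition = s$condition,
               pct_methylation = as.numeric(pm),
               hpaii_floored = isTRUE(attr(pm, "hpaii_floored")),
               stringsAsFactors = FALSE)
  }))
  ref <- rows$pct_methylation[rows$condition == control_condition]
  rows$pct_change_from_control <- if (length(ref) == 1L && ref != 0)
    percent_change_from_control(rows$pct_methylation, ref) else NA_real_
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(rows)
}

#' Write a simulation ground-truth sidecar
#'
#' Records the generator's true parameters next to a simulated data set as
#' `key=value` lines, so downstream estimates can be checked against
#' truth.
#'
#' @param params A [sim_params()] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_truth_sidecar <- function(params, path) {
  keys <- c("m", "h", "e", "S", "d", "d_hemi_factor", "lambda0", "kappa",
            "sigma", "n_cells", "n_wells", "seed")
  lines <- vapply(keys, function(k) {
    v <- params[[k]]
    sprintf("%s=%s", k, if (is.null(v)) "NA" else format(v, digits = 17))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a simulation ground-truth sidecar
#'
#' @param path Path written by [write_truth_sidecar()].
#' @return A named list of numeric parameter values (`seed` may be `NA`).
#' @export
read_truth_sidecar <- function(path) {
  lines <- readLines(path)
  kv <- strsplit(lines, "=", fixed = TRUE)
  vals <- lapply(kv, function(x) suppressWarnings(as.numeric(x[2L])))
  stats::setNames(vals, vapply(kv, `[[`, character(1), 1L))
}
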