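#' Cell-level quantification constants
#'
#' @param cell_mass dry mass per cell, pg (default 13, the reference-condition
#'   measurement).
#' @param protein_content named vector of protein per cell, pg, one entry per
#'   condition (may be a single unnamed value).
#' @return a `quant_params` list.
#' @export
quant_params <- function(cell_mass = 13, protein_content = NULL) {
  stopifnot(cell_mass > 0)
  if (!is.null(protein_content) && any(protein_content <= 0)) {
    stop("protein_content must be positive")
  }
  structure(
    list(cell_mass = cell_mass, protein_content = protein_content),
    class = "quant_params"
  )
}

#' Count theoretically observable peptides
#'
#' In-silico digestion of a protein sequence: LysC cleaves after K, trypsin
#' after K or R except before proline. Returns the number of cleavage
#' products whose length falls in the closed `length_range` - the
#' denominator of the iBAQ intensity.
#'
#' @param protein_sequence amino-acid string (20-letter alphabet).
#' @param protease `"LysC"` or `"Trypsin"`.
#' @param length_range closed length window, default `c(7, 30)`.
#' @param missed_cleavages number of allowed missed cleavages (default 0).
#' @return integer count of observable peptides.
#' @export
count_observable_peptides <- function(protein_sequence,
                                      protease = c("LysC", "Trypsin"),
                                      length_range = c(7, 30),
                                      missed_cleavages = 0) {
  protease <- match.arg(protease)
  aa <- strsplit(toupper(protein_sequence), "")[[1]]
  valid <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  bad <- which(!aa %in% valid)
  if (length(bad)) {
    stop("invalid residue '", aa[bad[1]], "' at position ", bad[1])
  }
  n <- length(aa)
  cut_after <- if (protease == "LysC") {
    which(aa == "K")
  } else {
    which(aa %in% c("K", "R") & c(aa[-1], "") != "P")
  }
  cut_after <- cut_after[cut_after < n]
  starts <- c(1, cut_after + 1)
  ends <- c(cut_after, n)
  lens <- integer(0)
  for (mc in 0:missed_cleavages) {
    idx <- seq_len(length(starts) - mc)
    lens <- c(lens, ends[idx + mc] - starts[idx] + 1)
  }
  sum(lens >= length_range[1] & lens <= length_range[2])
}

#' iBAQ intensity
#'
#' Intensity divided by the number of theoretically observable peptides.
#'
#' @param intensity non-negative summed precursor intensity.
#' @param n_observable observable-peptide count (>= 1).
#' @return the iBAQ value.
#' @export
ibaq <- function(intensity, n_observable) {
  if (any(n_observable < 1)) {
    stop("iBAQ undefined: protein has no observable peptides")
  }
  if (any(intensity < 0)) stop("intensity must be non-negative")
  intensity / n_observable
}

#' Fit the spike-in absolute-quantification calibration
#'
#' Ordinary least squares of log known amount on log signal (both already
#' log-transformed by the caller, conventionally log10): the prediction
#' direction used to translate iBAQ intensities of unknown proteins into
#' absolute amounts.
#'
#' @param log_signal log-transformed signals of the calibrant proteins.
#' @param log_known_amount log-transformed known amounts.
#' @return a `calibration_fit`: list with `slope`, `intercept`, `r` (Pearson
#'   correlation), `n_calibrants`, `domain` (range of the predictor).
#' @export
fit_absolute_calibration <- function(log_signal, log_known_amount) {
  if (length(log_signal) != length(log_known_amount)) {
    stop("calibrant vectors must have equal length")
  }
  if (length(log_signal) < 3) stop("need at least 3 calibrants")
  if (any(!is.finite(log_signal)) || any(!is.finite(log_known_amount))) {
    stop("calibrant values must be finite")
  }
  if (stats::sd(log_signal) == 0) {
    stop("degenerate calibration: zero predictor variance")
  }
  fit <- stats::lm(log_known_amount ~ log_signal)
  r <- stats::cor(log_signal, log_known_amount)
  if (r < 0) warning("calibration is anti-correlated (r = ", signif(r, 3), ")")
  structure(
    list(
      slope = unname(stats::coef(fit)[2]),
      intercept = unname(stats::coef(fit)[1]),
      r = r,
      n_calibrants = length(log_signal),
      domain = range(log_signal)
    ),
    class = "calibration_fit"
  )
}

#' Predict from a calibration fit
#'
#' @param fit a `calibration_fit`.
#' @param log_signal new predictor values (log scale). Values outside the
#'   calibrant domain are extrapolated with a warning.
#' @return predicted log amounts.
#' @export
predict_calibration <- function(fit, log_signal) {
  outside <- log_signal < fit$domain[1] | log_signal > fit$domain[2]
  if (any(outside)) {
    warning(
      sum(outside), " value(s) outside the calibrant domain [",
      signif(fit$domain[1], 4), ", ", signif(fit$domain[2], 4),
      "]; extrapolating"
    )
  }
  fit$intercept + fit$slope * log_signal
}

#' Convert relative protein amounts to copies per cell
#'
#' Interprets the table as mass fractions of total protein per condition and
#' converts via `copies = fraction * protein_content / MW * Avogadro`.
#'
#' @param relative_amounts [omics_table()] of per-condition mass fractions.
#' @param params [quant_params()] with one `protein_content` entry (pg/cell)
#'   per condition.
#' @param molecular_weights named vector, entity -> molecular weight in kDa.
#'   Entities without a weight are skipped with a warning.
#' @return [omics_table()] in copies per cell.
#' @export
to_copies_per_cell <- function(relative_amounts, params, molecular_weights) {
  stopifnot(inherits(relative_amounts, "omics_table"))
  vals <- relative_amounts$values
  pc <- params$protein_content
  if (is.null(pc)) stop("quant_params must carry protein_content")
  if (length(pc) == 1 && is.null(names(pc))) {
    pc <- stats::setNames(rep(pc, ncol(vals)), colnames(vals))
  }
  if (!all(colnames(vals) %in% names(pc))) {
    stop("protein_content missing for some conditions")
  }
  have_mw <- rownames(vals) %in% names(molecular_weights)
  if (!all(have_mw)) {
    warning(
      sum(!have_mw), " entities skipped: no molecular weight supplied"
    )
    vals <- vals[have_mw, , drop = FALSE]
  }
  mw_g_per_mol <- molecular_weights[rownames(vals)] * 1000
  copies <- sweep(vals, 2, pc[colnames(vals)] * 1e-12 * AVOGADRO, `*`) /
    mw_g_per_mol
  omics_table(copies, unit = "copies_per_cell")
}

#' Median-center log H/L ratios
#'
#' Shifts peptide log heavy/light ratios so their median is exactly zero,
#' correcting 1:1 mixing deviations of the spike-in standard.
#'
#' @param peptide_log_ratios numeric vector of finite log ratios.
#' @return the centered vector (order preserved).
#' @export
normalize_hl <- function(peptide_log_ratios) {
  if (!length(peptide_log_ratios)) stop("empty ratio vector")
  if (any(!is.finite(peptide_log_ratios))) stop("log ratios must be finite")
  peptide_log_ratios - stats::median(peptide_log_ratios)
}

#' Protein ratio from peptide ratios
#'
#' Median of a protein's normalized peptide log ratios; at least one peptide
#' measurement is required.
#'
#' @param peptide_log_ratios normalized log ratios of one protein's peptides.
#' @return the protein-level log ratio.
#' @export
protein_ratio <- function(peptide_log_ratios) {
  if (!length(peptide_log_ratios)) {
    stop("at least one peptide ratio is required")
  }
  stats::median(peptide_log_ratios)
}

#' Calibrate FPKM to absolute mRNA copies per cell
#'
#' Fits a log-log regression of molecules per cell on FPKM over spike-in
#' calibrants measured at the reference condition, converts all reference
#' FPKM values to absolute copies, and propagates to the other conditions by
#' the supplied fold-changes.
#'
#' @param fpkm_reference named vector of FPKM values at the reference
#'   condition.
#' @param calibrants data frame with columns `fpkm`, `molecules_per_cell`
#'   (>= 3 rows); zero-FPKM calibrants are excluded with a warning.
#' @param fold_changes [omics_table()] in `relative_to_reference` units over
#'   the genes and conditions to emit.
#' @return [omics_table()] of mRNA copies per cell.
#' @export
fpkm_to_absolute <- function(fpkm_reference, calibrants, fold_changes) {
  stopifnot(inherits(fold_changes, "omics_table"))
  if (fold_changes$unit != "relative_to_reference") {
    stop("fold_changes must be relative_to_reference")
  }
  keep <- calibrants$fpkm > 0
  if (any(!keep)) {
    warning(sum(!keep), " calibrant(s) with zero FPKM excluded")
    calibrants <- calibrants[keep, , drop = FALSE]
  }
  fit <- fit_absolute_calibration(
    log10(calibrants$fpkm), log10(calibrants$molecules_per_cell)
  )
  genes <- intersect(rownames(fold_changes$values), names(fpkm_reference))
  ref_abs <- 10^(fit$intercept + fit$slope * log10(fpkm_reference[genes]))
  vals <- fold_changes$values[genes, , drop = FALSE] * ref_abs
  omics_table(vals, unit = "copies_per_cell")
}

#' Median-normalize intensities across conditions
#'
#' Rescales each condition so its median intensity equals the global median
#' of the per-condition medians; within-condition ratios are preserved. The
#' operation is idempotent.
#'
#' @param intensities [omics_table()] of positive intensities.
#' @return the normalized [omics_table()].
#' @export
median_normalize <- function(intensities) {
  stopifnot(inherits(intensities, "omics_table"))
  vals <- intensities$values
  med <- apply(vals, 2, stats::median, na.rm = TRUE)
  if (any(med == 0)) {
    stop(
      "all-zero (zero-median) condition: ",
      colnames(vals)[which(med == 0)[1]]
    )
  }
  target <- stats::median(med)
  out <- sweep(vals, 2, target / med, `*`)
  omics_table(out,
    unit = intensities$unit,
    reference_condition = intensities$reference_condition
  )
}
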