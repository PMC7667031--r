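#' Intensity-based absolute quantification (iBAQ)
#'
#' iBAQ of a protein is the sum of its detected peptide intensities divided by
#' its number of theoretically observable peptides. Proteins with no detected
#' peptides are absent from the output, not zero.
#'
#' @param peptides data.frame with columns `protein_id`, `intensity` (one row
#'   per detected peptide; technical replicates should be averaged upstream).
#' @param annotation annotation data.frame carrying `gene_id` and
#'   `n_theoretical_peptides`.
#' @param sample_id column name for the single output sample.
#' @return `AbundanceMatrix` (protein layer, signal units) with one column.
#' @export
compute_ibaq <- function(peptides, annotation, sample_id = "pooled_reference") {
  stopifnot(all(c("protein_id", "intensity") %in% names(peptides)))
  missing <- setdiff(unique(peptides$protein_id), annotation$gene_id)
  if (length(missing))
    stop(sprintf("proteins missing from annotation: %s",
                 paste(utils::head(missing, 5), collapse = ", ")),
         call. = FALSE)
  sums <- tapply(peptides$intensity, peptides$protein_id, sum)
  npep <- annotation$n_theoretical_peptides[match(names(sums),
                                                  annotation$gene_id)]
  if (any(npep < 1)) stop("n_theoretical_peptides must be >= 1", call. = FALSE)
  vals <- matrix(as.numeric(sums) / npep, ncol = 1,
                 dimnames = list(names(sums), sample_id))
  abundance_matrix(vals, "protein", "signal")
}

#' Filter spike-in standards on detection quality
#'
#' Retains standards detected with at least `min_unique_peptides` unique
#' peptides and strictly positive measured signal, preserving row order.
#'
#' @param spike data.frame with columns `standard_id`, `known_concentration`,
#'   `measured_signal`, `n_unique_peptides`.
#' @param min_unique_peptides detection threshold (default 2, the usual
#'   two-or-more-unique-peptides rule).
#' @return the filtered data.frame.
#' @export
filter_standards <- function(spike, min_unique_peptides = 2L) {
  if (!"n_unique_peptides" %in% names(spike))
    stop("spike-in table lacks n_unique_peptides", call. = FALSE)
  keep <- spike$n_unique_peptides >= min_unique_peptides &
    spike$measured_signal > 0
  out <- spike[keep, , drop = FALSE]
  if (nrow(out) == 0L)
    stop("no standards survive filtering; calibration impossible",
         call. = FALSE)
  rownames(out) <- NULL
  out
}

#' Fit a log-log calibration curve from spike-in standards
#'
#' Ordinary least squares of `log10(known_concentration)` on
#' `log10(measured_signal)`. Both axes span orders of magnitude, so the fit is
#' done in log10-log10 space; linear-space OLS would be dominated by the
#' largest standards.
#'
#' @param spike data.frame with `known_concentration` (> 0) and
#'   `measured_signal` (> 0) columns; rows with nonpositive signal are dropped.
#' @return object of class `CalibrationCurve`: slope, intercept, r_squared,
#'   n_points, space = "log10-log10".
#' @export
fit_calibration <- function(spike) {
  use <- spike$measured_signal > 0 & spike$known_concentration > 0
  x <- log10(spike$measured_signal[use])
  y <- log10(spike$known_concentration[use])
  if (length(x) < 2L)
    stop("need >= 2 usable standards; calibration impossible", call. = FALSE)
  if (stats::var(x) == 0)
    stop("zero variance in measured signal; degenerate fit", call. = FALSE)
  fit <- stats::lm(y ~ x)
  ss_tot <- sum((y - mean(y)) ^ 2)
  r2 <- if (ss_tot == 0) 1 else
    max(0, min(1, 1 - sum(stats::residuals(fit) ^ 2) / ss_tot))
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = r2,
                 n_points = length(x),
                 space = "log10-log10"),
            class = "CalibrationCurve")
}

#' @export
print.CalibrationCurve <- function(x, ...) {
  cat(sprintf("CalibrationCurve (%s): slope=%.4f intercept=%.4f R2=%.3f n=%d\n",
              x$space, x$slope, x$intercept, x$r_squared, x$n_points))
  invisible(x)
}

#' Apply a calibration curve to a signal matrix
#'
#' Elementwise `10^(slope * log10(signal) + intercept)`. Zero or missing
#' signals become `NA` (undetected stays undetected; log-space calibration is
#' undefined at zero), never infinity or an invented value.
#'
#' @param curve a `CalibrationCurve`.
#' @param signals `AbundanceMatrix` in signal units.
#' @return `AbundanceMatrix` with the same layer, units `arbitrary_absolute`
#'   (the scale is fixed by the standards the curve was fitted on).
#' @export
apply_calibration <- function(curve, signals) {
  stopifnot(inherits(curve, "CalibrationCurve"))
  if (!inherits(signals, "AbundanceMatrix") || signals$units != "signal")
    stop("apply_calibration expects an AbundanceMatrix in signal units",
         call. = FALSE)
  v <- ab_values(signals)
  v[!is.na(v) & v == 0] <- NA_real_
  out <- 10 ^ (curve$slope * log10(v) + curve$intercept)
  abundance_matrix(out, layer = signals$layer, units = "arbitrary_absolute")
}

#' Propagate pooled-reference absolute values through TMT ratios
#'
#' `absolute(protein, sample) = reference(protein) * ratio(protein, sample)`.
#' Proteins absent from the reference are absent from the output; a missing
#' ratio yields a missing absolute value.
#'
#' @param reference_absolute single-column `AbundanceMatrix` of absolute
#'   pooled-reference abundances.
#' @param tmt_ratios numeric matrix (proteins x samples) of sample/reference
#'   ratios, rownames aligned with reference proteins.
#' @return `AbundanceMatrix` (protein layer, same units as the reference).
#' @export
propagate_tmt <- function(reference_absolute, tmt_ratios) {
  stopifnot(inherits(reference_absolute, "AbundanceMatrix"))
  if (ncol(ab_values(reference_absolute)) != 1L)
    stop("reference must be a single-sample matrix", call. = FALSE)
  if (any(tmt_ratios < 0, na.rm = TRUE))
    stop("TMT ratios must be >= 0", call. = FALSE)
  ref <- ab_values(reference_absolute)[, 1]
  common <- intersect(names(ref), rownames(tmt_ratios))
  if (length(common) == 0L) {
    offenders <- utils::head(setdiff(names(ref), rownames(tmt_ratios)), 5)
    stop(sprintf("no proteins shared between reference and ratios (e.g. %s)",
                 paste(offenders, collapse = ", ")), call. = FALSE)
  }
  out <- tmt_ratios[common, , drop = FALSE] * ref[common]
  abundance_matrix(out, layer = "protein",
                   units = reference_absolute$units)
}

#' Calibrate both omics layers end to end
#'
#' Convenience wrapper for the quantification stage: fits the mRNA
#' calibration from its standards and applies it to the signal matrix; runs
#' iBAQ on the pooled-reference peptides, filters and fits the UPS2-style
#' standards, calibrates the reference, and propagates it through the TMT
#' ratios.
#'
#' @param mrna_signal `AbundanceMatrix` (mRNA, signal).
#' @param mrna_standards spike-in data.frame for the mRNA layer.
#' @param peptides pooled-reference peptide table.
#' @param ups2 UPS2-style spike-in table with `n_unique_peptides`.
#' @param tmt_ratios proteins x samples ratio matrix.
#' @param annotation annotation data.frame.
#' @param min_unique_peptides detection filter threshold for protein standards.
#' @return list: `mrna_absolute`, `protein_absolute` (AbundanceMatrix),
#'   `mrna_curve`, `protein_curve` (CalibrationCurve),
#'   `reference_absolute`.
#' @export
quantify_absolute <- function(mrna_signal, mrna_standards,
                              peptides, ups2, tmt_ratios, annotation,
                              min_unique_peptides = 2L) {
  mrna_curve <- fit_calibration(mrna_standards)
  mrna_abs <- apply_calibration(mrna_curve, mrna_signal)

  ibaq <- compute_ibaq(peptides, annotation)
  kept <- filter_standards(ups2, min_unique_peptides)
  protein_curve <- fit_calibration(kept)
  ref_abs <- apply_calibration(protein_curve, ibaq)
  protein_abs <- propagate_tmt(ref_abs, tmt_ratios)

  list(mrna_absolute = mrna_abs, protein_absolute = protein_abs,
       mrna_curve = mrna_curve, protein_curve = protein_curve,
       reference_absolute = ref_abs)
}
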