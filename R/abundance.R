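#' Gene-by-sample abundance matrix with layer and unit tags
#'
#' The central quantitative container of the package: a non-negative numeric
#' matrix (genes in rows, samples in columns) tagged with the omics layer it
#' carries and the units its values are expressed in. Missing observations are
#' `NA` -- a gene undetected in a sample is missing, never zero, because the
#' calibration machinery works in log space.
#'
#' @param values numeric matrix with gene ids as rownames and sample ids as
#'   colnames. Negative finite values are rejected; `NA` marks missingness.
#' @param layer one of `"mRNA"`, `"protein"`.
#' @param units one of `"signal"` (FPKM-like or iBAQ-like, uncalibrated),
#'   `"molecules_per_cell"`, `"fmol"`, `"arbitrary_absolute"` (calibrated via a
#'   spike-in curve whose standards fix the unit), or `"mmol_per_gdcw"` (model
#'   enzyme-usage units).
#' @return an object of class `AbundanceMatrix`.
#' @export
abundance_matrix <- function(values,
                             layer = c("mRNA", "protein"),
                             units = c("signal", "molecules_per_cell", "fmol",
                                       "arbitrary_absolute", "mmol_per_gdcw")) {
  layer <- match.arg(layer)
  units <- match.arg(units)
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix", call. = FALSE)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("'values' must carry gene ids as rownames and sample ids as colnames",
         call. = FALSE)
  if (anyDuplicated(rownames(values)) || anyDuplicated(colnames(values)))
    stop("gene and sample ids must be unique", call. = FALSE)
  if (any(values < 0, na.rm = TRUE))
    stop("abundances must be non-negative (use NA for missing values)",
         call. = FALSE)
  structure(list(values = values, layer = layer, units = units),
            class = "AbundanceMatrix")
}

#' @export
print.AbundanceMatrix <- function(x, ...) {
  cat(sprintf("AbundanceMatrix: %d genes x %d samples [layer=%s, units=%s]\n",
              nrow(x$values), ncol(x$values), x$layer, x$units))
  cat(sprintf("  %.1f%% missing\n", 100 * mean(is.na(x$values))))
  invisible(x)
}

#' @rdname abundance_matrix
#' @param x an `AbundanceMatrix`.
#' @export
ab_values <- function(x) {
  stopifnot(inherits(x, "AbundanceMatrix"))
  x$values
}

#' @rdname abundance_matrix
#' @export
ab_genes <- function(x) rownames(ab_values(x))

#' @rdname abundance_matrix
#' @export
ab_samples <- function(x) colnames(ab_values(x))

#' @export
dim.AbundanceMatrix <- function(x) dim(x$values)
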