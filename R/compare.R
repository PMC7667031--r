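#' Protein-mRNA correlation within a sample
#'
#' Gene level: squared Pearson correlation of log10 absolute abundances over
#' the genes quantified in both layers ("protein-transcript pairs"); the log
#' transform is essential for abundances spanning orders of magnitude.
#' Process level: squared Pearson correlation of untransformed process
#' fractions across processes.
#'
#' @param protein,mrna gene level: `AbundanceMatrix` objects in absolute
#'   units; process level: `ProcessFractionTable` objects.
#' @param sample sample id present in both layers.
#' @param level `"gene"` or `"process"`.
#' @return object of class `CorrelationResult`: r_squared, n_pairs, level,
#'   transform.
#' @export
correlate_layers <- function(protein, mrna, sample,
                             level = c("gene", "process")) {
  level <- match.arg(level)
  if (level == "gene") {
    stopifnot(inherits(protein, "AbundanceMatrix"),
              inherits(mrna, "AbundanceMatrix"))
    p <- ab_values(protein)[, sample]
    m <- ab_values(mrna)[, sample]
    common <- intersect(names(p)[!is.na(p) & p > 0],
                        names(m)[!is.na(m) & m > 0])
    x <- log10(m[common]); y <- log10(p[common])
    transform <- "log10"
  } else {
    stopifnot(inherits(protein, "ProcessFractionTable"),
              inherits(mrna, "ProcessFractionTable"))
    common <- intersect(rownames(protein$fractions), rownames(mrna$fractions))
    x <- mrna$fractions[common, sample]
    y <- protein$fractions[common, sample]
    transform <- "none"
  }
  if (length(common) < 3L)
    stop(sprintf("only %d common pairs; need >= 3", length(common)),
         call. = FALSE)
  if (stats::var(x) == 0 || stats::var(y) == 0)
    stop("zero variance in one layer; correlation degenerate", call. = FALSE)
  structure(list(r_squared = stats::cor(x, y) ^ 2,
                 n_pairs = length(common),
                 level = level, transform = transform, sample = sample),
            class = "CorrelationResult")
}

#' @export
print.CorrelationResult <- function(x, ...) {
  cat(sprintf("CorrelationResult [%s, %s]: R2=%.3f over %d pairs (%s)\n",
              x$level, x$sample, x$r_squared, x$n_pairs, x$transform))
  invisible(x)
}

#' Translation propensity (P/T)
#'
#' Elementwise ratio of absolute protein to absolute mRNA abundance over the
#' intersection of genes and samples quantified in both layers. Missing or
#' zero mRNA yields a missing ratio, never an exception or infinity.
#'
#' @param protein,mrna `AbundanceMatrix` objects in absolute units.
#' @return object of class `PropensityTable`: `values` (gene x sample matrix
#'   of P/T ratios), `samples`.
#' @export
translation_propensity <- function(protein, mrna) {
  stopifnot(inherits(protein, "AbundanceMatrix"),
            inherits(mrna, "AbundanceMatrix"))
  genes <- intersect(ab_genes(protein), ab_genes(mrna))
  samples <- intersect(ab_samples(protein), ab_samples(mrna))
  if (length(genes) == 0L)
    stop("protein and mRNA layers share no genes", call. = FALSE)
  p <- ab_values(protein)[genes, samples, drop = FALSE]
  m <- ab_values(mrna)[genes, samples, drop = FALSE]
  m[!is.na(m) & m == 0] <- NA_real_
  structure(list(values = p / m, samples = samples),
            class = "PropensityTable")
}

#' @export
print.PropensityTable <- function(x, ...) {
  cat(sprintf("PropensityTable: %d genes x %d samples\n",
              nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Percent change in translation propensity between two strains
#'
#' `100 * (mean_b - mean_a) / mean_a` over replicate samples of each strain at
#' the given dilution rate; strain_a is the reference.
#'
#' @param prop a `PropensityTable`.
#' @param gene gene id.
#' @param design `ExperimentDesign` mapping samples to strain x rate.
#' @param strain_a,strain_b strain names (reference first).
#' @param rate dilution rate.
#' @return percent change (scalar).
#' @export
compare_propensity <- function(prop, gene, design, strain_a, strain_b, rate) {
  stopifnot(inherits(prop, "PropensityTable"))
  if (!gene %in% rownames(prop$values))
    stop(sprintf("gene '%s' absent from propensity table", gene),
         call. = FALSE)
  pick <- function(strain) {
    s <- design$samples$sample_id[design$samples$strain == strain &
                                    design$samples$dilution_rate == rate]
    s <- intersect(s, colnames(prop$values))
    v <- prop$values[gene, s]
    v <- v[!is.na(v)]
    if (length(v) == 0L)
      stop(sprintf("gene '%s' has no defined P/T in %s at %g/h",
                   gene, strain, rate), call. = FALSE)
    v
  }
  a <- pick(strain_a); b <- pick(strain_b)
  100 * (mean(b) - mean(a)) / mean(a)
}
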