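#' Allocate absolute abundances to bioprocess gene sets as fractions
#'
#' For each process and sample, the molar fraction is the summed abundance of
#' member genes divided by the total abundance over all quantified genes; the
#' mass fraction weights each gene by its molecular weight (kDa) first.
#' A gene belonging to several processes contributes fully to each (GO-Slim
#' mapping is many-to-many), while the denominator always covers every
#' quantified gene -- so fractions may sum above 1 across an overlapping
#' ontology, and genes with no membership contribute to denominators only.
#'
#' @param abundances `AbundanceMatrix` in absolute units; `NA` entries
#'   (undetected) are excluded from numerators and denominators.
#' @param annotation annotation data.frame (needs `mol_weight` in mass mode).
#' @param gene_sets either an `Ontology` (memberships taken from the
#'   annotation) or a named list of gene-id vectors (GMT-style custom sets,
#'   e.g. secretory-pathway subsystems).
#' @param mode `"molar"` (mol/mol) or `"mass"` (g/g).
#' @return object of class `ProcessFractionTable`: `fractions` (process x
#'   sample matrix), `mode`, `layer`.
#' @export
allocate <- function(abundances, annotation, gene_sets,
                     mode = c("molar", "mass")) {
  mode <- match.arg(mode)
  stopifnot(inherits(abundances, "AbundanceMatrix"))
  a <- ab_values(abundances)

  if (inherits(gene_sets, "Ontology")) {
    sets <- process_members(annotation, gene_sets)
  } else {
    sets <- gene_sets
    if (is.null(names(sets))) stop("gene sets must be named", call. = FALSE)
  }

  if (mode == "mass") {
    mw <- annotation$mol_weight[match(rownames(a), annotation$gene_id)]
    if (anyNA(mw))
      stop("mass mode needs mol_weight for every quantified gene",
           call. = FALSE)
    a <- a * mw
  }

  totals <- colSums(a, na.rm = TRUE)
  if (any(totals == 0))
    stop(sprintf("sample(s) with zero total abundance: %s",
                 paste(colnames(a)[totals == 0], collapse = ", ")),
         call. = FALSE)

  frac <- matrix(0, length(sets), ncol(a),
                 dimnames = list(names(sets), colnames(a)))
  for (i in seq_along(sets)) {
    idx <- match(intersect(sets[[i]], rownames(a)), rownames(a))
    if (length(idx))
      frac[i, ] <- colSums(a[idx, , drop = FALSE], na.rm = TRUE) / totals
  }

  structure(list(fractions = frac, mode = mode, layer = abundances$layer),
            class = "ProcessFractionTable")
}

#' @export
print.ProcessFractionTable <- function(x, ...) {
  cat(sprintf("ProcessFractionTable: %d processes x %d samples [%s, %s]\n",
              nrow(x$fractions), ncol(x$fractions), x$layer,
              if (x$mode == "molar") "mol/mol" else "g/g"))
  invisible(x)
}

pooled_t_test <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) / (na + nb - 2)
  se <- sqrt(sp2 * (1 / na + 1 / nb))
  tstat <- if (se == 0) {
    if (mean(b) == mean(a)) 0 else sign(mean(b) - mean(a)) * Inf
  } else (mean(b) - mean(a)) / se
  p <- 2 * stats::pt(-abs(tstat), df = na + nb - 2)
  c(t = tstat, p = p)
}

#' Differential testing of processes or genes between two sample groups
#'
#' Two-tailed pooled-variance Student's t-test per row, with
#' `log2FC = log2(mean_b / mean_a)`. By convention `group_a` is the reference
#' (the reference strain at the matched dilution rate). P-values are reported
#' raw (no multiple-testing correction) to follow the plain `P < alpha` call;
#' set `adjust = "BH"` for Benjamini-Hochberg control instead.
#'
#' @param values matrix of replicate measurements (units x samples): process
#'   fractions, or absolute abundances for gene-level tests. A
#'   `ProcessFractionTable` or `AbundanceMatrix` is also accepted.
#' @param group_a,group_b disjoint character vectors of sample ids, >= 2 each.
#' @param alpha significance threshold (default 0.05).
#' @param adjust `"none"` (default) or any method of [stats::p.adjust()].
#' @return data.frame of class `DiffTable`: unit_id, log2_fold_change,
#'   t_statistic, p_value, significant. A nonpositive group mean leaves
#'   log2_fold_change `NA` (undefined), the test still reported.
#' @export
diff_units <- function(values, group_a, group_b, alpha = 0.05,
                       adjust = "none") {
  if (inherits(values, "ProcessFractionTable")) values <- values$fractions
  if (inherits(values, "AbundanceMatrix")) values <- ab_values(values)
  if (length(intersect(group_a, group_b)))
    stop("groups must be disjoint", call. = FALSE)
  if (length(group_a) < 2L || length(group_b) < 2L)
    stop("need >= 2 replicates per group", call. = FALSE)
  missing <- setdiff(c(group_a, group_b), colnames(values))
  if (length(missing))
    stop(sprintf("unknown samples: %s", paste(missing, collapse = ", ")),
         call. = FALSE)

  A <- values[, group_a, drop = FALSE]
  B <- values[, group_b, drop = FALSE]
  res <- t(vapply(seq_len(nrow(values)), function(i) {
    tp <- pooled_t_test(A[i, ], B[i, ])
    ma <- mean(A[i, ]); mb <- mean(B[i, ])
    lfc <- if (ma > 0 && mb > 0) log2(mb / ma) else NA_real_
    c(lfc, tp[["t"]], tp[["p"]])
  }, numeric(3)))
  p <- stats::p.adjust(res[, 3], method = adjust)
  out <- data.frame(unit_id = rownames(values),
                    log2_fold_change = res[, 1],
                    t_statistic = res[, 2],
                    p_value = p,
                    significant = p < alpha,
                    stringsAsFactors = FALSE)
  class(out) <- c("DiffTable", "data.frame")
  attr(out, "alpha") <- alpha
  out
}

#' Summarize a differential table
#'
#' @param diff a `DiffTable` from [diff_units()].
#' @return list: `n_significant`, `min_log2fc`, `max_log2fc` (range over
#'   significant rows only; `NA` when nothing is significant).
#' @export
count_differential <- function(diff) {
  if (nrow(diff) == 0L) stop("empty differential table", call. = FALSE)
  sig <- diff[diff$significant & !is.na(diff$log2_fold_change), , drop = FALSE]
  if (nrow(sig) == 0L)
    return(list(n_significant = sum(diff$significant),
                min_log2fc = NA_real_, max_log2fc = NA_real_))
  list(n_significant = sum(diff$significant),
       min_log2fc = min(sig$log2_fold_change),
       max_log2fc = max(sig$log2_fold_change))
}
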