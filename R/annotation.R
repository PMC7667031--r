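#' Bioprocess ontology
#'
#' A flat vocabulary of biological-process identifiers used as gene sets for
#' resource allocation (the role the 99-term yeast GO-Slim bioprocess mapper
#' plays for real data), plus optional named collections of process subsets
#' such as a simplified secretory pathway.
#'
#' @param process_ids character vector of unique process identifiers.
#' @param collections optional named list; each element is a character vector
#'   of process ids forming a named subset (e.g. 8 secretory subsystems).
#' @return an object of class `Ontology`.
#' @export
ontology <- function(process_ids, collections = list()) {
  process_ids <- as.character(process_ids)
  if (length(process_ids) < 1L) stop("ontology needs >= 1 process", call. = FALSE)
  if (anyDuplicated(process_ids)) stop("process ids must be unique", call. = FALSE)
  for (nm in names(collections)) {
    bad <- setdiff(collections[[nm]], process_ids)
    if (length(bad))
      stop(sprintf("collection '%s' references unknown processes: %s",
                   nm, paste(bad, collapse = ", ")), call. = FALSE)
  }
  structure(list(process_ids = process_ids, collections = collections),
            class = "Ontology")
}

#' @export
print.Ontology <- function(x, ...) {
  cat(sprintf("Ontology: %d processes, %d collections\n",
              length(x$process_ids), length(x$collections)))
  invisible(x)
}

#' Generate a synthetic gene annotation and ontology
#'
#' Emits per-gene records (molecular weight, theoretically observable peptide
#' count, process memberships) over a fresh ontology. Memberships are
#' many-to-many as in GO-Slim: each gene belongs to a Poisson-distributed
#' number of processes (possibly zero).
#'
#' Molecular weights are log-uniform on 10--200 kDa; theoretical peptide
#' counts scale with protein size (roughly one observable tryptic peptide per
#' 2 kDa), with a floor of 1.
#'
#' @param n_genes number of genes (>= 1).
#' @param ontology_size number of processes (>= 1); 99 mirrors the yeast
#'   GO-Slim bioprocess vocabulary.
#' @param membership_rate mean number of process memberships per gene.
#' @param seed integer seed; identical arguments give identical output.
#' @return a list with elements `annotation` (data.frame with columns
#'   `gene_id`, `mol_weight` (kDa), `n_theoretical_peptides`, `processes`
#'   (semicolon-separated process ids, possibly empty)) and `ontology`.
#' @export
generate_annotation <- function(n_genes, ontology_size = 99L,
                                membership_rate = 1.5, seed = 1L) {
  if (!is.numeric(n_genes) || n_genes < 1)
    stop("'n_genes' must be >= 1", call. = FALSE)
  if (!is.numeric(ontology_size) || ontology_size < 1)
    stop("'ontology_size' must be >= 1", call. = FALSE)
  n_genes <- as.integer(n_genes)
  ontology_size <- as.integer(ontology_size)
  withr::local_seed(seed)

  process_ids <- sprintf("bp%03d", seq_len(ontology_size))
  gene_id <- sprintf("g%05d", seq_len(n_genes))
  mol_weight <- 10 ^ stats::runif(n_genes, log10(10), log10(200))
  n_pep <- pmax(1L, stats::rpois(n_genes, mol_weight / 2))

  k <- pmin(stats::rpois(n_genes, membership_rate), ontology_size)
  processes <- vapply(k, function(ki) {
    if (ki == 0L) "" else paste(sort(sample(process_ids, ki)), collapse = ";")
  }, character(1))

  annotation <- data.frame(gene_id = gene_id,
                           mol_weight = mol_weight,
                           n_theoretical_peptides = n_pep,
                           processes = processes,
                           stringsAsFactors = FALSE)
  list(annotation = annotation, ontology = ontology(process_ids))
}

#' Per-gene process membership as a named list
#'
#' @param annotation annotation data.frame as produced by
#'   [generate_annotation()] or read from TSV.
#' @return named list mapping gene_id to a character vector of process ids
#'   (zero-length for unassigned genes).
#' @export
process_sets <- function(annotation) {
  out <- strsplit(annotation$processes, ";", fixed = TRUE)
  out <- lapply(out, function(p) p[nzchar(p)])
  names(out) <- annotation$gene_id
  out
}

#' Invert gene->process membership into process->gene sets
#'
#' @inheritParams process_sets
#' @param ontology an `Ontology`; processes with no member genes map to
#'   zero-length sets.
#' @return named list mapping process_id to member gene ids.
#' @export
process_members <- function(annotation, ontology) {
  ps <- process_sets(annotation)
  genes <- rep(names(ps), lengths(ps))
  procs <- unlist(ps, use.names = FALSE)
  out <- split(genes, factor(procs, levels = ontology$process_ids))
  lapply(out, as.character)
}
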