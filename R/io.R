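#' Tabular readers and writers
#'
#' Plain TSV/CSV interchange for every stage: gene annotation, gene x sample
#' matrices (columns named `strain_rate_replicate`), spike-in standards,
#' peptide intensities, GMT-style gene sets, differential tables, and a
#' versioned JSON schema for toy networks.
#'
#' @param annotation annotation data.frame.
#' @param path file path.
#' @name omniflux-io
NULL

#' @rdname omniflux-io
#' @export
write_annotation_tsv <- function(annotation, path) {
  utils::write.table(annotation, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname omniflux-io
#' @export
read_annotation_tsv <- function(path) {
  out <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = c(processes = "character"))
  out$processes[is.na(out$processes)] <- ""
  out
}

#' @rdname omniflux-io
#' @param x `AbundanceMatrix` or plain matrix (genes x samples).
#' @param id_col name of the leading identifier column.
#' @export
write_matrix_tsv <- function(x, path, id_col = "gene_id") {
  m <- if (inherits(x, "AbundanceMatrix")) ab_values(x) else x
  df <- data.frame(rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- id_col
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname omniflux-io
#' @param layer,units tags to attach when reading into an `AbundanceMatrix`;
#'   `NULL` returns the bare matrix.
#' @export
read_matrix_tsv <- function(path, layer = NULL, units = NULL) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  if (is.null(layer)) return(m)
  abundance_matrix(m, layer, units)
}

#' @rdname omniflux-io
#' @param spike spike-in data.frame.
#' @export
write_spikein_tsv <- function(spike, path) {
  utils::write.table(spike, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname omniflux-io
#' @export
read_spikein_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' @rdname omniflux-io
#' @export
read_peptides_tsv <- function(path) {
  out <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("protein_id", "intensity") %in% names(out)))
  out
}

#' @rdname omniflux-io
#' @description `read_gmt`/`write_gmt` handle gene-set files with one set per
#'   line: set id, description, then member gene ids, tab-separated (used for
#'   custom collections such as secretory-pathway subsystems).
#' @param sets named list of character vectors (gene ids).
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(nm)
    paste(c(nm, nm, sets[[nm]]), collapse = "\t"), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname omniflux-io
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  stats::setNames(lapply(parts, function(p) p[-(1:2)]),
                  vapply(parts, `[[`, character(1), 1))
}

#' @rdname omniflux-io
#' @param network a `MetabolicNetwork`.
#' @export
write_network_json <- function(network, path) {
  obj <- list(
    schema_version = "1.0",
    metabolites = network$metabolites,
    reactions = lapply(network$reactions, function(r)
      list(id = r$id, stoich = as.list(r$stoich), lb = r$lb, ub = r$ub,
           reversible = r$reversible, role = r$role)),
    enzymes = network$enzymes
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname omniflux-io
#' @export
read_network_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  mets <- data.frame(
    id = vapply(obj$metabolites, function(m) m$id, character(1)),
    external = vapply(obj$metabolites, function(m) isTRUE(m$external),
                      logical(1)),
    stringsAsFactors = FALSE)
  rxns <- lapply(obj$reactions, function(r)
    reaction(r$id, unlist(r$stoich), lb = r$lb, ub = r$ub,
             reversible = isTRUE(r$reversible), role = r$role))
  enz <- if (length(obj$enzymes)) {
    do.call(rbind, lapply(obj$enzymes, function(e)
      data.frame(reaction_id = e$reaction_id, enzyme_id = e$enzyme_id,
                 kcat = e$kcat, mw = e$mw, stringsAsFactors = FALSE)))
  } else NULL
  metabolic_network(mets, rxns, enz)
}
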