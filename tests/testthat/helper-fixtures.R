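# Small hand-built fixtures shared across test files.

tiny_annotation <- function() {
  data.frame(gene_id = c("g1", "g2", "g3"),
             mol_weight = c(10, 30, 50),
             n_theoretical_peptides = c(3L, 1L, 2L),
             processes = c("p1", "p2", "p1;p2"),
             stringsAsFactors = FALSE)
}

tiny_ontology <- function() ontology(c("p1", "p2"))

make_abundance <- function(values, genes, samples, layer = "protein",
                           units = "arbitrary_absolute") {
  m <- matrix(values, nrow = length(genes),
              dimnames = list(genes, samples))
  abundance_matrix(m, layer, units)
}

# a partition annotation: every gene in exactly one process, round-robin
partition_annotation <- function(n_genes, n_proc, seed = 1) {
  ann <- generate_annotation(n_genes, n_proc, seed = seed)
  ann$annotation$processes <- sprintf("bp%03d",
                                      rep_len(seq_len(n_proc), n_genes))
  ann
}

two_strain_design <- function() experiment_design(c("REF", "PERT"), 0.1, 2)
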