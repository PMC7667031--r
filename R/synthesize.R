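#' Experiment design for synthetic chemostat multi-omics
#'
#' Strains x dilution rates x biological replicates. Defaults mirror a
#' three-strain recombinant-protein study grown in carbon-limited chemostats
#' at two dilution rates with biological duplicates.
#'
#' @param strains character vector of strain names; the first is the
#'   reference strain for differential contrasts.
#' @param dilution_rates per-hour dilution rates (> 0).
#' @param n_replicates biological replicates per strain x rate (>= 2; the
#'   differential t-tests need at least two).
#' @return object of class `ExperimentDesign` with a `samples` data.frame
#'   (sample_id, strain, dilution_rate, replicate).
#' @export
experiment_design <- function(strains = c("AAC", "MH34", "B184"),
                              dilution_rates = c(0.1, 0.2),
                              n_replicates = 2L) {
  if (any(dilution_rates <= 0)) stop("dilution rates must be > 0", call. = FALSE)
  if (n_replicates < 2L) stop("need >= 2 replicates per group", call. = FALSE)
  grid <- expand.grid(replicate = seq_len(n_replicates),
                      dilution_rate = dilution_rates,
                      strain = strains,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid <- grid[, c("strain", "dilution_rate", "replicate")]
  grid$sample_id <- sprintf("%s_%g_%d", grid$strain, grid$dilution_rate,
                            grid$replicate)
  structure(list(strains = strains, dilution_rates = dilution_rates,
                 n_replicates = as.integer(n_replicates), samples = grid),
            class = "ExperimentDesign")
}

#' @export
print.ExperimentDesign <- function(x, ...) {
  cat(sprintf("ExperimentDesign: %d strains x %d rates x %d replicates (%d samples)\n",
              length(x$strains), length(x$dilution_rates), x$n_replicates,
              nrow(x$samples)))
  invisible(x)
}

#' Shipped default strain effects
#'
#' A qualitative analogue of the study contrasts the generator emulates:
#' strain 2 (MH34-like) upregulates the folding-capacity and storage-sugar
#' processes; strain 3 (B184-like) upregulates the folding process more
#' strongly (higher folding precision) without the storage-sugar response.
#' Process roles are positional: the first ontology process plays "protein
#' folding", the second "trehalose/storage metabolism".
#'
#' @param ontology an `Ontology`.
#' @param strains strain names (reference first).
#' @return list of effect specifications consumable by [generate_truth()].
#' @export
default_effects <- function(ontology, strains = c("AAC", "MH34", "B184")) {
  p <- ontology$process_ids
  list(
    list(strain = strains[2], target = p[1], fold = 1.5, layer = "both"),
    list(strain = strains[2], target = p[min(2, length(p))], fold = 1.6,
         layer = "both"),
    list(strain = strains[3], target = p[1], fold = 2.0, layer = "both")
  )
}

#' Generate ground-truth absolute mRNA and protein abundances
#'
#' Per-gene mRNA (molecules/cell) is log-normal; protein equals mRNA times a
#' gene-specific translation propensity times strain effects times replicate
#' noise. The propensity dispersion is chosen so that the squared Pearson
#' correlation of the log layers hits `coupling_r2`:
#' `Var(log10 propensity) = Var(log10 mRNA) * (1 - R2) / R2`.
#'
#' @param design an `ExperimentDesign`.
#' @param annotation annotation data.frame (see [generate_annotation()]).
#' @param effect_config list with elements:
#'   * `effects`: list of `list(strain=, target=, fold=, layer=)` where
#'     `target` is a process id (all member genes affected) or a gene id and
#'     `layer` is `"mRNA"` (propagates into protein through the coupling) or
#'     `"protein"` (post-transcriptional, changes P/T);
#'   * `coupling_r2`: target protein-mRNA R2 on log10 scale (0 < r2 <= 1);
#'   * `noise_sd`: replicate noise SD, log10 scale, per layer;
#'   * `mrna_meanlog10`, `mrna_sdlog10`: base mRNA distribution (molecules/cell);
#'   * `propensity_meanlog10`: mean log10 protein/mRNA ratio.
#' @param ontology optional `Ontology` used to validate effect targets.
#' @param seed integer seed.
#' @return object of class `SyntheticTruth`: `true_mrna` and `true_protein`
#'   (`AbundanceMatrix`, molecules/cell), `propensity` (named per-gene vector),
#'   `protein_effect` and `mrna_effect` (gene x sample multipliers),
#'   `design`, `generator_params`.
#' @export
generate_truth <- function(design, annotation,
                           effect_config = list(), ontology = NULL,
                           seed = 1L) {
  cfg <- list(effects = list(), coupling_r2 = 0.5,
              noise_sd = 0.05, mrna_meanlog10 = 0.5,
              mrna_sdlog10 = 0.5, propensity_meanlog10 = 3)
  cfg[names(effect_config)] <- effect_config   # non-recursive: keep effects list intact
  if (cfg$coupling_r2 <= 0 || cfg$coupling_r2 > 1)
    stop("coupling_r2 must be in (0, 1]", call. = FALSE)
  known_targets <- c(annotation$gene_id,
                     if (!is.null(ontology)) ontology$process_ids
                     else unique(unlist(process_sets(annotation))))
  for (ef in cfg$effects) {
    if (!all(c("strain", "target", "fold", "layer") %in% names(ef)))
      stop("each effect needs strain/target/fold/layer", call. = FALSE)
    if (!ef$target %in% known_targets)
      stop(sprintf("effect targets unknown process or gene '%s'", ef$target),
           call. = FALSE)
    if (!ef$strain %in% design$strains)
      stop(sprintf("effect references unknown strain '%s'", ef$strain),
           call. = FALSE)
  }
  withr::local_seed(seed)

  genes <- annotation$gene_id
  n <- length(genes)
  samples <- design$samples
  ns <- nrow(samples)

  base_log_mrna <- stats::rnorm(n, cfg$mrna_meanlog10, cfg$mrna_sdlog10)
  prop_sd <- cfg$mrna_sdlog10 * sqrt((1 - cfg$coupling_r2) / cfg$coupling_r2)
  propensity <- 10 ^ stats::rnorm(n, cfg$propensity_meanlog10, prop_sd)
  names(propensity) <- genes

  ps <- process_sets(annotation)
  effect_genes <- function(target) {
    if (target %in% genes) return(target)
    genes[vapply(ps, function(p) target %in% p, logical(1))]
  }
  mrna_eff <- matrix(1, n, ns, dimnames = list(genes, samples$sample_id))
  prot_eff <- mrna_eff
  for (ef in cfg$effects) {
    idx <- match(effect_genes(ef$target), genes)
    cols <- which(samples$strain == ef$strain)
    if (ef$layer %in% c("mRNA", "both"))
      mrna_eff[idx, cols] <- mrna_eff[idx, cols] * ef$fold
    if (ef$layer %in% c("protein", "both"))
      prot_eff[idx, cols] <- prot_eff[idx, cols] * ef$fold
  }

  noise <- function() {
    if (cfg$noise_sd == 0) matrix(1, n, ns)
    else matrix(10 ^ stats::rnorm(n * ns, 0, cfg$noise_sd), n, ns)
  }
  mrna <- 10 ^ base_log_mrna * mrna_eff * noise()
  protein <- mrna * propensity * prot_eff * noise()
  dimnames(mrna) <- dimnames(protein) <- list(genes, samples$sample_id)

  structure(list(
    true_mrna = abundance_matrix(mrna, "mRNA", "molecules_per_cell"),
    true_protein = abundance_matrix(protein, "protein", "molecules_per_cell"),
    propensity = propensity,
    mrna_effect = mrna_eff,
    protein_effect = prot_eff,
    design = design,
    generator_params = c(cfg, list(seed = seed))
  ), class = "SyntheticTruth")
}

#' @export
print.SyntheticTruth <- function(x, ...) {
  cat(sprintf("SyntheticTruth: %d genes x %d samples (coupling R2 target %.2f)\n",
              nrow(ab_values(x$true_mrna)), ncol(ab_values(x$true_mrna)),
              x$generator_params$coupling_r2))
  invisible(x)
}

#' Simulate an FPKM-like mRNA assay with external calibration standards
#'
#' The measurement law is log-linear: `log10(concentration) =
#' slope * log10(signal) + intercept`. Signals are the inverse of that law
#' applied to the true concentrations, with log-normal measurement noise.
#' Calibration standards are chosen by stratified quantiles of the dynamic
#' range (one gene per quantile bin of the mean true concentration), so they
#' cover the full expression range as external spike-in mixes are designed to.
#'
#' @param truth a `SyntheticTruth`.
#' @param calib_config list: `slope`, `intercept` (true measurement law),
#'   `noise_sd` (log10 SD on signals), `n_standards` (default 36).
#' @param seed integer seed.
#' @return list with `signal` (`AbundanceMatrix`, mRNA/signal units) and
#'   `standards` (data.frame standard_id, known_concentration, measured_signal).
#' @export
simulate_mrna_assay <- function(truth,
                                calib_config = list(),
                                seed = 1L) {
  cfg <- utils::modifyList(list(slope = 0.9, intercept = 2.0,
                                noise_sd = 0.1, n_standards = 36L),
                           calib_config)
  conc <- ab_values(truth$true_mrna)
  if (nrow(conc) < cfg$n_standards)
    stop(sprintf("cannot pick %d standards from %d genes",
                 cfg$n_standards, nrow(conc)), call. = FALSE)
  withr::local_seed(seed)

  to_signal <- function(x) (log10(x) - cfg$intercept) / cfg$slope
  noise <- function(m) if (cfg$noise_sd == 0) 0 else
    stats::rnorm(m, 0, cfg$noise_sd)

  sig <- 10 ^ (to_signal(conc) + noise(length(conc)))
  dim(sig) <- dim(conc); dimnames(sig) <- dimnames(conc)

  mean_conc <- rowMeans(conc)
  bins <- cut(rank(mean_conc, ties.method = "first"),
              breaks = cfg$n_standards, labels = FALSE)
  std_idx <- vapply(split(seq_along(mean_conc), bins),
                    function(i) if (length(i) == 1L) i else sample(i, 1L),
                    integer(1))
  known <- mean_conc[std_idx]
  standards <- data.frame(
    standard_id = names(mean_conc)[std_idx],
    known_concentration = unname(known),
    measured_signal = 10 ^ (to_signal(known) + noise(length(known))),
    stringsAsFactors = FALSE)
  rownames(standards) <- NULL

  list(signal = abundance_matrix(sig, "mRNA", "signal"),
       standards = standards)
}

#' Default UPS2-like dynamic-range standard configuration
#'
#' 48 standard proteins with known amounts log-spaced over five orders of
#' magnitude. A configurable number of the lowest-amount standards carry a
#' single unique peptide, to exercise the >= 2-unique-peptides detection
#' filter downstream (with the default 5, 43 of 48 survive it).
#'
#' @param n_standards number of standards.
#' @param n_low_peptides standards assigned < 2 unique peptides.
#' @return data.frame standard_id, amount, n_unique_peptides.
#' @export
ups2_default_config <- function(n_standards = 48L, n_low_peptides = 5L) {
  amount <- 10 ^ seq(log10(0.5), log10(5e4), length.out = n_standards)
  n_unique <- 2L + (seq_len(n_standards) %/% 3L)
  n_unique[seq_len(min(n_low_peptides, n_standards))] <- 1L
  data.frame(standard_id = sprintf("ups%02d", seq_len(n_standards)),
             amount = amount, n_unique_peptides = n_unique,
             stringsAsFactors = FALSE)
}

#' Simulate the proteome assay: pooled-reference peptides, UPS2-like
#' standards, and TMT ratios
#'
#' The pooled reference is the mean of the true protein abundances over all
#' samples. Its iBAQ-able peptide-intensity table is generated so that the
#' summed intensity of a protein divided by its theoretical peptide count
#' follows the protein measurement law (same log-linear form as the mRNA
#' assay). Standards obey the same law, anchoring the absolute scale. TMT
#' ratios are true sample/reference ratios with log-normal noise.
#'
#' @param truth a `SyntheticTruth`.
#' @param annotation annotation data.frame (theoretical peptide counts).
#' @param ups2_config data.frame as from [ups2_default_config()] (non-empty).
#' @param tmt_config list: `noise_sd` (log10 SD on ratios).
#' @param calib_config list: `slope`, `intercept`, `noise_sd` of the protein
#'   measurement law.
#' @param seed integer seed.
#' @return list with `peptides` (data.frame protein_id, peptide_id,
#'   intensity), `ups2` (data.frame standard_id, known_concentration,
#'   measured_signal, n_unique_peptides), `tmt_ratios` (gene x sample matrix).
#' @export
simulate_protein_assay <- function(truth, annotation,
                                   ups2_config = ups2_default_config(),
                                   tmt_config = list(),
                                   calib_config = list(),
                                   seed = 1L) {
  if (is.null(ups2_config) || nrow(ups2_config) == 0L)
    stop("ups2_config must list at least one standard", call. = FALSE)
  tcfg <- utils::modifyList(list(noise_sd = 0.05), tmt_config)
  ccfg <- utils::modifyList(list(slope = 0.95, intercept = 0.8, noise_sd = 0.1),
                            calib_config)
  withr::local_seed(seed)

  prot <- ab_values(truth$true_protein)
  genes <- rownames(prot)
  npep <- annotation$n_theoretical_peptides[match(genes, annotation$gene_id)]
  if (anyNA(npep))
    stop("truth contains genes missing from annotation", call. = FALSE)

  pooled <- rowMeans(prot)
  to_signal <- function(x) (log10(x) - ccfg$intercept) / ccfg$slope
  noise <- function(m, sd) if (sd == 0) 0 else stats::rnorm(m, 0, sd)

  ibaq_signal <- 10 ^ (to_signal(pooled) + noise(length(pooled), ccfg$noise_sd))
  n_det <- pmax(1L, stats::rbinom(length(genes), npep, 0.7))
  total <- ibaq_signal * npep
  pep_list <- lapply(seq_along(genes), function(i) {
    w <- stats::runif(n_det[i])
    data.frame(protein_id = genes[i],
               peptide_id = sprintf("%s_pep%02d", genes[i], seq_len(n_det[i])),
               intensity = total[i] * w / sum(w),
               stringsAsFactors = FALSE)
  })
  peptides <- do.call(rbind, pep_list)
  rownames(peptides) <- NULL

  ups2 <- data.frame(
    standard_id = ups2_config$standard_id,
    known_concentration = ups2_config$amount,
    measured_signal = 10 ^ (to_signal(ups2_config$amount) +
                              noise(nrow(ups2_config), ccfg$noise_sd)),
    n_unique_peptides = ups2_config$n_unique_peptides,
    stringsAsFactors = FALSE)

  ratio_noise <- if (tcfg$noise_sd == 0) 1 else
    matrix(10 ^ stats::rnorm(length(prot), 0, tcfg$noise_sd),
           nrow(prot), ncol(prot))
  tmt_ratios <- prot / pooled * ratio_noise
  dimnames(tmt_ratios) <- dimnames(prot)

  list(peptides = peptides, ups2 = ups2, tmt_ratios = tmt_ratios)
}
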