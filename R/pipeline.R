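#' Default pipeline configuration
#'
#' All tunable parameters of the end-to-end analysis with their defaults:
#' significance threshold `alpha = 0.05`, enzyme-pool `f = 0.5` and
#' `sigma = 0.5`, exchange flexibility `flex = 1.03`, standard detection
#' filter `min_unique_peptides = 2`, and the synthetic-experiment settings
#' (2,800 genes over a 99-process ontology, three strains at two dilution
#' rates in biological duplicate).
#'
#' @param ... overrides for any defaults.
#' @return list of class `PipelineConfig`.
#' @export
pipeline_config <- function(...) {
  cfg <- utils::modifyList(list(
    seed = 1L,
    out_dir = NULL,
    n_genes = 2800L,
    ontology_size = 99L,
    strains = c("AAC", "MH34", "B184"),
    dilution_rates = c(0.1, 0.2),
    n_replicates = 2L,
    coupling_r2 = 0.5,
    noise_sd = 0.05,
    mrna_calib = list(slope = 0.9, intercept = 2.0, noise_sd = 0.1,
                      n_standards = 36L),
    protein_calib = list(slope = 0.95, intercept = 0.8, noise_sd = 0.1),
    tmt = list(noise_sd = 0.05),
    alpha = 0.05,
    min_unique_peptides = 2L,
    f = 0.5,
    sigma = 0.5,
    flex = 1.03,
    toy = list()
  ), list(...))
  stopifnot(cfg$alpha > 0, cfg$alpha <= 1, cfg$f >= 0, cfg$sigma > 0,
            cfg$flex >= 1, cfg$min_unique_peptides >= 0)
  class(cfg) <- c("PipelineConfig", "list")
  cfg
}

#' Run the full synthetic multi-omics analysis pipeline
#'
#' simulate -> quantify -> allocate -> compare -> chemostat -> NGAM, on
#' synthetic data with recorded ground truth. Identical config and seed give
#' an identical report (and byte-identical output files when `out_dir` is
#' set). Any stage failure halts with the stage name in the error.
#'
#' @param config a `PipelineConfig` (see [pipeline_config()]).
#' @return a report list: `truth`, `inputs` (simulated assays),
#'   `quant` (calibration curves + absolute layers), `fractions`,
#'   `diff` (per contrast), `correlations` (data.frame), `propensity`,
#'   `physiology` (yield/productivity per condition), `rates`,
#'   `ngam` (data.frame: condition, solved NGAM, true NGAM), `manifest`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stage <- function(name, expr) {
    tryCatch(force(expr), error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }
  seed <- as.integer(config$seed)

  sim <- stage("simulate", {
    ann <- generate_annotation(config$n_genes, config$ontology_size,
                               seed = seed)
    design <- experiment_design(config$strains, config$dilution_rates,
                                config$n_replicates)
    truth <- generate_truth(design, ann$annotation,
                            effect_config = list(
                              effects = default_effects(ann$ontology,
                                                        config$strains),
                              coupling_r2 = config$coupling_r2,
                              noise_sd = config$noise_sd),
                            ontology = ann$ontology, seed = seed + 1L)
    mrna <- simulate_mrna_assay(truth, config$mrna_calib, seed = seed + 2L)
    prot <- simulate_protein_assay(truth, ann$annotation,
                                   tmt_config = config$tmt,
                                   calib_config = config$protein_calib,
                                   seed = seed + 3L)
    toy <- generate_toy_ecmodel(config$toy, seed = seed + 4L)
    chem <- simulate_chemostat(toy, n_replicates = config$n_replicates,
                               seed = seed + 5L)
    list(annotation = ann$annotation, ontology = ann$ontology,
         design = design, truth = truth, mrna = mrna, protein = prot,
         toy = toy, chemostat = chem)
  })

  quant <- stage("quantify",
    quantify_absolute(sim$mrna$signal, sim$mrna$standards,
                      sim$protein$peptides, sim$protein$ups2,
                      sim$protein$tmt_ratios, sim$annotation,
                      config$min_unique_peptides))

  fractions <- stage("allocate", list(
    mrna_molar = allocate(quant$mrna_absolute, sim$annotation,
                          sim$ontology, "molar"),
    protein_mass = allocate(quant$protein_absolute, sim$annotation,
                            sim$ontology, "mass")))

  diff <- stage("allocate", {
    ref <- config$strains[1]
    samp <- sim$design$samples
    out <- list()
    for (D in config$dilution_rates) {
      ga <- samp$sample_id[samp$strain == ref & samp$dilution_rate == D]
      for (s in setdiff(config$strains, ref)) {
        gb <- samp$sample_id[samp$strain == s & samp$dilution_rate == D]
        key <- sprintf("%s_vs_%s_%g", s, ref, D)
        out[[paste0("protein_", key)]] <-
          diff_units(fractions$protein_mass, ga, gb, alpha = config$alpha)
        out[[paste0("mrna_", key)]] <-
          diff_units(fractions$mrna_molar, ga, gb, alpha = config$alpha)
      }
    }
    out
  })

  compare <- stage("compare", {
    prop <- translation_propensity(quant$protein_absolute,
                                   quant$mrna_absolute)
    cors <- do.call(rbind, lapply(sim$design$samples$sample_id, function(s) {
      g <- correlate_layers(quant$protein_absolute, quant$mrna_absolute, s,
                            "gene")
      pm <- allocate(quant$mrna_absolute, sim$annotation, sim$ontology,
                     "molar")
      pp <- allocate(quant$protein_absolute, sim$annotation, sim$ontology,
                     "molar")
      p <- correlate_layers(pp, pm, s, "process")
      data.frame(sample = s,
                 gene_r2 = g$r_squared, gene_n_pairs = g$n_pairs,
                 process_r2 = p$r_squared, process_n_pairs = p$n_pairs,
                 stringsAsFactors = FALSE)
    }))
    list(propensity = prop, correlations = cors)
  })

  physiology <- stage("chemostat", {
    recs <- sim$chemostat
    do.call(rbind, lapply(recs, function(rec) {
      yp <- product_yield_and_productivity(rec)
      data.frame(strain = rec$strain, dilution_rate = rec$dilution_rate,
                 replicate = rec$replicate,
                 yield = yp$yield, productivity = yp$productivity,
                 total_aa_uptake = sum(vapply(
                   setdiff(names(rec$feed), c("glc", "etoh")),
                   function(cp) specific_rate(rec, cp, "uptake"),
                   numeric(1))),
                 stringsAsFactors = FALSE)
    }))
  })

  ngam <- stage("ngam", {
    toy <- sim$toy
    conds <- toy$truth$conditions
    do.call(rbind, lapply(seq_len(nrow(conds)), function(i) {
      cid <- conds$condition_id[i]
      recs <- Filter(function(r) r$strain == conds$strain[i] &&
                       r$dilution_rate == conds$dilution_rate[i],
                     sim$chemostat)
      rates <- exchange_rates_from_records(recs)
      model <- build_ec_model(toy$network, f = config$f,
                              sigma = config$sigma)
      model <- apply_proteomics(model, toy$truth$proteome[, cid])
      model <- apply_exchange_constraints(model, rates, flex = config$flex)
      sol <- solve_ngam(model, conds$dilution_rate[i])
      data.frame(condition = cid, strain = conds$strain[i],
                 dilution_rate = conds$dilution_rate[i],
                 status = sol$status,
                 ngam = sol$objective_value,
                 true_ngam = unname(toy$truth$ngam[cid]),
                 stringsAsFactors = FALSE)
    }))
  })

  report <- list(config = config, truth = sim$truth, inputs = sim,
                 quant = quant, fractions = fractions, diff = diff,
                 correlations = compare$correlations,
                 propensity = compare$propensity,
                 physiology = physiology, ngam = ngam)

  if (!is.null(config$out_dir)) {
    report$manifest <- stage("write", write_report(report, config$out_dir))
  }
  report
}

write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(out_dir, f)
  sim <- report$inputs
  write_annotation_tsv(sim$annotation, p("annotation.tsv"))
  write_matrix_tsv(sim$mrna$signal, p("mrna_signal.tsv"))
  write_spikein_tsv(sim$mrna$standards, p("mrna_standards.tsv"))
  write_spikein_tsv(sim$protein$ups2, p("ups2_standards.tsv"))
  utils::write.table(sim$protein$peptides, p("peptides.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_matrix_tsv(sim$protein$tmt_ratios, p("tmt_ratios.tsv"))
  write_network_json(sim$toy$network, p("toy_network.json"))
  write_matrix_tsv(report$quant$mrna_absolute, p("mrna_absolute.tsv"))
  write_matrix_tsv(report$quant$protein_absolute, p("protein_absolute.tsv"))
  write_matrix_tsv(report$fractions$mrna_molar$fractions,
                   p("fractions_mrna_molar.tsv"), id_col = "process_id")
  write_matrix_tsv(report$fractions$protein_mass$fractions,
                   p("fractions_protein_mass.tsv"), id_col = "process_id")
  for (nm in names(report$diff))
    utils::write.table(report$diff[[nm]], p(sprintf("diff_%s.tsv", nm)),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(report$correlations, p("correlations.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_matrix_tsv(report$propensity$values, p("propensity.tsv"))
  utils::write.table(report$physiology, p("physiology.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(report$ngam, p("ngam.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  files <- sort(list.files(out_dir))
  manifest <- list(
    files = files,
    parameters = report$config[c("seed", "alpha", "f", "sigma", "flex",
                                 "min_unique_peptides")],
    curves = list(
      mrna = unclass(report$quant$mrna_curve),
      protein = unclass(report$quant$protein_curve)))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  manifest
}
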