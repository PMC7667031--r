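test_that("annotation generation is seed-deterministic and validates inputs", {
  a1 <- generate_annotation(1, 1, seed = 7)
  a2 <- generate_annotation(1, 1, seed = 7)
  expect_identical(a1, a2)
  expect_equal(nrow(a1$annotation), 1L)
  expect_equal(length(a1$ontology$process_ids), 1L)

  big <- generate_annotation(2800, 99, seed = 1)
  expect_equal(nrow(big$annotation), 2800L)
  expect_equal(length(big$ontology$process_ids), 99L)
  expect_true(all(big$annotation$mol_weight >= 10 &
                    big$annotation$mol_weight <= 200))
  expect_true(all(big$annotation$n_theoretical_peptides >= 1))

  expect_error(generate_annotation(0, 5), "n_genes")
  expect_error(generate_annotation(10, 0), "ontology_size")
})

test_that("mean process memberships per gene match the configured rate", {
  # independent tally over the emitted records, against the Poisson rate
  rate <- 1.5
  ann <- generate_annotation(5000, 25, membership_rate = rate, seed = 3)
  k <- lengths(process_sets(ann$annotation))
  se <- sqrt(rate / length(k))   # Poisson SE of the mean (truncation at 25 negligible)
  expect_lt(abs(mean(k) - rate), 3 * se)

  small <- generate_annotation(100, 5, membership_rate = rate, seed = 3)
  k2 <- lengths(process_sets(small$annotation))
  # truncation at 5 processes bites harder here; allow the same 3-SE band
  # around the truncated-Poisson mean computed by brute force
  pk <- stats::dpois(0:100, rate)
  mean_trunc <- sum(pmin(0:100, 5) * pk)
  expect_lt(abs(mean(k2) - mean_trunc), 3 * sqrt(rate / 100))
})

test_that("truth generator honors the noise-free and degenerate-coupling limits", {
  ann <- generate_annotation(50, 4, seed = 2)
  des <- experiment_design()
  tr <- generate_truth(des, ann$annotation,
                       list(noise_sd = 0, coupling_r2 = 0.5),
                       ontology = ann$ontology, seed = 5)
  ratio <- ab_values(tr$true_protein) / ab_values(tr$true_mrna)
  expect_equal(ratio, matrix(tr$propensity, nrow = 50, ncol = 12,
                             dimnames = dimnames(ratio)),
               tolerance = 1e-12)

  tr1 <- generate_truth(des, ann$annotation,
                        list(noise_sd = 0, coupling_r2 = 1),
                        ontology = ann$ontology, seed = 5)
  r2 <- stats::cor(log10(ab_values(tr1$true_mrna)[, 1]),
                   log10(ab_values(tr1$true_protein)[, 1])) ^ 2
  expect_equal(r2, 1, tolerance = 1e-12)

  expect_error(generate_truth(des, ann$annotation,
                              list(effects = list(list(strain = "AAC",
                                                       target = "nope",
                                                       fold = 2,
                                                       layer = "protein"))),
                              ontology = ann$ontology),
               "unknown process")
})

test_that("truth coupling R2 tracks its target across seeds", {
  des <- experiment_design()
  r2s <- vapply(1:20, function(s) {
    ann <- generate_annotation(2500, 10, seed = s)
    tr <- generate_truth(des, ann$annotation, list(coupling_r2 = 0.5),
                         ontology = ann$ontology, seed = 100 + s)
    # oracle: direct correlation on the generated truth
    stats::cor(log10(ab_values(tr$true_mrna)[, 1]),
               log10(ab_values(tr$true_protein)[, 1])) ^ 2
  }, numeric(1))
  expect_lt(abs(median(r2s) - 0.5), 0.05)
})

test_that("planted strain effects are present in the truth layers", {
  ann <- generate_annotation(300, 8, seed = 4)
  des <- experiment_design()
  tr <- generate_truth(des, ann$annotation,
                       list(noise_sd = 0,
                            effects = list(list(strain = "MH34",
                                                target = "bp001",
                                                fold = 1.7,
                                                layer = "protein"))),
                       ontology = ann$ontology, seed = 6)
  members <- process_members(ann$annotation, ann$ontology)$bp001
  p <- ab_values(tr$true_protein)
  expect_equal(unique(round(p[members, "MH34_0.1_1"] /
                              p[members, "AAC_0.1_1"], 10)), 1.7)
  others <- setdiff(rownames(p), members)
  expect_equal(unique(round(p[others, "MH34_0.1_1"] /
                              p[others, "AAC_0.1_1"], 10)), 1)
})

test_that("mRNA assay round-trips its calibration law and emits 36 standards", {
  ann <- generate_annotation(500, 5, seed = 8)
  tr <- generate_truth(experiment_design(), ann$annotation,
                       ontology = ann$ontology, seed = 9)
  assay <- simulate_mrna_assay(tr, list(slope = 0.9, intercept = 2.0,
                                        noise_sd = 0), seed = 10)
  expect_equal(nrow(assay$standards), 36L)
  fit <- fit_calibration(assay$standards)
  expect_equal(fit$slope, 0.9, tolerance = 1e-10)
  expect_equal(fit$intercept, 2.0, tolerance = 1e-10)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)

  expect_error(simulate_mrna_assay(tr, list(n_standards = 501)),
               "standards")
})

test_that("noisy mRNA standards land in a plausible calibration-quality band", {
  ann <- generate_annotation(800, 5, seed = 1)
  tr <- generate_truth(experiment_design(), ann$annotation,
                       ontology = ann$ontology, seed = 2)
  r2s <- vapply(1:15, function(s) {
    assay <- simulate_mrna_assay(tr, list(noise_sd = 0.15), seed = s)
    # independent least-squares oracle via the normal equations
    x <- log10(assay$standards$measured_signal)
    y <- log10(assay$standards$known_concentration)
    bx <- cov(x, y) / var(x)
    yhat <- mean(y) + bx * (x - mean(x))
    1 - sum((y - yhat) ^ 2) / sum((y - mean(y)) ^ 2)
  }, numeric(1))
  expect_gt(median(r2s), 0.85)
  expect_lt(median(r2s), 0.98)
})

test_that("protein assay: self-ratio, peptide sums, and UPS2 filtering scale", {
  ann <- generate_annotation(60, 4, seed = 3)
  tr <- generate_truth(experiment_design(), ann$annotation,
                       list(noise_sd = 0), ontology = ann$ontology, seed = 4)
  assay <- simulate_protein_assay(tr, ann$annotation,
                                  tmt_config = list(noise_sd = 0),
                                  calib_config = list(noise_sd = 0),
                                  seed = 5)
  # with zero replicate noise every sample equals the pooled mean
  expect_equal(max(abs(assay$tmt_ratios - 1)), 0, tolerance = 1e-12)

  # per-protein summed intensity equals an independent group-and-sum oracle
  sums <- tapply(assay$peptides$intensity, assay$peptides$protein_id, sum)
  ib <- compute_ibaq(assay$peptides, ann$annotation)
  npep <- ann$annotation$n_theoretical_peptides[
    match(names(sums), ann$annotation$gene_id)]
  expect_equal(as.numeric(ab_values(ib)[names(sums), 1]),
               as.numeric(sums) / npep, tolerance = 1e-12)

  # 48 standards, 5 below the two-peptide threshold -> 43 retained
  expect_equal(nrow(assay$ups2), 48L)
  expect_equal(nrow(filter_standards(assay$ups2)), 43L)

  expect_error(simulate_protein_assay(tr, ann$annotation,
                                      ups2_config = data.frame()),
               "ups2")
})

test_that("generators are byte-deterministic and non-negative", {
  ann <- generate_annotation(120, 6, seed = 11)
  tr <- generate_truth(experiment_design(), ann$annotation,
                       ontology = ann$ontology, seed = 12)
  a1 <- simulate_mrna_assay(tr, seed = 13)
  a2 <- simulate_mrna_assay(tr, seed = 13)
  expect_identical(a1, a2)
  p1 <- simulate_protein_assay(tr, ann$annotation, seed = 14)
  p2 <- simulate_protein_assay(tr, ann$annotation, seed = 14)
  expect_identical(p1, p2)
  t1 <- generate_toy_ecmodel(seed = 15)
  t2 <- generate_toy_ecmodel(seed = 15)
  expect_identical(t1, t2)

  expect_true(all(ab_values(tr$true_mrna) >= 0))
  expect_true(all(ab_values(tr$true_protein) >= 0))
  expect_true(all(a1$signal$values >= 0))
  expect_true(all(p1$peptides$intensity >= 0))
  expect_true(all(p1$tmt_ratios >= 0))
})

test_that("toy ec-network truth is stoichiometrically consistent", {
  for (s in 1:10) {
    toy <- generate_toy_ecmodel(seed = s)
    S <- stoich_matrix(toy$network)
    resid <- max(abs(S %*% toy$truth$fluxes))
    expect_lt(resid, 1e-9)
    # recorded enzyme abundance always covers v/kcat, reaction by reaction
    enz <- toy$network$enzymes
    for (cid in colnames(toy$truth$fluxes)) {
      v <- toy$truth$fluxes[enz$reaction_id, cid]
      expect_true(all(toy$truth$proteome[enz$enzyme_id, cid] >=
                        v / enz$kcat - 1e-12))
    }
  }
  expect_error(generate_toy_ecmodel(list(include_ngam = FALSE)),
               "NGAM")
})

test_that("a minimal uptake-to-ATP chain has NGAM = uptake x ATP yield", {
  mets <- data.frame(id = c("S", "atp"), external = FALSE,
                     stringsAsFactors = FALSE)
  rxns <- list(
    reaction("EX_S", c(S = 1), ub = 2, role = "exchange"),
    reaction("CAT", c(S = -1, atp = 4)),
    reaction("NGAM", c(atp = -1), role = "ngam"))
  net <- metabolic_network(mets, rxns,
                           data.frame(reaction_id = "CAT", enzyme_id = "E",
                                      kcat = 1e4, mw = 50,
                                      stringsAsFactors = FALSE))
  model <- build_ec_model(net, p_total = 10)  # pool far from binding
  sol <- solve_ngam(model)
  expect_equal(sol$objective_value, 2 * 4, tolerance = 1e-9)
})

test_that("chemostat simulation inverts back to the true exchange fluxes", {
  toy <- generate_toy_ecmodel(seed = 21)
  recs <- simulate_chemostat(toy, noise_sd = 0, seed = 22)
  r1 <- Filter(function(r) r$strain == "MH34" && r$dilution_rate == 0.2, recs)
  rates <- exchange_rates_from_records(r1)
  v <- toy$truth$fluxes[, "MH34_0.2"]
  expect_equal(rates$rate[match("EX_glc", rates$reaction_id)],
               unname(v["EX_glc"]), tolerance = 1e-9)
  expect_equal(rates$rate[match("EX_aa", rates$reaction_id)],
               unname(v["EX_aa"]), tolerance = 1e-9)
  expect_equal(rates$rate[match("EX_etoh", rates$reaction_id)],
               unname(v["EX_etoh"]), tolerance = 1e-9)
  expect_equal(rates$rate[match("EX_prod", rates$reaction_id)],
               unname(v["EX_prod"]), tolerance = 1e-9)
})
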