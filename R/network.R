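DEFAULT_FLUX_BOUND <- 1000

#' Define a reaction
#'
#' @param id reaction id.
#' @param stoich named numeric vector: metabolite -> coefficient (negative =
#'   consumed). Exchange reactions are unbalanced by design (they touch the
#'   boundary); internal reactions must reference internal metabolites.
#' @param lb,ub flux bounds (mmol/gDCW/h); the default upper bound 1000 is the
#'   conventional "effectively unconstrained" FBA cap.
#' @param reversible logical; reversible enzymatic reactions are split into
#'   forward/backward halves when the enzyme-constrained model is built.
#' @param role one of `"internal"`, `"exchange"`, `"biomass"`, `"ngam"`,
#'   `"product_secretion"`.
#' @return a reaction record (list).
#' @export
reaction <- function(id, stoich, lb = 0, ub = DEFAULT_FLUX_BOUND,
                     reversible = FALSE,
                     role = c("internal", "exchange", "biomass", "ngam",
                              "product_secretion")) {
  role <- match.arg(role)
  if (is.null(names(stoich)) || any(!nzchar(names(stoich))))
    stop("stoichiometry must be a named vector", call. = FALSE)
  list(id = id, stoich = stoich, lb = lb, ub = ub,
       reversible = isTRUE(reversible), role = role,
       ub_is_default = missing(ub))
}

#' Assemble a metabolic network
#'
#' @param metabolites data.frame with columns `id` and `external` (logical);
#'   only internal metabolites enter the steady-state balance.
#' @param reactions list of [reaction()] records. At most one reaction tagged
#'   `biomass`; exactly one tagged `ngam` (the ATP-hydrolysis maintenance
#'   reaction -- without it the NGAM objective is undefined).
#' @param enzymes `NULL` or data.frame with columns `reaction_id`,
#'   `enzyme_id`, `kcat` (per hour, > 0), `mw` (kDa); one enzyme per reaction
#'   (isoenzymes and complexes are out of scope at toy scale).
#' @return object of class `MetabolicNetwork`.
#' @export
metabolic_network <- function(metabolites, reactions, enzymes = NULL) {
  rids <- vapply(reactions, `[[`, character(1), "id")
  if (anyDuplicated(rids)) stop("duplicate reaction ids", call. = FALSE)
  roles <- vapply(reactions, `[[`, character(1), "role")
  if (sum(roles == "ngam") != 1L)
    stop("network must contain exactly one ATP-hydrolysis (ngam) reaction",
         call. = FALSE)
  if (sum(roles == "biomass") > 1L)
    stop("at most one biomass reaction", call. = FALSE)
  for (r in reactions) {
    bad <- setdiff(names(r$stoich), metabolites$id)
    if (length(bad))
      stop(sprintf("reaction '%s' references unknown metabolites: %s",
                   r$id, paste(bad, collapse = ", ")), call. = FALSE)
    if (r$lb > r$ub)
      stop(sprintf("reaction '%s' has lb > ub", r$id), call. = FALSE)
  }
  if (!is.null(enzymes)) {
    stopifnot(all(c("reaction_id", "enzyme_id", "kcat", "mw") %in%
                    names(enzymes)))
    if (any(is.na(enzymes$kcat)) || any(enzymes$kcat <= 0))
      stop("every enzymatic reaction needs a kcat > 0", call. = FALSE)
    bad <- setdiff(enzymes$reaction_id, rids)
    if (length(bad))
      stop(sprintf("enzyme table references unknown reactions: %s",
                   paste(bad, collapse = ", ")), call. = FALSE)
    if (anyDuplicated(enzymes$reaction_id))
      stop("one enzyme per reaction; isoenzymes unsupported", call. = FALSE)
  }
  structure(list(metabolites = metabolites, reactions = reactions,
                 enzymes = enzymes),
            class = "MetabolicNetwork")
}

#' @export
print.MetabolicNetwork <- function(x, ...) {
  cat(sprintf("MetabolicNetwork: %d metabolites (%d internal), %d reactions, %d enzymes\n",
              nrow(x$metabolites), sum(!x$metabolites$external),
              length(x$reactions),
              if (is.null(x$enzymes)) 0L else nrow(x$enzymes)))
  invisible(x)
}

#' Stoichiometric matrix over internal metabolites
#'
#' @param network a `MetabolicNetwork`.
#' @return dense matrix, internal metabolites x reactions.
#' @export
stoich_matrix <- function(network) {
  mets <- network$metabolites$id[!network$metabolites$external]
  rids <- vapply(network$reactions, `[[`, character(1), "id")
  S <- matrix(0, length(mets), length(rids), dimnames = list(mets, rids))
  for (r in network$reactions) {
    keep <- intersect(names(r$stoich), mets)
    S[keep, r$id] <- r$stoich[keep]
  }
  S
}

reaction_ids <- function(network)
  vapply(network$reactions, `[[`, character(1), "id")

reaction_by_role <- function(network, role) {
  ids <- reaction_ids(network)
  ids[vapply(network$reactions, `[[`, character(1), "role") == role]
}

#' Generate a toy enzyme-constrained network with recorded ground truth
#'
#' Emits a small yeast-like network -- glucose uptake, glycolysis,
#' fermentation and respiration branches, amino-acid uptake, a biomass
#' reaction, a recombinant-protein synthesis/secretion branch, and an
#' ATP-hydrolysis maintenance (NGAM) reaction -- together with a feasible
#' reference flux vector per strain x dilution rate whose NGAM is configured
#' directly. Glucose uptake is then solved from the ATP balance, so the
#' recorded "measured" exchange fluxes are exactly consistent with the
#' configured NGAM.
#'
#' The recorded measured proteome is `e = v_true / (kcat * saturation)` per
#' enzyme, i.e. abundance at the configured average saturation, so
#' `e >= v/kcat` always holds.
#'
#' @param config list overriding any of: `strains`, `dilution_rates`,
#'   `ngam_base` (named by rate, mmol ATP/gDCW/h), `ngam_factor` (named by
#'   strain; strain-specific energy waste), `q_prod` (named by strain,
#'   mmol/gDCW/h), `ferm_frac` (named by rate, fraction of non-biomass
#'   pyruvate fermented), stoichiometric yields (`atp_per_glc`,
#'   `pyr_per_glc`, `atp_per_pyr_resp`, `o2_per_pyr`, `atp_per_x`,
#'   `pyr_per_x`, `aa_per_x`, `aa_per_prod`, `atp_per_prod`), `n_extra`
#'   (decoy side-branches), `saturation`, `include_ngam`.
#' @param seed integer seed (kcats and molecular weights).
#' @return list: `network` (`MetabolicNetwork` with enzymes),
#'   `truth` (list with `conditions` data.frame, `fluxes` reaction x
#'   condition matrix, `ngam` named vector, `proteome` enzyme x condition
#'   matrix in mmol/gDCW), `config`.
#' @export
generate_toy_ecmodel <- function(config = list(), seed = 1L) {
  cfg <- utils::modifyList(list(
    strains = c("AAC", "MH34", "B184"),
    dilution_rates = c(0.1, 0.2),
    ngam_base = c("0.1" = 0.7, "0.2" = 1.0),
    ngam_factor = c(AAC = 1.3, MH34 = 1.4, B184 = 1.0),
    q_prod = c(AAC = 0.010, MH34 = 0.030, B184 = 0.030),
    ferm_frac = c("0.1" = 0.10, "0.2" = 0.35),
    atp_per_glc = 2, pyr_per_glc = 2, atp_per_pyr_resp = 12, o2_per_pyr = 3,
    atp_per_x = 30, pyr_per_x = 1, aa_per_x = 0.5,
    aa_per_prod = 1, atp_per_prod = 4,
    n_extra = 4L, saturation = 0.5, include_ngam = TRUE
  ), config)
  if (!isTRUE(cfg$include_ngam))
    stop("config must include the ATP-hydrolysis reaction; NGAM objective undefined",
         call. = FALSE)
  withr::local_seed(seed)

  mets <- c("glc", "pyr", "atp", "etoh", "o2", "co2", "aa", "prod",
            if (cfg$n_extra > 0) sprintf("x%02d", seq_len(cfg$n_extra)))
  metabolites <- data.frame(id = mets, external = FALSE,
                            stringsAsFactors = FALSE)

  rxns <- list(
    reaction("EX_glc", c(glc = 1), role = "exchange"),
    reaction("EX_o2", c(o2 = 1), role = "exchange"),
    reaction("EX_aa", c(aa = 1), role = "exchange"),
    reaction("EX_etoh", c(etoh = -1), role = "exchange"),
    reaction("EX_co2", c(co2 = -1), role = "exchange"),
    reaction("EX_prod", c(prod = -1), role = "product_secretion"),
    reaction("GLYC", c(glc = -1, pyr = cfg$pyr_per_glc,
                       atp = cfg$atp_per_glc)),
    reaction("FERM", c(pyr = -1, etoh = 1)),
    reaction("RESP", c(pyr = -1, o2 = -cfg$o2_per_pyr,
                       atp = cfg$atp_per_pyr_resp, co2 = cfg$o2_per_pyr)),
    reaction("PROT", c(aa = -cfg$aa_per_prod, atp = -cfg$atp_per_prod,
                       prod = 1)),
    reaction("BIOMASS", c(pyr = -cfg$pyr_per_x, aa = -cfg$aa_per_x,
                          atp = -cfg$atp_per_x), role = "biomass"),
    reaction("NGAM", c(atp = -1), role = "ngam")
  )
  enzymatic <- c("GLYC", "FERM", "RESP", "PROT")
  if (cfg$n_extra > 0) {
    for (i in seq_len(cfg$n_extra)) {
      xm <- sprintf("x%02d", i)
      rxns <- c(rxns, list(
        reaction(sprintf("DECOY%02d", i),
                 stats::setNames(c(-1, 1), c("pyr", xm))),
        reaction(sprintf("EX_x%02d", i),
                 stats::setNames(-1, xm), role = "exchange")))
      enzymatic <- c(enzymatic, sprintf("DECOY%02d", i))
    }
  }
  enzymes <- data.frame(
    reaction_id = enzymatic,
    enzyme_id = paste0("E_", enzymatic),
    kcat = 10 ^ stats::runif(length(enzymatic), 3, 5),
    mw = stats::runif(length(enzymatic), 30, 150),
    stringsAsFactors = FALSE)

  network <- metabolic_network(metabolites, rxns, enzymes)
  rids <- reaction_ids(network)

  conditions <- expand.grid(dilution_rate = cfg$dilution_rates,
                            strain = cfg$strains,
                            KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  conditions <- conditions[, c("strain", "dilution_rate")]
  conditions$condition_id <- sprintf("%s_%g", conditions$strain,
                                     conditions$dilution_rate)

  fluxes <- matrix(0, length(rids), nrow(conditions),
                   dimnames = list(rids, conditions$condition_id))
  ngam_true <- stats::setNames(numeric(nrow(conditions)),
                               conditions$condition_id)
  for (i in seq_len(nrow(conditions))) {
    D <- conditions$dilution_rate[i]
    strain <- conditions$strain[i]
    phi <- cfg$ferm_frac[[as.character(D)]]
    qp <- cfg$q_prod[[strain]]
    ngam <- cfg$ngam_base[[as.character(D)]] * cfg$ngam_factor[[strain]]
    demand <- cfg$atp_per_x * D + cfg$atp_per_prod * qp + ngam
    # atp balance: atp_per_glc*G + atp_per_pyr_resp*R = demand
    # pyr balance: pyr_per_glc*G = pyr_per_x*D + F + R,  F = phi/(1-phi)*R
    apg <- cfg$atp_per_glc / cfg$pyr_per_glc
    R <- (demand - apg * cfg$pyr_per_x * D) /
      (cfg$atp_per_pyr_resp + apg / (1 - phi))
    if (R < 0) stop("infeasible toy configuration: ATP demand below baseline",
                    call. = FALSE)
    FF <- phi / (1 - phi) * R
    G <- (cfg$pyr_per_x * D + FF + R) / cfg$pyr_per_glc
    v <- stats::setNames(numeric(length(rids)), rids)
    v["EX_glc"] <- G
    v["GLYC"] <- G
    v["FERM"] <- FF
    v["EX_etoh"] <- FF
    v["RESP"] <- R
    v["EX_o2"] <- cfg$o2_per_pyr * R
    v["EX_co2"] <- cfg$o2_per_pyr * R
    v["BIOMASS"] <- D
    v["PROT"] <- qp
    v["EX_prod"] <- qp
    v["EX_aa"] <- cfg$aa_per_x * D + cfg$aa_per_prod * qp
    v["NGAM"] <- ngam
    fluxes[, i] <- v
    ngam_true[i] <- ngam
  }

  proteome <- matrix(0, nrow(enzymes), nrow(conditions),
                     dimnames = list(enzymes$enzyme_id,
                                     conditions$condition_id))
  for (j in seq_len(nrow(conditions))) {
    proteome[, j] <- fluxes[enzymes$reaction_id, j] /
      (enzymes$kcat * cfg$saturation)
  }

  list(network = network,
       truth = list(conditions = conditions, fluxes = fluxes,
                    ngam = ngam_true, proteome = proteome),
       config = c(cfg, list(seed = seed)))
}

#' Simulate chemostat measurement records consistent with the toy-model truth
#'
#' For each strain x rate condition of the toy truth, emits replicate
#' measurement records (biomass, product titer, feed/residual concentrations
#' for glucose, 14 amino acids, and ethanol) whose steady-state mass balances
#' return the toy model's true exchange fluxes up to the configured
#' measurement noise.
#'
#' @param toy output of [generate_toy_ecmodel()].
#' @param n_replicates biological replicates per condition.
#' @param biomass_conc dry-weight concentration (g/L).
#' @param glc_feed glucose feed concentration (mmol/L).
#' @param aa_feed per-amino-acid feed concentration (mmol/L; 14 compounds).
#' @param product_mw product molecular weight (kDa), converts mmol to mg.
#' @param noise_sd log10-scale measurement noise SD on derived quantities.
#' @param seed integer seed.
#' @return list of `ChemostatRecord`s.
#' @export
simulate_chemostat <- function(toy, n_replicates = 2L, biomass_conc = 3.5,
                               glc_feed = 41.6, aa_feed = 1.0,
                               product_mw = 54.4, noise_sd = 0.01,
                               seed = 1L) {
  withr::local_seed(seed)
  aa_names <- c("Arg", "Asp", "Glu", "Gly", "His", "Ile", "Leu", "Lys",
                "Met", "Phe", "Thr", "Trp", "Tyr", "Val")
  conds <- toy$truth$conditions
  jitter <- function(x) if (noise_sd == 0) x else
    x * 10 ^ stats::rnorm(length(x), 0, noise_sd)
  records <- list()
  for (i in seq_len(nrow(conds))) {
    D <- conds$dilution_rate[i]
    v <- toy$truth$fluxes[, conds$condition_id[i]]
    for (r in seq_len(n_replicates)) {
      X <- jitter(biomass_conc)
      q_aa_each <- v[["EX_aa"]] / length(aa_names)
      feed <- c(glc = glc_feed,
                stats::setNames(rep(aa_feed, length(aa_names)), aa_names),
                etoh = 0)
      residual <- c(glc = max(0, glc_feed - jitter(v[["EX_glc"]]) * X / D),
                    stats::setNames(
                      pmax(0, aa_feed - jitter(rep(q_aa_each,
                                                   length(aa_names))) * X / D),
                      aa_names),
                    etoh = jitter(v[["EX_etoh"]]) * X / D)
      titer <- jitter(v[["EX_prod"]]) * product_mw * X / D
      records[[length(records) + 1L]] <-
        chemostat_record(conds$strain[i], D, X, feed, residual,
                         product_titer = titer, replicate = r)
    }
  }
  records
}

#' Average measured exchange rates into an ecModel constraint table
#'
#' Maps chemostat records of one strain x rate onto the toy network's
#' exchange reactions: glucose -> `EX_glc` (uptake), summed amino acids ->
#' `EX_aa` (uptake), ethanol -> `EX_etoh` (secretion), product titer ->
#' `EX_prod` (secretion, converted from mg via the product molecular weight).
#'
#' @param records list of `ChemostatRecord`s (replicates of one condition).
#' @param product_mw product molecular weight (kDa).
#' @return data.frame: reaction_id, direction, rate (mmol/gDCW/h).
#' @export
exchange_rates_from_records <- function(records, product_mw = 54.4) {
  per_rec <- lapply(records, function(rec) {
    aa <- setdiff(names(rec$feed), c("glc", "etoh"))
    c(EX_glc = specific_rate(rec, "glc", "uptake"),
      EX_aa = sum(vapply(aa, function(cp) specific_rate(rec, cp, "uptake"),
                         numeric(1))),
      EX_etoh = specific_rate(rec, "etoh", "secretion"),
      EX_prod = rec$dilution_rate * rec$product_titer / product_mw /
        rec$biomass)
  })
  m <- rowMeans(do.call(cbind, per_rec))
  data.frame(reaction_id = names(m),
             direction = c("uptake", "uptake", "secretion", "secretion"),
             rate = unname(m), stringsAsFactors = FALSE)
}
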