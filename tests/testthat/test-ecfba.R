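one_enzyme_net <- function(kcat = 100, mw = 50, ub = 1000) {
  mets <- data.frame(id = c("A", "atp"), external = FALSE,
                     stringsAsFactors = FALSE)
  rxns <- list(reaction("EX_A", c(A = 1), role = "exchange"),
               reaction("CAT", c(A = -1, atp = 1)),
               reaction("NGAM", c(atp = -1), role = "ngam"))
  metabolic_network(mets, rxns,
                    data.frame(reaction_id = "CAT", enzyme_id = "E1",
                               kcat = kcat, mw = mw,
                               stringsAsFactors = FALSE))
}

test_that("a single enzyme is limited by pool algebra, and f=0 shuts it off", {
  net <- one_enzyme_net(kcat = 200, mw = 40)
  model <- build_ec_model(net, p_total = 0.46, f = 0.5, sigma = 0.5)
  sol <- fba(model, "CAT", "max")
  e_max <- 0.46 * 0.5 * 0.5 / 40
  expect_equal(sol$objective_value, 200 * e_max, tolerance = 1e-9)
  expect_equal(sol$status, "optimal")

  zero <- build_ec_model(net, p_total = 0.46, f = 0, sigma = 0.5)
  expect_equal(fba(zero, "CAT", "max")$objective_value, 0, tolerance = 1e-12)
})

test_that("the constraint matrix equals an independently assembled oracle", {
  toy <- generate_toy_ecmodel(seed = 5)
  model <- build_ec_model(toy$network, p_total = 0.46, f = 0.5, sigma = 0.5)
  lp <- ec_lp_matrices(model)

  # oracle: dense assembly straight from the network definition
  net <- toy$network
  rids <- vapply(net$reactions, `[[`, character(1), "id")
  enz <- net$enzymes
  vars <- c(rids, enz$enzyme_id)
  mets <- net$metabolites$id
  Aeq <- matrix(0, length(mets), length(vars),
                dimnames = list(mets, vars))
  for (r in net$reactions) Aeq[names(r$stoich), r$id] <- r$stoich
  expect_equal(unname(lp$A_eq), unname(Aeq[rownames(lp$A_eq), ]))

  ncoup <- nrow(enz)
  Aub <- matrix(0, ncoup + 1, length(vars), dimnames = list(NULL, vars))
  for (k in seq_len(ncoup)) {
    Aub[k, enz$reaction_id[k]] <- 1
    Aub[k, enz$enzyme_id[k]] <- -enz$kcat[k]
  }
  Aub[ncoup + 1, enz$enzyme_id] <- enz$mw
  # rows may be ordered differently; compare as sorted row sets
  canon <- function(m) m[do.call(order, as.data.frame(m)), ]
  expect_equal(canon(unname(lp$A_ub[, vars])), canon(unname(Aub)))
  expect_equal(unname(sort(lp$b_ub)),
               sort(c(rep(0, ncoup), 0.46 * 0.5 * 0.5)), tolerance = 1e-12)

  no_enz <- metabolic_network(net$metabolites,
                              net$reactions[!rids %in% enz$reaction_id],
                              NULL)
  expect_error(build_ec_model(no_enz), "no enzyme table")
})

test_that("proteomics bounds only ever tighten the optimum", {
  toy <- generate_toy_ecmodel(seed = 6)
  model <- build_ec_model(toy$network)
  base <- fba(model, "NGAM", "max")$objective_value
  capped <- apply_proteomics(model, toy$truth$proteome[, 1])
  after <- fba(capped, "NGAM", "max")$objective_value
  expect_lte(after, base + 1e-9)

  # zero abundance on the only catabolic enzyme kills the objective
  net <- one_enzyme_net()
  m <- apply_proteomics(build_ec_model(net), c(E1 = 0))
  sol <- fba(m, "NGAM", "max")
  expect_true(sol$status == "infeasible" ||
                abs(sol$objective_value) < 1e-12)

  expect_error(apply_proteomics(model, c(E_GLYC = -1)), "negative")
})

test_that("truth-implied proteomics keeps the true flux vector feasible", {
  toy <- generate_toy_ecmodel(seed = 7)
  model <- build_ec_model(toy$network)
  for (cid in colnames(toy$truth$fluxes)) {
    m <- apply_proteomics(model, toy$truth$proteome[, cid])
    v <- toy$truth$fluxes[, cid]
    enz <- toy$network$enzymes
    e_needed <- v[enz$reaction_id] / enz$kcat
    expect_true(all(e_needed <= m$ub[enz$enzyme_id] + 1e-12))
    expect_true(all(v >= m$lb[names(v)] - 1e-12 &
                      v <= m$ub[names(v)] + 1e-12))
  }
})

test_that("exchange windows apply the flexibility factor arithmetic", {
  toy <- generate_toy_ecmodel(seed = 8)
  model <- build_ec_model(toy$network)
  rates <- data.frame(reaction_id = "EX_etoh", rate = 2.0,
                      direction = "secretion")
  m <- apply_exchange_constraints(model, rates, flex = 1.03)
  expect_equal(unname(m$lb["EX_etoh"]), 2 / 1.03, tolerance = 1e-12)
  expect_equal(unname(m$ub["EX_etoh"]), 2.06, tolerance = 1e-12)

  rigid <- apply_exchange_constraints(model, rates, flex = 1)
  expect_equal(unname(rigid$lb["EX_etoh"]), 2)
  expect_equal(unname(rigid$ub["EX_etoh"]), 2)

  one_sided <- apply_exchange_constraints(model, rates, flex = 1.03,
                                          two_sided = FALSE)
  expect_equal(unname(one_sided$lb["EX_etoh"]), 2)

  bad <- data.frame(reaction_id = "GLYC", rate = 1, direction = "uptake")
  expect_error(apply_exchange_constraints(model, bad), "unknown exchange")
})

test_that("solved exchange fluxes stay inside the flex window of truth", {
  toy <- generate_toy_ecmodel(seed = 9)
  recs <- simulate_chemostat(toy, noise_sd = 0, seed = 10)
  cid <- "B184_0.1"
  r1 <- Filter(function(r) r$strain == "B184" && r$dilution_rate == 0.1,
               recs)
  rates <- exchange_rates_from_records(r1)
  model <- build_ec_model(toy$network)
  model <- apply_proteomics(model, toy$truth$proteome[, cid])
  model <- apply_exchange_constraints(model, rates, flex = 1.03)
  sol <- solve_ngam(model, 0.1)
  expect_equal(sol$status, "optimal")
  check_solution(model, sol)
  v <- toy$truth$fluxes[, cid]
  for (rid in rates$reaction_id) {
    expect_gte(sol$fluxes[rid], v[rid] / 1.03 - 1e-8)
    expect_lte(sol$fluxes[rid], v[rid] * 1.03 + 1e-8)
  }
})

test_that("starvation makes fixed growth infeasible", {
  toy <- generate_toy_ecmodel(seed = 12)
  model <- build_ec_model(toy$network)
  rates <- data.frame(reaction_id = "EX_glc", rate = 0, direction = "uptake")
  m <- apply_exchange_constraints(model, rates, flex = 1)
  sol <- solve_ngam(m, 0.1)
  expect_equal(sol$status, "infeasible")
})

test_that("fba attains simple bound optima and flags free objectives", {
  net <- one_enzyme_net()
  mets <- data.frame(id = c("A", "atp"), external = FALSE,
                     stringsAsFactors = FALSE)
  rxns <- list(reaction("EX_A", c(A = 1), ub = 5, role = "exchange"),
               reaction("CAT", c(A = -1, atp = 1)),
               reaction("NGAM", c(atp = -1), role = "ngam"))
  m <- build_ec_model(metabolic_network(mets, rxns, net$enzymes),
                      p_total = 100)
  expect_equal(fba(m, "EX_A", "max")$objective_value, 5, tolerance = 1e-9)
  expect_equal(fba(m, "EX_A", "min")$objective_value, 0, tolerance = 1e-12)

  # nothing limits uptake in the default-capped model: reported unbounded
  free <- build_ec_model(one_enzyme_net(kcat = 1e8), p_total = 100)
  expect_equal(fba(free, "EX_A", "max")$status, "unbounded")

  expect_error(fba(m, "NOPE", "max"), "not in model")
})

test_that("LP objectives match exhaustive vertex enumeration on small models", {
  for (s in 1:25) {
    model <- random_small_ec_network(s)
    sol <- fba(model, "NGAM", "max")
    oracle <- oracle_ec_objective(model, "NGAM", maximize = TRUE)
    expect_equal(sol$status == "optimal" || sol$status == "unbounded",
                 oracle$feasible)
    if (sol$status == "optimal") {
      expect_lt(abs(sol$objective_value - oracle$objective), 1e-7)
      check_solution(model, sol)
    }
  }
})

test_that("solve_ngam matches the oracle with growth pinned", {
  for (s in 1:15) {
    model <- random_small_ec_network(100 + s)
    withr::local_seed(300 + s)
    D <- stats::runif(1, 0, 0.05)
    sol <- solve_ngam(model, D)
    oracle <- oracle_ec_objective(model, "NGAM", maximize = TRUE,
                                  dilution_rate = D)
    if (sol$status == "optimal") {
      expect_true(oracle$feasible)
      expect_lt(abs(sol$objective_value - oracle$objective), 1e-7)
      check_solution(model, sol)
      resid <- max(abs(model$A_eq %*% c(sol$fluxes,
                                        sol$enzymes)[model$var_names]))
      expect_lt(resid, 1e-8)
    } else {
      expect_false(oracle$feasible)
    }
  }
})

test_that("relaxing proteomics bounds or flex never decreases NGAM", {
  toy <- generate_toy_ecmodel(seed = 30)
  recs <- simulate_chemostat(toy, noise_sd = 0, seed = 31)
  cid <- "MH34_0.2"
  r1 <- Filter(function(r) r$strain == "MH34" && r$dilution_rate == 0.2,
               recs)
  rates <- exchange_rates_from_records(r1)
  base_model <- build_ec_model(toy$network)
  base_model <- apply_proteomics(base_model, toy$truth$proteome[, cid])
  m0 <- apply_exchange_constraints(base_model, rates, flex = 1.01)
  base <- solve_ngam(m0, 0.2)$objective_value
  withr::local_seed(32)
  for (i in 1:30) {
    if (i %% 2 == 0) {
      enzyme <- sample(base_model$enzyme_ids, 1)
      m <- m0
      m$ub[enzyme] <- m$ub[enzyme] * stats::runif(1, 1, 10)
    } else {
      m <- apply_exchange_constraints(base_model, rates,
                                      flex = 1.01 + stats::runif(1, 0, 0.1))
    }
    expect_gte(solve_ngam(m, 0.2)$objective_value, base - 1e-9)
  }
})

test_that("reversible enzymatic reactions split into coupled halves", {
  mets <- data.frame(id = c("A", "B", "atp"), external = FALSE,
                     stringsAsFactors = FALSE)
  rxns <- list(reaction("EX_A", c(A = 1), ub = 3, role = "exchange"),
               reaction("ISO", c(A = -1, B = 1), lb = -1000,
                        reversible = TRUE),
               reaction("CAT", c(B = -1, atp = 1)),
               reaction("NGAM", c(atp = -1), role = "ngam"))
  enz <- data.frame(reaction_id = c("ISO", "CAT"),
                    enzyme_id = c("E_iso", "E_cat"),
                    kcat = c(1e3, 1e3), mw = c(50, 50),
                    stringsAsFactors = FALSE)
  model <- build_ec_model(metabolic_network(mets, rxns, enz), p_total = 10)
  expect_true(all(c("ISO_fwd", "ISO_bwd") %in% model$flux_ids))
  sol <- fba(model, "NGAM", "max")
  expect_equal(sol$objective_value, 3, tolerance = 1e-9)
})
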