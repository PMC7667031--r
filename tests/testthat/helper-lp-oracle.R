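# Exhaustive vertex-enumeration oracle for small LPs, independent of the
# package's simplex: enumerate every basis of the slack-augmented standard
# form, keep basic solutions that are feasible, and report the best
# objective over them.

enumerate_lp_objective <- function(cvec, A_eq, b_eq, A_ub, b_ub, lb, ub,
                                   maximize = TRUE) {
  n <- length(cvec)
  beq <- as.numeric(b_eq - A_eq %*% lb)
  fin <- which(is.finite(ub))
  Aub_all <- rbind(A_ub, diag(n)[fin, , drop = FALSE])
  bub_all <- c(as.numeric(b_ub - A_ub %*% lb), (ub - lb)[fin])
  m_eq <- nrow(A_eq); m_ub <- nrow(Aub_all)
  M <- cbind(rbind(A_eq, Aub_all),
             rbind(matrix(0, m_eq, m_ub), diag(m_ub)))
  b <- c(beq, bub_all)
  m <- nrow(M); nt <- ncol(M)
  stopifnot(choose(nt, m) < 2e5)  # keep the oracle exhaustive but tractable
  best <- if (maximize) -Inf else Inf
  feasible <- FALSE
  for (cols in utils::combn(nt, m, simplify = FALSE)) {
    B <- M[, cols, drop = FALSE]
    x_b <- tryCatch(solve(B, b), error = function(e) NULL)
    if (is.null(x_b) || anyNA(x_b)) next
    if (max(abs(B %*% x_b - b)) > 1e-7) next
    if (any(x_b < -1e-9)) next
    x <- numeric(nt)
    x[cols] <- x_b
    obj <- sum(cvec * (x[seq_len(n)] + lb))
    feasible <- TRUE
    best <- if (maximize) max(best, obj) else min(best, obj)
  }
  list(feasible = feasible, objective = best)
}

# oracle applied to an EcModel via its exposed constraint contract
oracle_ec_objective <- function(model, objective_reaction, maximize = TRUE,
                                dilution_rate = NULL) {
  if (!is.null(dilution_rate)) {
    bio <- omniflux:::reaction_by_role(model$network, "biomass")
    model$lb[bio] <- dilution_rate
    model$ub[bio] <- dilution_rate
  }
  lp <- ec_lp_matrices(model)
  cvec <- stats::setNames(rep(0, length(lp$var_names)), lp$var_names)
  cvec[objective_reaction] <- 1
  enumerate_lp_objective(cvec, lp$A_eq, lp$b_eq, lp$A_ub, lp$b_ub,
                         lp$lb, lp$ub, maximize = maximize)
}

# random two-metabolite ec-networks, small enough for full enumeration
random_small_ec_network <- function(seed) {
  withr::local_seed(seed)
  two_branch <- stats::runif(1) < 0.5
  mets <- data.frame(id = c("A", "atp"), external = FALSE,
                     stringsAsFactors = FALSE)
  rxns <- list(
    reaction("EX_A", c(A = 1), ub = stats::runif(1, 0.5, 2),
             role = "exchange"),
    reaction("CONV", c(A = -1, atp = stats::runif(1, 2, 12))),
    reaction("NGAM", c(atp = -1), role = "ngam"),
    reaction("BIOMASS", c(atp = -stats::runif(1, 5, 20)), role = "biomass"))
  enz <- data.frame(reaction_id = "CONV", enzyme_id = "E1",
                    kcat = 10 ^ stats::runif(1, 2, 4),
                    mw = stats::runif(1, 30, 150), stringsAsFactors = FALSE)
  if (two_branch) {
    rxns <- c(rxns, list(reaction("FERM",
                                  c(A = -1, atp = stats::runif(1, 1, 6)))))
    enz <- rbind(enz, data.frame(reaction_id = "FERM", enzyme_id = "E2",
                                 kcat = 10 ^ stats::runif(1, 2, 4),
                                 mw = stats::runif(1, 30, 150),
                                 stringsAsFactors = FALSE))
  }
  build_ec_model(metabolic_network(mets, rxns, enz),
                 p_total = stats::runif(1, 0.2, 0.6))
}
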