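#' Build an enzyme-constrained model from a metabolic network
#'
#' GECKO-style mathematical form: the LP variables are the reaction fluxes
#' plus one enzyme-usage variable per enzymatic reaction (mmol enzyme/gDCW).
#' Constraints are steady state (`S v = 0` over internal metabolites), flux
#' bounds, kcat coupling (`v <= kcat * e`), and the shared enzyme pool
#' `sum(MW_i * e_i) <= P_total * f * sigma` (kDa x mmol/gDCW = g/gDCW).
#' Reversible enzymatic reactions are split into forward/backward halves,
#' both coupled to the same enzyme.
#'
#' @param network a `MetabolicNetwork` with an enzyme table.
#' @param p_total total cell protein content (g protein/gDCW).
#' @param f mass fraction of the proteome available to metabolic enzymes
#'   (default 0.5, the conventional choice when the pool is constrained).
#' @param sigma average enzyme saturation (default 0.5).
#' @return object of class `EcModel`.
#' @export
build_ec_model <- function(network, p_total = 0.46, f = 0.5, sigma = 0.5) {
  stopifnot(inherits(network, "MetabolicNetwork"))
  if (is.null(network$enzymes) || nrow(network$enzymes) == 0L)
    stop("network has no enzyme table; cannot build an ecModel", call. = FALSE)

  # split reversible enzymatic reactions
  rxns <- list()
  enz <- network$enzymes
  split_map <- list()
  for (r in network$reactions) {
    is_enz <- r$id %in% enz$reaction_id
    if (r$reversible && is_enz) {
      fwd <- r; fwd$id <- paste0(r$id, "_fwd")
      fwd$lb <- 0; fwd$ub <- r$ub; fwd$reversible <- FALSE
      bwd <- r; bwd$id <- paste0(r$id, "_bwd")
      bwd$stoich <- -r$stoich
      bwd$lb <- 0; bwd$ub <- if (r$lb < 0) -r$lb else 0
      bwd$reversible <- FALSE
      rxns <- c(rxns, list(fwd, bwd))
      split_map[[r$id]] <- c(fwd$id, bwd$id)
    } else {
      rxns <- c(rxns, list(r))
      split_map[[r$id]] <- r$id
    }
  }

  rids <- vapply(rxns, `[[`, character(1), "id")
  enzyme_ids <- unique(enz$enzyme_id)
  var_names <- c(rids, enzyme_ids)
  n_flux <- length(rids)
  n_enz <- length(enzyme_ids)

  lb <- c(vapply(rxns, `[[`, numeric(1), "lb"), rep(0, n_enz))
  pool_cap <- p_total * f * sigma
  mw <- enz$mw[match(enzyme_ids, enz$enzyme_id)]
  ub_enz <- if (pool_cap > 0) pool_cap / mw else rep(0, n_enz)
  ub <- c(vapply(rxns, `[[`, numeric(1), "ub"), ub_enz)
  names(lb) <- names(ub) <- var_names
  ub_default <- c(vapply(rxns, function(r) isTRUE(r$ub_is_default),
                         logical(1)), rep(FALSE, n_enz))

  mets <- network$metabolites$id[!network$metabolites$external]
  A_eq <- matrix(0, length(mets), length(var_names),
                 dimnames = list(mets, var_names))
  for (r in rxns) {
    keep <- intersect(names(r$stoich), mets)
    A_eq[keep, r$id] <- r$stoich[keep]
  }
  b_eq <- rep(0, length(mets))

  # coupling rows: v - kcat * e <= 0, one per (split) enzymatic flux
  coup <- list()
  for (k in seq_len(nrow(enz))) {
    for (fid in split_map[[enz$reaction_id[k]]]) {
      row <- stats::setNames(rep(0, length(var_names)), var_names)
      row[fid] <- 1
      row[enz$enzyme_id[k]] <- -enz$kcat[k]
      coup[[paste0("cap_", fid)]] <- row
    }
  }
  A_ub <- do.call(rbind, coup)
  pool_row <- stats::setNames(rep(0, length(var_names)), var_names)
  pool_row[enzyme_ids] <- mw
  A_ub <- rbind(A_ub, pool = pool_row)
  b_ub <- c(rep(0, length(coup)), pool_cap)
  names(b_ub) <- rownames(A_ub)

  # enzyme columns are solved in capacity units (kcat * e) internally so the
  # LP is well scaled; the exposed matrices stay in canonical (v, e) form
  var_scale <- stats::setNames(rep(1, length(var_names)), var_names)
  var_scale[enzyme_ids] <- 1 / enz$kcat[match(enzyme_ids, enz$enzyme_id)]

  structure(list(network = network, var_names = var_names,
                 flux_ids = rids, enzyme_ids = enzyme_ids,
                 lb = lb, ub = ub, ub_default = ub_default,
                 A_eq = A_eq, b_eq = b_eq, A_ub = A_ub, b_ub = b_ub,
                 var_scale = var_scale,
                 params = list(p_total = p_total, f = f, sigma = sigma)),
            class = "EcModel")
}

#' @export
print.EcModel <- function(x, ...) {
  cat(sprintf("EcModel: %d fluxes + %d enzyme usages; pool cap %.4g g/gDCW (f=%.2g, sigma=%.2g)\n",
              length(x$flux_ids), length(x$enzyme_ids),
              x$params$p_total * x$params$f * x$params$sigma,
              x$params$f, x$params$sigma))
  invisible(x)
}

#' The dense LP pieces of an ecModel
#'
#' Exposes the assembled constraint system (equalities, inequalities, bounds)
#' for inspection and for cross-checks against independently assembled
#' matrices.
#'
#' @param model an `EcModel`.
#' @return list: `A_eq`, `b_eq`, `A_ub`, `b_ub`, `lb`, `ub`, `var_names`.
#' @export
ec_lp_matrices <- function(model) {
  model[c("A_eq", "b_eq", "A_ub", "b_ub", "lb", "ub", "var_names")]
}

#' Bound enzyme usages by measured absolute proteomics
#'
#' `e_i <= measured_i` for every enzyme present in the data; unmeasured
#' enzymes stay limited only by the pool. Measurements must already be in
#' model units (mmol enzyme/gDCW); see [protein_to_usage_units()] for the
#' conversion chain from molar cellular abundances.
#'
#' @param model an `EcModel`.
#' @param protein_abs named numeric vector of enzyme abundances
#'   (mmol/gDCW), or an `AbundanceMatrix` with units `mmol_per_gdcw` and
#'   enzyme ids as gene ids.
#' @param sample sample/condition column when `protein_abs` is a matrix.
#' @return the constrained `EcModel`.
#' @export
apply_proteomics <- function(model, protein_abs, sample = NULL) {
  stopifnot(inherits(model, "EcModel"))
  if (inherits(protein_abs, "AbundanceMatrix")) {
    if (protein_abs$units != "mmol_per_gdcw")
      stop("proteomics must be in mmol_per_gdcw model units", call. = FALSE)
    v <- ab_values(protein_abs)[, sample]
  } else {
    v <- protein_abs
  }
  if (is.null(names(v))) stop("abundances must be named by enzyme", call. = FALSE)
  if (any(v < 0, na.rm = TRUE))
    stop("negative enzyme abundance", call. = FALSE)
  v <- v[!is.na(v)]
  hit <- intersect(names(v), model$enzyme_ids)
  model$ub[hit] <- pmin(model$ub[hit], v[hit])
  model$lb[hit] <- pmin(model$lb[hit], model$ub[hit])
  model
}

#' Convert molar cellular protein abundances to enzyme-usage units
#'
#' molecules/cell -> mmol/gDCW via Avogadro's number and the cell density
#' (cells per gram dry weight). Documented unit chain:
#' `mmol/gDCW = molecules/cell * cells_per_gdcw / (6.02214076e23 * 1e-3)`.
#'
#' @param abundances `AbundanceMatrix` in `molecules_per_cell` units.
#' @param cells_per_gdcw cells per gram dry cell weight.
#' @return `AbundanceMatrix` in `mmol_per_gdcw` units.
#' @export
protein_to_usage_units <- function(abundances, cells_per_gdcw = 2.5e13) {
  stopifnot(inherits(abundances, "AbundanceMatrix"))
  if (abundances$units != "molecules_per_cell")
    stop("expected molecules_per_cell units", call. = FALSE)
  vals <- ab_values(abundances) * cells_per_gdcw / 6.02214076e20
  abundance_matrix(vals, abundances$layer, "mmol_per_gdcw")
}

#' Constrain measured exchange fluxes with a flexibility window
#'
#' Each measured exchange flux is bounded within
#' `[measured / flex, measured * flex]` in its declared direction (or
#' `[measured, measured * flex]` one-sided), so the LP is not overconstrained
#' by measurement error. The conventional flexibility factor is 1.03.
#'
#' @param model an `EcModel`.
#' @param rates data.frame with columns `reaction_id`, `rate`
#'   (mmol/gDCW/h, magnitude in the declared direction), `direction`.
#' @param flex flexibility factor (>= 1).
#' @param two_sided logical; `FALSE` keeps the measured value as the lower
#'   edge.
#' @return the constrained `EcModel`.
#' @export
apply_exchange_constraints <- function(model, rates, flex = 1.03,
                                       two_sided = TRUE) {
  stopifnot(inherits(model, "EcModel"))
  if (flex < 1) stop("flex must be >= 1", call. = FALSE)
  roles <- vapply(model$network$reactions, `[[`, character(1), "role")
  exch <- reaction_ids(model$network)[roles %in%
                                        c("exchange", "product_secretion")]
  for (i in seq_len(nrow(rates))) {
    rid <- rates$reaction_id[i]
    if (!rid %in% exch)
      stop(sprintf("rate given for unknown exchange reaction '%s'", rid),
           call. = FALSE)
    m <- rates$rate[i]
    model$lb[rid] <- if (two_sided) m / flex else m
    model$ub[rid] <- m * flex
    model$ub_default[match(rid, model$var_names)] <- FALSE
  }
  model
}

# Solve the model LP with the package's two-phase simplex: columns rescaled
# by var_scale (enzymes in capacity units), variables shifted to
# x = z - lb >= 0, finite upper bounds materialized as rows, and each
# inequality row normalized to unit max coefficient.
solve_model_lp <- function(model, objective_coef, maximize = TRUE) {
  s <- model$var_scale
  n <- length(s)
  lb <- model$lb / s
  ub <- model$ub / s
  cvec <- objective_coef * s
  A_eq <- sweep(model$A_eq, 2, s, `*`)
  A_ub <- sweep(model$A_ub, 2, s, `*`)

  A_up <- rbind(A_ub, diag(n))
  b_up <- c(model$b_ub, ub)
  keep <- is.finite(b_up)
  A_up <- A_up[keep, , drop = FALSE]
  b_up <- b_up[keep]

  b1 <- b_up - as.numeric(A_up %*% lb)
  rs <- pmax(apply(abs(A_up), 1, max), 1e-12)
  A_up <- A_up / rs
  b1 <- b1 / rs

  b3 <- model$b_eq - as.numeric(A_eq %*% lb)
  A3 <- A_eq
  flip <- b3 < 0
  A3[flip, ] <- -A3[flip, , drop = FALSE]
  b3[flip] <- -b3[flip]

  neg <- b1 < -1e-12
  A1 <- A_up[!neg, , drop = FALSE]; bb1 <- pmax(b1[!neg], 0)
  A2 <- -A_up[neg, , drop = FALSE]; bb2 <- -b1[neg]

  res <- solve_lp(cvec,
                  A1 = if (nrow(A1)) A1 else NULL,
                  b1 = if (nrow(A1)) bb1 else NULL,
                  A2 = if (nrow(A2)) A2 else NULL,
                  b2 = if (nrow(A2)) bb2 else NULL,
                  A3 = if (nrow(A3)) A3 else NULL,
                  b3 = if (nrow(A3)) b3 else NULL,
                  maximize = maximize)
  if (res$status != "optimal") return(list(status = res$status))
  x <- (res$x + lb) * s
  names(x) <- model$var_names
  list(status = "optimal", x = x,
       value = sum(objective_coef * x))
}

#' Flux balance analysis on an enzyme-constrained model
#'
#' Linear program over fluxes and enzyme usages; deterministic up to solver
#' tolerance. The objective value is unique and contract-bearing; the flux
#' vector may be degenerate.
#'
#' @param model an `EcModel`.
#' @param objective_reaction flux variable to optimize.
#' @param sense `"max"` or `"min"`.
#' @return object of class `FluxSolution`: `status` (`optimal`,
#'   `infeasible`, `unbounded`), `fluxes`, `enzymes`, `objective_value`.
#'   `unbounded` is reported when the optimum rides the default (never
#'   user-set) flux cap, i.e. nothing in the model limits the objective.
#' @export
fba <- function(model, objective_reaction, sense = c("max", "min")) {
  sense <- match.arg(sense)
  stopifnot(inherits(model, "EcModel"))
  j <- match(objective_reaction, model$var_names)
  if (is.na(j))
    stop(sprintf("objective reaction '%s' not in model", objective_reaction),
         call. = FALSE)
  cvec <- stats::setNames(rep(0, length(model$var_names)), model$var_names)
  cvec[j] <- 1
  sol <- solve_model_lp(model, cvec, maximize = (sense == "max"))
  if (sol$status != "optimal") {
    return(structure(list(status = sol$status, fluxes = NULL, enzymes = NULL,
                          objective_value = NA_real_,
                          objective = objective_reaction),
                     class = "FluxSolution"))
  }
  status <- "optimal"
  if (sense == "max" && model$ub_default[j] &&
      sol$x[j] >= model$ub[j] - 1e-6)
    status <- "unbounded"
  structure(list(status = status,
                 fluxes = sol$x[model$flux_ids],
                 enzymes = sol$x[model$enzyme_ids],
                 objective_value = sol$value,
                 objective = objective_reaction),
            class = "FluxSolution")
}

#' @export
print.FluxSolution <- function(x, ...) {
  cat(sprintf("FluxSolution [%s]: %s = %s\n", x$status, x$objective,
              format(x$objective_value)))
  invisible(x)
}

#' Maximize maintenance ATP hydrolysis at a fixed growth rate
#'
#' Fixes the biomass flux to the dilution rate (chemostat steady state forces
#' growth = D) and maximizes the flux through the ATP-hydrolysis maintenance
#' reaction -- the NGAM proxy for accessory energy expenditure. Maximization
#' absorbs the surplus catabolic capacity the measured exchange fluxes allow
#' beyond growth.
#'
#' @param model an `EcModel` (typically after [apply_proteomics()] and
#'   [apply_exchange_constraints()]).
#' @param dilution_rate growth rate to pin the biomass reaction to; `NULL`
#'   leaves growth free (e.g. toy chains without a biomass reaction).
#' @return a `FluxSolution`; the objective value is the NGAM flux
#'   (mmol ATP/gDCW/h).
#' @export
solve_ngam <- function(model, dilution_rate = NULL) {
  stopifnot(inherits(model, "EcModel"))
  ngam_id <- reaction_by_role(model$network, "ngam")
  if (!is.null(dilution_rate)) {
    bio <- reaction_by_role(model$network, "biomass")
    if (length(bio) != 1L)
      stop("no biomass reaction; cannot fix growth", call. = FALSE)
    # split-aware: biomass is never enzymatic-reversible here
    model$lb[bio] <- dilution_rate
    model$ub[bio] <- dilution_rate
    model$ub_default[match(bio, model$var_names)] <- FALSE
  }
  fba(model, ngam_id, "max")
}

#' Verify a flux solution against the model constraints
#'
#' @param model an `EcModel`.
#' @param solution a `FluxSolution` with status optimal.
#' @param tol feasibility tolerance.
#' @return invisibly `TRUE`; errors with the violated constraint otherwise.
#' @export
check_solution <- function(model, solution, tol = 1e-8) {
  stopifnot(inherits(solution, "FluxSolution"),
            solution$status %in% c("optimal", "unbounded"))
  x <- c(solution$fluxes, solution$enzymes)[model$var_names]
  resid <- max(abs(model$A_eq %*% x - model$b_eq))
  if (resid > tol)
    stop(sprintf("steady-state violation: |S v| = %g", resid), call. = FALSE)
  slack <- model$b_ub - as.numeric(model$A_ub %*% x)
  if (min(slack) < -tol)
    stop(sprintf("inequality violation: %s",
                 rownames(model$A_ub)[which.min(slack)]), call. = FALSE)
  if (any(x < model$lb - tol) || any(x > model$ub + tol))
    stop("bound violation", call. = FALSE)
  invisible(TRUE)
}
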