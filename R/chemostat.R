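#' A steady-state chemostat measurement record
#'
#' One strain x dilution-rate x replicate observation: biomass concentration,
#' product titer, and per-compound feed and residual concentrations.
#'
#' @param strain strain name.
#' @param dilution_rate per hour (> 0); at steady state the specific growth
#'   rate equals the dilution rate.
#' @param biomass g dry cell weight / liter (> 0).
#' @param feed,residual named numeric vectors of compound concentrations
#'   (mmol/liter), same names.
#' @param product_titer extracellular product concentration (mg/liter).
#' @param replicate replicate index.
#' @return object of class `ChemostatRecord`.
#' @export
chemostat_record <- function(strain, dilution_rate, biomass, feed, residual,
                             product_titer = 0, replicate = 1L) {
  if (dilution_rate <= 0) stop("dilution_rate must be > 0", call. = FALSE)
  if (biomass <= 0) stop("biomass must be > 0", call. = FALSE)
  if (!setequal(names(feed), names(residual)))
    stop("feed and residual must cover the same compounds", call. = FALSE)
  residual <- residual[names(feed)]
  structure(list(strain = strain, dilution_rate = dilution_rate,
                 biomass = biomass, feed = feed, residual = residual,
                 product_titer = product_titer,
                 replicate = as.integer(replicate)),
            class = "ChemostatRecord")
}

#' @export
print.ChemostatRecord <- function(x, ...) {
  cat(sprintf("ChemostatRecord: %s D=%g/h X=%.2f g/L, %d compounds, titer %.2f mg/L\n",
              x$strain, x$dilution_rate, x$biomass, length(x$feed),
              x$product_titer))
  invisible(x)
}

#' Specific uptake or secretion rate from a steady-state mass balance
#'
#' Uptake: `q = D * (c_feed - c_residual) / X`; secretion:
#' `q = D * c_residual / X` (feed is zero for products). Units follow the
#' concentrations: mmol/gDCW/h for mmol/liter inputs.
#'
#' @param record a `ChemostatRecord`.
#' @param compound compound name present in the record.
#' @param direction `"uptake"` or `"secretion"`.
#' @return specific rate (>= 0 in the declared direction).
#' @export
specific_rate <- function(record, compound,
                          direction = c("uptake", "secretion")) {
  direction <- match.arg(direction)
  stopifnot(inherits(record, "ChemostatRecord"))
  if (!compound %in% names(record$feed))
    stop(sprintf("compound '%s' not measured", compound), call. = FALSE)
  cf <- record$feed[[compound]]
  cr <- record$residual[[compound]]
  if (direction == "uptake") {
    if (cr > cf)
      stop(sprintf("residual exceeds feed for '%s' declared as uptake",
                   compound), call. = FALSE)
    record$dilution_rate * (cf - cr) / record$biomass
  } else {
    record$dilution_rate * cr / record$biomass
  }
}

#' Product yield and productivity
#'
#' Yield is titer per biomass (`titer / X`, mg/gDCW); productivity is
#' `yield * D` (mg/gDCW/h) -- at steady state the product leaves the vessel
#' at the dilution rate.
#'
#' @param record a `ChemostatRecord`.
#' @return list: `yield` (mg/gDCW), `productivity` (mg/gDCW/h).
#' @export
product_yield_and_productivity <- function(record) {
  stopifnot(inherits(record, "ChemostatRecord"))
  if (record$biomass <= 0) stop("biomass must be > 0", call. = FALSE)
  yield <- record$product_titer / record$biomass
  list(yield = yield, productivity = yield * record$dilution_rate)
}

#' Specific rates for a set of compounds as an exchange-constraints table
#'
#' @param record a `ChemostatRecord`.
#' @param directions named character vector mapping compound -> direction
#'   (`"uptake"` / `"secretion"`); defaults to uptake for every measured
#'   compound.
#' @return data.frame: compound, direction, rate (mmol/gDCW/h), consumable by
#'   [apply_exchange_constraints()] via a reaction mapping.
#' @export
specific_rates_table <- function(record, directions = NULL) {
  if (is.null(directions)) {
    directions <- stats::setNames(rep("uptake", length(record$feed)),
                                  names(record$feed))
  }
  data.frame(
    compound = names(directions),
    direction = unname(directions),
    rate = vapply(names(directions), function(cp)
      specific_rate(record, cp, directions[[cp]]), numeric(1)),
    stringsAsFactors = FALSE, row.names = NULL)
}
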