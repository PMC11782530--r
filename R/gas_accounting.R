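#' @title Headspace gas accounting
#' @description Ideal-gas mole bookkeeping for sealed serum bottles:
#'   pressure-to-mole conversion, headspace growth across liquid
#'   withdrawals, zero-control baseline correction and GC-derived
#'   per-species amounts.
#' @name gas_accounting
NULL

# J mol-1 K-1
GAS_CONSTANT <- 8.314

#' Vessel state of a sealed serum bottle
#'
#' @param bottle_volume_ml total bottle volume (mL); the field standard
#'   is a 117 mL serum bottle.
#' @param liquid_volume_ml liquid working volume (mL), typically 50 mL,
#'   strictly less than the bottle volume.
#' @param temperature_k temperature at which pressures are read (K);
#'   bottles are cooled to room temperature before measurement.
#' @param pressure_abs_bar optional current absolute pressure (bar).
#' @return An object of class `vessel_state`; `headspace_volume_ml` is
#'   derived as bottle minus liquid.
#' @examples
#' vessel_state(117, 50)
#' @export
vessel_state <- function(bottle_volume_ml, liquid_volume_ml,
                         temperature_k = 298.15, pressure_abs_bar = NA_real_) {
  stopifnot(bottle_volume_ml > 0, liquid_volume_ml >= 0,
            liquid_volume_ml < bottle_volume_ml, temperature_k > 0,
            is.na(pressure_abs_bar) || pressure_abs_bar >= 0)
  structure(list(
    bottle_volume_ml = bottle_volume_ml,
    liquid_volume_ml = liquid_volume_ml,
    headspace_volume_ml = bottle_volume_ml - liquid_volume_ml,
    temperature_k = temperature_k,
    pressure_abs_bar = pressure_abs_bar
  ), class = "vessel_state")
}

#' @export
print.vessel_state <- function(x, ...) {
  cat(sprintf("<vessel_state> bottle %.4g mL | liquid %.4g mL | headspace %.4g mL | %.2f K",
              x$bottle_volume_ml, x$liquid_volume_ml, x$headspace_volume_ml,
              x$temperature_k))
  if (!is.na(x$pressure_abs_bar)) cat(sprintf(" | %.4g bar abs", x$pressure_abs_bar))
  cat("\n")
  invisible(x)
}

#' Moles from pressure (ideal gas law)
#'
#' n = pV/RT with bar converted to Pa and mL to m^3.
#'
#' @param p_abs_bar absolute pressure (bar), > 0.
#' @param headspace_ml headspace volume (mL), > 0.
#' @param temperature_k temperature (K), > 0.
#' @param allow_zero permit p = 0 (returns 0 mol); used internally for
#'   pressure differences.
#' @return Moles of gas.
#' @examples
#' moles_from_pressure(3, 67, 298.15)
#' @export
moles_from_pressure <- function(p_abs_bar, headspace_ml, temperature_k,
                                allow_zero = FALSE) {
  stopifnot(is.numeric(p_abs_bar), is.numeric(headspace_ml), is.numeric(temperature_k))
  if (any(headspace_ml <= 0) || any(temperature_k <= 0)) {
    stop("headspace volume and temperature must be positive")
  }
  if (any(p_abs_bar < 0) || (!allow_zero && any(p_abs_bar <= 0))) {
    stop("absolute pressure must be positive")
  }
  (p_abs_bar * 1e5) * (headspace_ml * 1e-6) / (GAS_CONSTANT * temperature_k)
}

#' Pressure from moles (ideal gas law)
#'
#' @param n_mol moles of gas (>= 0).
#' @param headspace_ml headspace volume (mL), > 0.
#' @param temperature_k temperature (K), > 0.
#' @return Absolute pressure in bar.
#' @export
pressure_from_moles <- function(n_mol, headspace_ml, temperature_k) {
  stopifnot(all(n_mol >= 0), all(headspace_ml > 0), all(temperature_k > 0))
  n_mol * GAS_CONSTANT * temperature_k / (headspace_ml * 1e-6) / 1e5
}

#' Apply a liquid withdrawal to a vessel
#'
#' Removing sample liquid enlarges the headspace by exactly the
#' withdrawn volume; the bottle volume is unchanged. Headspace volume
#' must be adjusted this way after every sampling event or mole
#' bookkeeping drifts.
#'
#' @param state a `vessel_state`.
#' @param withdrawn_ml withdrawn liquid volume (mL), in `[0, liquid)`.
#' @return The updated `vessel_state`.
#' @examples
#' apply_withdrawal(vessel_state(117, 50), 0.75)
#' @export
apply_withdrawal <- function(state, withdrawn_ml) {
  stopifnot(inherits(state, "vessel_state"), is.numeric(withdrawn_ml),
            length(withdrawn_ml) == 1L, withdrawn_ml >= 0)
  if (withdrawn_ml >= state$liquid_volume_ml) {
    stop("withdrawal (", withdrawn_ml, " mL) must be smaller than the liquid volume (",
         state$liquid_volume_ml, " mL)")
  }
  vessel_state(state$bottle_volume_ml,
               state$liquid_volume_ml - withdrawn_ml,
               state$temperature_k,
               state$pressure_abs_bar)
}

#' Zero-control baseline correction
#'
#' The uninoculated zero-control bottle is gassed together with the
#' culture bottles; because removing the gassing needle releases some
#' gas, its reading is the real starting pressure of the round. Bottle
#' readings are shifted so that a bottle reading equal to the zero
#' control maps onto the nominal pressure, i.e. the zero control defines
#' the time-zero reference for all pressure differences.
#'
#' @param p_measured_rel measured relative pressure(s) of a bottle (bar).
#' @param zero_control_rel zero-control relative reading of the same
#'   gassing round (bar); `NA`/`NULL` falls back to nominal with a
#'   warning.
#' @param nominal_rel nominal relative gassing pressure (bar).
#' @return Corrected relative pressure(s) (bar).
#' @examples
#' baseline_correct(1.95, zero_control_rel = 1.95, nominal_rel = 2)
#' @export
baseline_correct <- function(p_measured_rel, zero_control_rel, nominal_rel) {
  stopifnot(is.numeric(p_measured_rel), is.numeric(nominal_rel))
  if (is.null(zero_control_rel) || length(zero_control_rel) == 0L || is.na(zero_control_rel)) {
    warning("no zero-control reading available; falling back to the nominal gassing pressure")
    return(p_measured_rel)
  }
  p_measured_rel + (nominal_rel - zero_control_rel)
}

#' Normalise a GC reading to mole fractions
#'
#' Raw detector fractions need not sum to one; each channel is divided
#' by the sum of measured channels.
#'
#' @param raw_fractions named non-negative numeric vector of detector
#'   fractions (subset of H2, CO2, N2, CH4, NH3).
#' @return A `gas_mixture`.
#' @examples
#' normalize_gc(c(H2 = 0.30, CO2 = 0.05, CH4 = 0.10, N2 = 0.05))
#' @export
normalize_gc <- function(raw_fractions) {
  stopifnot(is.numeric(raw_fractions), !is.null(names(raw_fractions)))
  if (any(raw_fractions < 0)) stop("GC fractions must be non-negative")
  if (sum(raw_fractions) <= 0) stop("all-zero GC reading cannot be normalised")
  gas_mixture(raw_fractions)
}

#' Per-species headspace amounts
#'
#' Splits the ideal-gas total over species according to a (normalised)
#' composition.
#'
#' @param p_abs_bar absolute pressure (bar).
#' @param vessel a `vessel_state`.
#' @param composition a `gas_mixture` or named raw GC fractions (which
#'   are normalised first).
#' @return Named numeric vector of moles per species (all species, zeros
#'   where absent); sums to the ideal-gas total.
#' @export
species_amounts <- function(p_abs_bar, vessel, composition) {
  stopifnot(inherits(vessel, "vessel_state"))
  if (!inherits(composition, "gas_mixture")) composition <- normalize_gc(composition)
  n_tot <- moles_from_pressure(p_abs_bar, vessel$headspace_volume_ml,
                               vessel$temperature_k, allow_zero = TRUE)
  n_tot * composition$fractions
}

#' Headspace amount of N2
#'
#' Immediately after gassing the exact N2 feed fraction (11.392 Vol.-%
#' for the 7:1:1 mixture) applies; once a GC reading is available its
#' normalised N2 fraction supersedes the feed value. Zero-control N2
#' amounts computed the same way serve as the baseline for delta-N2.
#'
#' @param p_abs_bar absolute pressure (bar).
#' @param vessel a `vessel_state`.
#' @param gc optional named raw GC fractions; must include an `N2`
#'   channel when supplied.
#' @param initial_n2_fraction N2 mole fraction of the feed gas, in
#'   (0, 1); default 0.11392.
#' @return Moles of N2 in the headspace.
#' @examples
#' n2_amount(3, vessel_state(117, 50))
#' @export
n2_amount <- function(p_abs_bar, vessel, gc = NULL,
                      initial_n2_fraction = 0.11392) {
  stopifnot(inherits(vessel, "vessel_state"),
            initial_n2_fraction > 0, initial_n2_fraction < 1)
  n_tot <- moles_from_pressure(p_abs_bar, vessel$headspace_volume_ml,
                               vessel$temperature_k, allow_zero = TRUE)
  if (is.null(gc)) {
    return(n_tot * initial_n2_fraction)
  }
  if (!("N2" %in% names(gc))) stop("GC reading lacks an N2 channel")
  n_tot * normalize_gc(gc)$fractions[["N2"]]
}
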