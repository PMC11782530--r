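#' @title Uptake/evolution rates and mass balances
#' @description Interval rates (NUR, qN2, HUR, CUR, MER, AUR, amino-acid
#'   excretion) and carbon mass balances for closed-batch cultivations.
#'   Sign convention throughout: consumption rates are non-positive
#'   (negative NUR indicates N2 fixation), evolution rates non-negative.
#' @name rates_balances
NULL

#' Average molecular weights of free amino acids (g/mol)
#'
#' The 20 proteinogenic amino acids plus GABA and taurine, as the free
#' (non-residue) molecules. Used to convert assay concentrations
#' (umol/L) to mass concentrations (g/L).
#' @export
aa_molar_masses <- c(
  Ala = 89.09,  Arg = 174.20, Asn = 132.12, Asp = 133.10, Cys = 121.16,
  Gln = 146.15, Glu = 147.13, Gly = 75.07,  His = 155.15, Ile = 131.17,
  Leu = 131.17, Lys = 146.19, Met = 149.21, Phe = 165.19, Pro = 115.13,
  Ser = 105.09, Thr = 119.12, Trp = 204.23, Tyr = 181.19, Val = 117.15,
  GABA = 103.12, Tau = 125.15
)

# nitrogen atoms per molecule, used by the simulator's N bookkeeping
aa_nitrogen_atoms <- c(
  Ala = 1, Arg = 4, Asn = 2, Asp = 1, Cys = 1, Gln = 2, Glu = 1, Gly = 1,
  His = 3, Ile = 1, Leu = 1, Lys = 2, Met = 1, Phe = 1, Pro = 1, Ser = 1,
  Thr = 1, Trp = 2, Tyr = 1, Val = 1, GABA = 1, Tau = 1
)

#' Volumetric uptake/evolution rate
#'
#' rate = delta_n / (V * dt), scaled to mmol L-1 h-1. The sign of the
#' mole change is preserved: a negative delta (consumption) gives a
#' negative rate, so negative NUR indicates N2 fixation.
#'
#' @param delta_n_mol mole change over the interval (after minus
#'   before, baseline-corrected).
#' @param liquid_volume_l liquid medium volume (L), > 0.
#' @param delta_t_h interval length (h), > 0.
#' @return Rate in mmol L-1 h-1.
#' @examples
#' uptake_rate(-5e-4, 0.05, 20)
#' @export
uptake_rate <- function(delta_n_mol, liquid_volume_l, delta_t_h) {
  stopifnot(is.numeric(delta_n_mol))
  if (any(liquid_volume_l <= 0)) stop("liquid volume must be positive")
  if (any(delta_t_h <= 0)) stop("interval length must be positive")
  1000 * delta_n_mol / (liquid_volume_l * delta_t_h)
}

#' Biomass-specific rate
#'
#' qN2 = |NUR| / x: the magnitude of a volumetric rate per gram of
#' biomass.
#'
#' @param rate_mmol_l_h volumetric rate (mmol L-1 h-1), sign ignored.
#' @param biomass_g_l biomass concentration (g/L), > 0.
#' @return Specific rate in mmol h-1 g-1.
#' @examples
#' specific_rate(-0.62, 0.0605)
#' @export
specific_rate <- function(rate_mmol_l_h, biomass_g_l) {
  stopifnot(is.numeric(rate_mmol_l_h))
  if (any(biomass_g_l <= 0)) stop("biomass concentration must be positive")
  abs(rate_mmol_l_h) / biomass_g_l
}

#' Biomass concentration from optical density
#'
#' x = OD578 * coefficient. The coefficient is strain- and
#' instrument-specific and must be determined experimentally; it is a
#' required configuration value, not a package constant.
#'
#' @param od578 optical density at 578 nm, >= 0.
#' @param coefficient g biomass per litre per OD unit, > 0.
#' @return Biomass concentration (g/L).
#' @export
biomass_from_od <- function(od578, coefficient) {
  if (missing(coefficient) || is.null(coefficient) || anyNA(coefficient)) {
    stop("the OD-to-biomass coefficient is required (experimentally determined, g/L per OD unit)")
  }
  stopifnot(all(od578 >= 0), all(coefficient > 0))
  od578 * coefficient
}

#' Biomass productivity in carbon units
#'
#' rx = (delta x / delta t) * carbon content, in C-mmol L-1 h-1. The
#' default carbon content 37.7 C-mmol/g corresponds to the standard
#' biomass composition CH1.8O0.5N0.2 (26.5 g per C-mol).
#'
#' @param delta_biomass_g_l biomass concentration change (g/L).
#' @param delta_t_h interval length (h), > 0.
#' @param carbon_content_cmmol_g carbon content of biomass (C-mmol/g).
#' @return Productivity in C-mmol L-1 h-1.
#' @export
biomass_productivity <- function(delta_biomass_g_l, delta_t_h,
                                 carbon_content_cmmol_g = 37.7) {
  if (any(delta_t_h <= 0)) stop("interval length must be positive")
  stopifnot(carbon_content_cmmol_g > 0)
  delta_biomass_g_l / delta_t_h * carbon_content_cmmol_g
}

#' Mass concentration of an amino acid
#'
#' Converts an assay concentration (umol/L) to g/L using the built-in
#' free-molecule molecular-weight table.
#'
#' @param conc_umol_l concentration in umol/L.
#' @param amino_acid three-letter code (plus GABA, Tau).
#' @return Mass concentration in g/L.
#' @examples
#' aa_mass_concentration(304.76, "Glu")
#' @export
aa_mass_concentration <- function(conc_umol_l, amino_acid) {
  stopifnot(is.character(amino_acid), length(amino_acid) == 1L)
  if (!(amino_acid %in% names(aa_molar_masses))) {
    stop("unknown amino-acid code: ", amino_acid)
  }
  stopifnot(all(conc_umol_l >= 0))
  conc_umol_l * aa_molar_masses[[amino_acid]] * 1e-6
}

#' Observation interval for rate calculation
#'
#' Bundles what one incubation interval contributes to the rate set:
#' its time span, the liquid volume at interval start, the biomass at
#' interval end (the sampling time), and the baseline-corrected mole
#' changes per gas species, plus optional liquid-phase concentration
#' changes.
#'
#' @param t_start_h,t_end_h interval bounds (h), `t_end_h > t_start_h`.
#' @param liquid_volume_l liquid volume during the interval (L).
#' @param biomass_g_l biomass concentration at interval end (g/L).
#' @param species_delta_mol named mole changes (after minus before) for
#'   any of H2, CO2, N2, CH4.
#' @param nh4_delta_mmol_l optional NH4+ concentration change (mmol/L).
#' @param aa_delta_umol_l optional named amino-acid concentration
#'   changes (umol/L).
#' @return An object of class `rate_interval`.
#' @export
rate_interval <- function(t_start_h, t_end_h, liquid_volume_l, biomass_g_l,
                          species_delta_mol, nh4_delta_mmol_l = NA_real_,
                          aa_delta_umol_l = NULL) {
  stopifnot(t_end_h > t_start_h, liquid_volume_l > 0,
            is.numeric(species_delta_mol), !is.null(names(species_delta_mol)))
  .check_species(names(species_delta_mol))
  structure(list(
    t_start_h = t_start_h, t_end_h = t_end_h,
    liquid_volume_l = liquid_volume_l, biomass_g_l = biomass_g_l,
    species_delta_mol = species_delta_mol,
    nh4_delta_mmol_l = nh4_delta_mmol_l,
    aa_delta_umol_l = aa_delta_umol_l
  ), class = "rate_interval")
}

#' Rates over one interval
#'
#' Applies [uptake_rate()] per gas species: NUR, HUR, CUR keep the
#' consumption-negative sign, MER is reported as positive evolution.
#' qN2 is |NUR| divided by the interval-end biomass. AUR and per-amino-
#' acid rates are concentration-based (no headspace conversion). A
#' missing species channel yields `NA` for that rate; the others are
#' still computed.
#'
#' @param interval a `rate_interval`.
#' @return An object of class `rate_set` with elements `nur`, `qn2`,
#'   `hur`, `cur`, `mer` (mmol L-1 h-1; qn2 in mmol h-1 g-1), `aur`
#'   (mmol L-1 h-1) and `aa_rates` (umol L-1 h-1).
#' @export
interval_rates <- function(interval) {
  stopifnot(inherits(interval, "rate_interval"))
  dt <- interval$t_end_h - interval$t_start_h
  v <- interval$liquid_volume_l
  d <- interval$species_delta_mol
  sp_rate <- function(s) {
    if (!(s %in% names(d)) || is.na(d[[s]])) return(NA_real_)
    uptake_rate(d[[s]], v, dt)
  }
  nur <- sp_rate("N2")
  hur <- sp_rate("H2")
  cur <- sp_rate("CO2")
  mer_raw <- sp_rate("CH4")
  mer <- if (is.na(mer_raw)) NA_real_ else mer_raw # evolution: positive delta
  qn2 <- if (is.na(nur) || is.na(interval$biomass_g_l) || interval$biomass_g_l <= 0) {
    NA_real_
  } else {
    specific_rate(nur, interval$biomass_g_l)
  }
  aur <- if (is.na(interval$nh4_delta_mmol_l)) NA_real_ else interval$nh4_delta_mmol_l / dt
  aa_rates <- NULL
  if (!is.null(interval$aa_delta_umol_l)) {
    aa_rates <- interval$aa_delta_umol_l / dt
  }
  structure(list(nur = nur, qn2 = qn2, hur = hur, cur = cur, mer = mer,
                 aur = aur, aa_rates = aa_rates,
                 biomass_g_l = interval$biomass_g_l,
                 t_start_h = interval$t_start_h, t_end_h = interval$t_end_h),
            class = "rate_set")
}

#' @export
print.rate_set <- function(x, ...) {
  cat(sprintf("<rate_set> [%g, %g] h: NUR %.4g | HUR %.4g | CUR %.4g | MER %.4g mmol/L/h | qN2 %.4g mmol/h/g\n",
              x$t_start_h, x$t_end_h, x$nur, x$hur, x$cur, x$mer, x$qn2))
  invisible(x)
}

#' Carbon mass balance and yields
#'
#' Y(CH4/CO2) = MER/|CUR|, Y(x/CO2) = rx/|CUR|, and the carbon balance
#' is their sum: the fraction of consumed CO2 carbon recovered in CH4
#' plus biomass (1 at closure). Also reports the HUR:CUR ratio, which is
#' 4 for pure methanogenesis.
#'
#' @param rates a `rate_set` with non-zero CUR.
#' @param rx biomass productivity (C-mmol L-1 h-1), >= 0.
#' @return An object of class `mass_balance` with `c_balance`,
#'   `y_ch4_co2`, `y_x_co2`, `rx`, `hur_cur_ratio`.
#' @examples
#' r <- interval_rates(rate_interval(0, 1, 0.05, 0.06,
#'   c(H2 = -40e-3 * 0.05, CO2 = -10e-3 * 0.05, CH4 = 8e-3 * 0.05, N2 = 0)))
#' mass_balance(r, rx = 2)
#' @export
mass_balance <- function(rates, rx) {
  stopifnot(inherits(rates, "rate_set"), is.numeric(rx), rx >= 0)
  if (is.na(rates$cur) || abs(rates$cur) <= 0) {
    stop("mass balance requires a non-zero CO2 uptake rate")
  }
  cur_mag <- abs(rates$cur)
  y_ch4 <- rates$mer / cur_mag
  y_x <- rx / cur_mag
  structure(list(
    c_balance = y_ch4 + y_x,
    y_ch4_co2 = y_ch4,
    y_x_co2 = y_x,
    rx = rx,
    hur_cur_ratio = if (is.na(rates$hur)) NA_real_ else abs(rates$hur) / cur_mag
  ), class = "mass_balance")
}

#' @export
print.mass_balance <- function(x, ...) {
  cat(sprintf("<mass_balance> C-balance %.4g = Y(CH4/CO2) %.4g + Y(x/CO2) %.4g | HUR:CUR %.4g\n",
              x$c_balance, x$y_ch4_co2, x$y_x_co2, x$hur_cur_ratio))
  invisible(x)
}
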