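#' @title Reaction algebra for closed-batch gas conversion
#' @description Gas-phase species, reactions and full-conversion
#'   residual-pressure thresholds for sealed serum-bottle cultivations of
#'   hydrogenotrophic, autotrophic, diazotrophic methanogens.
#' @name stoichiometry
NULL

# headspace species tracked by the package; H2O is always condensed and
# NH3 is always dissolved (as NH4+), so both live in non_gas bookkeeping
GAS_SPECIES <- c("H2", "CO2", "N2", "CH4", "NH3")

# element composition (columns H, C, N, O) for balance checks
.ELEMENTS <- matrix(
  c(
    2, 0, 0, 0, # H2
    0, 1, 0, 2, # CO2
    0, 0, 2, 0, # N2
    4, 1, 0, 0, # CH4
    3, 0, 1, 0, # NH3
    2, 0, 0, 1  # H2O
  ),
  ncol = 4, byrow = TRUE,
  dimnames = list(c(GAS_SPECIES, "H2O"), c("H", "C", "N", "O"))
)

#' Gas moles removed from the headspace per mol N2 fixed
#'
#' One N2 plus three net H2 (four H2 feed the eight electrons, one H2 is
#' returned by nitrogenase) leave the gas phase per N2 reduced; the
#' product ammonia stays dissolved. Exposed as a named constant for
#' sensitivity analysis.
#' @export
N2FIX_GAS_MOLES_PER_N2 <- 4

.check_species <- function(sp) {
  bad <- setdiff(sp, GAS_SPECIES)
  if (length(bad) > 0L) {
    stop("unknown species: ", paste(bad, collapse = ", "),
         " (expected one of ", paste(GAS_SPECIES, collapse = ", "), ")")
  }
  invisible(sp)
}

#' Construct a gas-phase reaction
#'
#' Coefficients are signed: negative = consumed, positive = produced.
#' `gas` holds headspace species only; condensed or dissolved products
#' (H2O, NH3-as-NH4+) go in `non_gas` so that elemental balance can be
#' verified across both.
#'
#' @param name reaction label.
#' @param gas named numeric vector of gas-phase coefficients.
#' @param non_gas named numeric vector of condensed/dissolved products.
#' @return An object of class `reaction`.
#' @export
reaction <- function(name, gas, non_gas = numeric(0)) {
  stopifnot(is.character(name), length(name) == 1L,
            is.numeric(gas), !is.null(names(gas)))
  .check_species(names(gas))
  if (length(non_gas) > 0L) {
    stopifnot(!is.null(names(non_gas)))
    bad <- setdiff(names(non_gas), rownames(.ELEMENTS))
    if (length(bad) > 0L) stop("unknown non-gas product: ", paste(bad, collapse = ", "))
  }
  if (!any(gas < 0)) stop("a reaction must consume at least one gas species")
  coef <- c(gas, non_gas)
  bal <- colSums(.ELEMENTS[names(coef), , drop = FALSE] * coef)
  if (any(abs(bal) > 1e-9)) {
    stop("reaction '", name, "' is not elementally balanced: ",
         paste(names(bal), bal, sep = "=", collapse = ", "))
  }
  structure(list(name = name, gas = gas, non_gas = non_gas), class = "reaction")
}

#' @export
print.reaction <- function(x, ...) {
  fmt <- function(v) paste(sprintf("%+g %s", v, names(v)), collapse = "  ")
  cat("<reaction>", x$name, "\n  gas:    ", fmt(x$gas), "\n")
  if (length(x$non_gas)) cat("  non-gas:", fmt(x$non_gas), "\n")
  invisible(x)
}

#' Hydrogenotrophic methanogenesis
#'
#' 4 H2 + CO2 -> CH4 + 2 H2O. Water is produced as liquid and does not
#' contribute to headspace pressure, so each reaction extent removes four
#' gas moles.
#'
#' @return A `reaction`.
#' @examples
#' methanogenesis()
#' @export
methanogenesis <- function() {
  reaction("methanogenesis",
           gas = c(H2 = -4, CO2 = -1, CH4 = 1),
           non_gas = c(H2O = 2))
}

#' Net gas-phase nitrogenase reaction
#'
#' Nitrogenase reduces N2 + 8 H+ + 8 e- to 2 NH3 + H2. With H2 as the
#' electron donor (4 H2 oxidised per turnover, 1 H2 returned) the net gas
#' exchange is N2 - 1, H2 - 3; the two NH3 stay dissolved as NH4+. Each
#' extent therefore also removes four gas moles.
#'
#' @return A `reaction`.
#' @examples
#' nitrogenase_net()
#' @export
nitrogenase_net <- function() {
  reaction("nitrogenase_net",
           gas = c(N2 = -1, H2 = -3),
           non_gas = c(NH3 = 2))
}

#' Combine reactions with positive weights
#'
#' Coefficients are weight-sums of the inputs. Combining methanogenesis
#' with the net nitrogenase reaction at unit weights yields the ideal
#' 7:1:1 H2:CO2:N2 feed for full conversion by a diazotrophic methanogen.
#'
#' @param rxns list of `reaction` objects.
#' @param weights positive numeric weights, one per reaction.
#' @param name label for the combined reaction.
#' @return A `reaction`.
#' @examples
#' combine_reactions(list(methanogenesis(), nitrogenase_net()))
#' @export
combine_reactions <- function(rxns, weights = rep(1, length(rxns)),
                              name = "combined") {
  if (length(rxns) == 0L) stop("empty reaction list")
  stopifnot(all(vapply(rxns, inherits, logical(1), "reaction")),
            length(weights) == length(rxns), all(weights > 0))
  acc <- function(field) {
    out <- numeric(0)
    for (i in seq_along(rxns)) {
      v <- rxns[[i]][[field]] * weights[i]
      for (s in names(v)) out[s] <- (if (s %in% names(out)) out[s] else 0) + v[s]
    }
    out[out != 0]
  }
  reaction(name, gas = acc("gas"), non_gas = acc("non_gas"))
}

#' Ideal feed ratio of a reaction
#'
#' Reads the consumed gas species (negative coefficients) as a feed part
#' table, e.g. H2:CO2:N2 = 7:1:1 for the combined diazotrophic reaction.
#'
#' @param rxn a `reaction`.
#' @return Named numeric vector of positive feed parts.
#' @export
feed_ratio <- function(rxn) {
  stopifnot(inherits(rxn, "reaction"))
  v <- -rxn$gas[rxn$gas < 0]
  v[order(match(names(v), GAS_SPECIES))]
}

#' Construct a gas mixture
#'
#' Accepts parts (any positive scale, e.g. `c(H2 = 7, CO2 = 1, N2 = 1)`)
#' or mole fractions; both are normalised to fractions that sum to one.
#' Parts are also retained exactly (as rationals) so that residual
#' pressures such as 5/3 bar come out bit-exact.
#'
#' @param parts named non-negative numeric vector over the headspace
#'   species H2, CO2, N2, CH4, NH3.
#' @return An object of class `gas_mixture` with elements `fractions`
#'   (named numeric over all species) and `parts` (exact rationals in the
#'   same order).
#' @examples
#' gas_mixture(c(H2 = 7, CO2 = 1, N2 = 1))
#' @export
gas_mixture <- function(parts) {
  stopifnot(is.numeric(parts), !is.null(names(parts)), all(is.finite(parts)))
  .check_species(names(parts))
  if (any(parts < 0)) stop("mixture parts must be non-negative")
  if (sum(parts) <= 0) stop("mixture must contain at least one positive part")
  full <- setNames(numeric(length(GAS_SPECIES)), GAS_SPECIES)
  full[names(parts)] <- parts
  r <- as_rational(full)
  total <- rational_sum(r)
  fr <- as.numeric(r) / as.numeric(total)
  if (abs(sum(fr) - 1) > 1e-9) stop("internal error: fractions do not sum to 1")
  structure(list(fractions = setNames(fr, GAS_SPECIES), parts = r),
            class = "gas_mixture")
}

#' @export
print.gas_mixture <- function(x, ...) {
  nz <- x$fractions[x$fractions > 0]
  cat("<gas_mixture>", paste(sprintf("%s %.5f", names(nz), nz), collapse = ", "), "\n")
  invisible(x)
}

#' Parse a mixture specification string
#'
#' Understands the part form `"H2:CO2:N2=7:1:1"` and the bare fraction
#' form `"0.77778,0.11111,0.11111"` (taken as H2, CO2, N2 in that order).
#'
#' @param spec character scalar.
#' @return A `gas_mixture`.
#' @examples
#' parse_mixture("H2:CO2:N2=7:1:1")
#' @export
parse_mixture <- function(spec) {
  stopifnot(is.character(spec), length(spec) == 1L)
  spec <- gsub("\\s", "", spec)
  if (grepl("=", spec, fixed = TRUE)) {
    halves <- strsplit(spec, "=", fixed = TRUE)[[1]]
    if (length(halves) != 2L) stop("malformed mixture spec: ", spec)
    sp <- strsplit(halves[1], ":", fixed = TRUE)[[1]]
    vals <- suppressWarnings(as.numeric(strsplit(halves[2], ":", fixed = TRUE)[[1]]))
    if (length(sp) != length(vals) || anyNA(vals)) stop("malformed mixture spec: ", spec)
    gas_mixture(setNames(vals, sp))
  } else {
    vals <- suppressWarnings(as.numeric(strsplit(spec, ",", fixed = TRUE)[[1]]))
    if (anyNA(vals) || !(length(vals) %in% c(3L, 4L, 5L))) {
      stop("malformed mixture spec: ", spec)
    }
    gas_mixture(setNames(vals, GAS_SPECIES[seq_along(vals)]))
  }
}

#' Residual pressure after full conversion
#'
#' Advances each active reaction, in list order, to the maximal extent
#' allowed by its limiting gas reactant, using exact rational
#' bookkeeping of mixture parts. The residual absolute pressure is
#' `p0_abs * residual moles / initial moles` (ideal gas, isothermal,
#' isochoric). A reaction whose reactants are absent is skipped with
#' zero extent rather than raising an error.
#'
#' @param mix a `gas_mixture`.
#' @param p0_abs initial absolute pressure (bar), > 0.
#' @param active a `reaction` or list of reactions, applied in order.
#' @return An object of class `threshold_result` with elements
#'   `threshold_abs_bar`, `fraction_of_initial` (exact rational),
#'   `residual_composition` (`gas_mixture` or `NULL` when nothing
#'   remains), `limiting_species`, `extent` (total advancement in
#'   mol-fraction units of the initial total), and per-reaction
#'   `extents`.
#' @examples
#' full_conversion_residual(gas_mixture(c(H2 = 4, CO2 = 1)), 3, methanogenesis())
#' @export
full_conversion_residual <- function(mix, p0_abs, active) {
  stopifnot(inherits(mix, "gas_mixture"), is.numeric(p0_abs),
            length(p0_abs) == 1L, p0_abs > 0)
  if (inherits(active, "reaction")) active <- list(active)
  if (length(active) == 0L) stop("no active reactions supplied")
  stopifnot(all(vapply(active, inherits, logical(1), "reaction")))

  parts <- mix$parts # rational, aligned to GAS_SPECIES
  init_total <- rational_sum(parts)
  limiting <- character(0)
  extents <- rational(numeric(0), numeric(0))

  for (rx in active) {
    reac <- names(rx$gas)[rx$gas < 0]
    idx <- match(reac, GAS_SPECIES)
    if (any(as.numeric(parts[idx]) == 0)) {
      # a required reactant is absent: skip with zero extent
      limiting <- c(limiting, setNames(NA_character_, rx$name))
      extents <- c_rational(extents, rational(0, 1))
      next
    }
    ratios <- parts[idx] / as_rational(abs(rx$gas[reac]))
    k <- .rational_which_min(ratios)
    ext <- ratios[k]
    limiting <- c(limiting, setNames(reac[k], rx$name))
    extents <- c_rational(extents, ext)
    for (s in names(rx$gas)) {
      j <- match(s, GAS_SPECIES)
      upd <- parts[j] + as_rational(rx$gas[[s]]) * ext
      parts <- .rational_assign(parts, j, upd)
    }
  }

  resid_total <- rational_sum(parts)
  frac <- resid_total / init_total
  threshold <- p0_abs * frac$num / frac$den
  resid_mix <- NULL
  if (as.numeric(resid_total) > 0) {
    resid_mix <- gas_mixture(setNames(as.numeric(parts), GAS_SPECIES))
  }
  applied <- limiting[!is.na(limiting)]
  structure(list(
    threshold_abs_bar = threshold,
    fraction_of_initial = frac,
    residual_composition = resid_mix,
    residual_parts = parts,
    limiting_species = if (length(applied)) unname(applied[1]) else NA_character_,
    limiting_by_reaction = limiting,
    extent = as.numeric(rational_sum(extents) / init_total),
    extents = extents,
    p0_abs = p0_abs,
    initial_mixture = mix,
    reactions = vapply(active, function(r) r$name, character(1))
  ), class = "threshold_result")
}

# helpers kept internal: rational vectors are plain lists, so element
# assignment and concatenation need explicit plumbing
c_rational <- function(x, y) rational(c(x$num, y$num), c(x$den, y$den))
.rational_assign <- function(x, i, value) {
  num <- x$num; den <- x$den
  num[i] <- value$num
  den[i] <- value$den
  rational(num, den)
}

#' @export
print.threshold_result <- function(x, ...) {
  cat(sprintf("<threshold_result> %.6g bar abs (= %s of p0 = %g bar)\n",
              x$threshold_abs_bar, format(x$fraction_of_initial), x$p0_abs))
  cat("  reactions:", paste(x$reactions, collapse = " -> "),
      "| limiting:", x$limiting_species, "\n")
  if (!is.null(x$residual_composition)) {
    nz <- x$residual_composition$fractions
    nz <- nz[nz > 0]
    cat("  residual: ", paste(sprintf("%s %.5f", names(nz), nz), collapse = ", "), "\n")
  } else {
    cat("  residual:  none (complete gas consumption)\n")
  }
  invisible(x)
}

#' Theoretical threshold pressure for N2 fixation (THp_N2fix)
#'
#' The residual absolute pressure after complete hydrogenotrophic
#' methanogenesis of the feed mixture, assuming no N2 fixation. Any
#' measured absolute pressure strictly below this value cannot be
#' explained by methanogenesis alone and therefore proves biological N2
#' fixation in the sealed bottle. For the 7:1:1 H2:CO2:N2 mixture at
#' 3 bar absolute the threshold is exactly 5/3 bar.
#'
#' @param mix a `gas_mixture`; must contain N2.
#' @param p0_abs initial absolute pressure (bar).
#' @return A `threshold_result` (methanogenesis as the only reaction).
#' @examples
#' thp_n2fix(gas_mixture(c(H2 = 7, CO2 = 1, N2 = 1)), 3)
#' @export
thp_n2fix <- function(mix, p0_abs) {
  stopifnot(inherits(mix, "gas_mixture"))
  if (mix$fractions[["N2"]] <= 0) {
    stop("THp_N2fix is undefined as an N2-fixation indicator: the feed mixture contains no N2")
  }
  full_conversion_residual(mix, p0_abs, methanogenesis())
}

#' Moles of N2 fixed, from pressure alone
#'
#' Once the measured absolute pressure is at or below the theoretical
#' threshold, the pressure deficit below the threshold can only come
#' from nitrogenase turnover, which removes four gas moles (1 N2 + 3 net
#' H2) per N2 fixed. Converting the deficit to moles by the ideal gas
#' law and dividing by four quantifies fixation without any GC
#' measurement.
#'
#' @param p_obs_abs measured absolute pressure (bar), must not exceed
#'   the threshold.
#' @param thp a `threshold_result` from [thp_n2fix()].
#' @param vessel a `vessel_state` giving headspace volume and the
#'   temperature at which the pressure was read.
#' @param gas_moles_per_n2 gas moles removed per N2 fixed; default
#'   [N2FIX_GAS_MOLES_PER_N2].
#' @return Moles of N2 fixed (>= 0).
#' @export
n2_fixed_from_pressure <- function(p_obs_abs, thp, vessel,
                                   gas_moles_per_n2 = N2FIX_GAS_MOLES_PER_N2) {
  stopifnot(inherits(thp, "threshold_result"), inherits(vessel, "vessel_state"),
            is.numeric(p_obs_abs), length(p_obs_abs) == 1L,
            gas_moles_per_n2 > 0)
  if (p_obs_abs > thp$threshold_abs_bar + 1e-12) {
    stop("observed pressure (", p_obs_abs, " bar) is above the threshold (",
         signif(thp$threshold_abs_bar, 6),
         " bar): no N2 fixation claimable from pressure alone")
  }
  dn <- moles_from_pressure(max(thp$threshold_abs_bar - p_obs_abs, 0),
                            vessel$headspace_volume_ml,
                            vessel$temperature_k,
                            allow_zero = TRUE)
  dn / gas_moles_per_n2
}
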