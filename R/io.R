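#' @title Observation tables and run configuration
#' @description Readers and writers for the delimited observation
#'   schema (one row per bottle and timepoint) and the structured run
#'   configuration, with the validation the analysis pipeline relies
#'   on.
#' @name io
NULL

.OBS_REQUIRED <- c("bottle_id", "time_h", "pressure_rel_bar", "od578",
                   "withdrawn_ml")
.OBS_KNOWN <- c(.OBS_REQUIRED, "role", "regas_after",
                "gc_h2", "gc_co2", "gc_ch4", "gc_n2", "nh4_umol_l")

#' Run configuration for the analysis pipeline
#'
#' Aggregates the constants every conversion step needs. Defaults match
#' the standard set-up: 117 mL bottles, 50 mL liquid, 7:1:1 H2:CO2:N2
#' at 3 bar absolute, pressures read at room temperature with a 1.000
#' bar atmospheric offset (so 2 bar relative is exactly 3 bar
#' absolute), an exact feed N2 fraction of 0.11392, calibration gate
#' R^2 >= 0.999 and Val/Met excluded from amino-acid panels. The
#' OD-to-biomass coefficient has no universal value and must be set
#' per strain and instrument.
#'
#' @param temperature_measurement_k temperature at which pressures are
#'   read (K).
#' @param atmospheric_bar relative-to-absolute pressure offset (bar).
#' @param bottle_volume_ml,liquid_volume_ml vessel geometry (mL).
#' @param od_coefficient g biomass per litre per OD578 unit.
#' @param initial_mixture feed `gas_mixture`.
#' @param initial_pressure_abs nominal gassing pressure (bar absolute).
#' @param initial_n2_fraction exact feed N2 mole fraction.
#' @param r2_min calibration acceptance threshold.
#' @param aa_exclusions amino-acid codes excluded from panels.
#' @param carbon_content_cmmol_g biomass carbon content (C-mmol/g).
#' @param undercut_margin_bar detection margin: fixation is flagged
#'   when the absolute pressure is below THp_N2fix minus this margin
#'   (guards against manometer noise around the threshold).
#' @return An object of class `run_config`.
#' @export
run_config <- function(temperature_measurement_k = 298.15,
                       atmospheric_bar = 1.0,
                       bottle_volume_ml = 117,
                       liquid_volume_ml = 50,
                       od_coefficient = 0.3,
                       initial_mixture = gas_mixture(c(H2 = 7, CO2 = 1, N2 = 1)),
                       initial_pressure_abs = 3,
                       initial_n2_fraction = 0.11392,
                       r2_min = 0.999,
                       aa_exclusions = c("Val", "Met"),
                       carbon_content_cmmol_g = 37.7,
                       undercut_margin_bar = 0.02) {
  stopifnot(temperature_measurement_k > 0, atmospheric_bar > 0,
            bottle_volume_ml > liquid_volume_ml, liquid_volume_ml > 0,
            od_coefficient > 0, inherits(initial_mixture, "gas_mixture"),
            initial_pressure_abs > 0,
            initial_n2_fraction > 0, initial_n2_fraction < 1,
            r2_min >= 0, r2_min <= 1, carbon_content_cmmol_g > 0,
            undercut_margin_bar >= 0)
  structure(as.list(environment()), class = "run_config")
}

#' Read a run configuration from a YAML file
#'
#' Keys mirror the arguments of [run_config()]; `initial_mixture` is
#' given as a mixture spec string (see [parse_mixture()]). Unknown keys
#' are an error so typos cannot silently fall back to defaults.
#'
#' @param path YAML file path.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  bad <- setdiff(names(vals), known)
  if (length(bad) > 0L) stop("unknown config keys: ", paste(bad, collapse = ", "))
  if (!is.null(vals$initial_mixture) && is.character(vals$initial_mixture)) {
    vals$initial_mixture <- parse_mixture(vals$initial_mixture)
  }
  do.call(run_config, vals)
}

#' Write an observation table
#'
#' @param observations data.frame in the observation schema (as emitted
#'   by [simulate_closed_batch()]).
#' @param path output file; comma-delimited with a header row.
#' @return `path`, invisibly.
#' @export
write_observations <- function(observations, path) {
  stopifnot(is.data.frame(observations))
  utils::write.csv(observations, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and validate an observation table
#'
#' One row per bottle and timepoint: `bottle_id`, `time_h`,
#' `pressure_rel_bar`, `od578`, `withdrawn_ml`, optional `role`
#' (`zero_control` rows are routed to the baseline store), optional
#' `regas_after` flag, optional GC channels `gc_h2`/`gc_co2`/`gc_ch4`/
#' `gc_n2`, optional `nh4_umol_l` and `aa_<code>_umol_l` columns.
#' Times must be strictly increasing within each bottle; duplicated
#' (bottle, time) pairs and negative absolute pressures are errors;
#' unknown columns produce a warning.
#'
#' @param path comma-delimited file with a header row.
#' @param atmospheric_bar offset used only to validate that absolute
#'   pressures are non-negative.
#' @return An object of class `observation_set`: `bottles` (named list
#'   of per-bottle data.frames), `zero_control` (data.frame or `NULL`),
#'   `aa_columns`.
#' @export
read_observations <- function(path, atmospheric_bar = 1.0) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  as_observation_set(df, atmospheric_bar = atmospheric_bar)
}

#' Coerce an in-memory observation table
#'
#' Same validation as [read_observations()], for tables that never
#' touch disk (e.g. straight from the simulator).
#'
#' @param df observation data.frame.
#' @param atmospheric_bar see [read_observations()].
#' @return An `observation_set`.
#' @export
as_observation_set <- function(df, atmospheric_bar = 1.0) {
  stopifnot(is.data.frame(df))
  missing_cols <- setdiff(.OBS_REQUIRED, names(df))
  if (length(missing_cols) > 0L) {
    stop("observation table lacks required columns: ",
         paste(missing_cols, collapse = ", "))
  }
  aa_cols <- grep("^aa_[a-z]+_umol_l$", names(df), value = TRUE)
  unknown <- setdiff(names(df), c(.OBS_KNOWN, aa_cols))
  if (length(unknown) > 0L) {
    warning("ignoring unknown observation columns: ",
            paste(unknown, collapse = ", "))
  }
  if (!("role" %in% names(df))) df$role <- "culture"
  if (!("regas_after" %in% names(df))) df$regas_after <- FALSE
  df$regas_after <- as.logical(df$regas_after)
  if (any(df$pressure_rel_bar + atmospheric_bar < 0)) {
    bad <- which(df$pressure_rel_bar + atmospheric_bar < 0)[1]
    stop("negative absolute pressure in row ", bad, " (bottle ",
         df$bottle_id[bad], ")")
  }
  split_ids <- unique(df$bottle_id)
  bottles <- list()
  zero <- NULL
  for (id in split_ids) {
    sub <- df[df$bottle_id == id, , drop = FALSE]
    sub <- sub[order(sub$time_h), , drop = FALSE]
    if (anyDuplicated(sub$time_h)) {
      stop("duplicate timepoint for bottle ", id, " at t = ",
           sub$time_h[anyDuplicated(sub$time_h)], " h")
    }
    raw <- df[df$bottle_id == id, , drop = FALSE]
    if (is.unsorted(raw$time_h, strictly = TRUE)) {
      row_bad <- which(diff(raw$time_h) <= 0)[1] + 1L
      stop("time regression within bottle ", id, " at input row ", row_bad)
    }
    rownames(sub) <- NULL
    if (identical(sub$role[1], "zero_control")) zero <- sub else bottles[[id]] <- sub
  }
  structure(list(bottles = bottles, zero_control = zero, aa_columns = aa_cols),
            class = "observation_set")
}

#' @export
print.observation_set <- function(x, ...) {
  cat(sprintf("<observation_set> %d culture bottle(s)%s\n", length(x$bottles),
              if (is.null(x$zero_control)) ", no zero control" else " + zero control"))
  invisible(x)
}
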