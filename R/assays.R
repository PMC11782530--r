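#' @title Standard-curve calibration and quantification
#' @description Linear external-standard calibration for the
#'   colorimetric NH4+ assay and the HPLC amino-acid panel, with the
#'   quality gate (R^2) and range rules of the wet-lab protocol.
#' @name assays
NULL

#' Fit a linear standard curve
#'
#' Ordinary least-squares regression of detector response on
#' concentration. The fit fails (an error, not a warning) when R^2 is
#' below `r2_min`; the NH4+ assay protocol requires R^2 > 0.999 over
#' nine standards between 100 and 1000 umol/L.
#'
#' @param concentration_umol_l standard concentrations (umol/L), at
#'   least two distinct values.
#' @param response detector responses, same length.
#' @param r2_min minimal acceptable R^2 (default 0.999).
#' @return An object of class `calibration_curve` with `slope`,
#'   `intercept`, `r_squared`, `valid_range`, `n_standards`.
#' @examples
#' fit_standard_curve(seq(100, 1000, 100), 0.002 * seq(100, 1000, 100) + 0.05)
#' @export
fit_standard_curve <- function(concentration_umol_l, response, r2_min = 0.999) {
  stopifnot(is.numeric(concentration_umol_l), is.numeric(response),
            length(concentration_umol_l) == length(response),
            length(concentration_umol_l) >= 2L,
            r2_min >= 0, r2_min <= 1)
  if (length(unique(concentration_umol_l)) < 2L) {
    stop("degenerate standards: at least two distinct concentrations are required")
  }
  fit <- stats::lm(response ~ concentration_umol_l)
  # R^2 computed directly; summary.lm() warns on exactly collinear
  # standards, which are legitimate here
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((response - mean(response))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_
  if (is.na(r2) || r2 < r2_min) {
    stop(sprintf("calibration rejected: R^2 = %.6f is below the required %.4g; re-run the standards",
                 r2, r2_min))
  }
  structure(list(
    slope = unname(stats::coef(fit)[2]),
    intercept = unname(stats::coef(fit)[1]),
    r_squared = r2,
    valid_range = range(concentration_umol_l),
    n_standards = length(concentration_umol_l)
  ), class = "calibration_curve")
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf("<calibration_curve> response = %.6g + %.6g * conc | R^2 %.6f | range [%g, %g] umol/L (n = %d)\n",
              x$intercept, x$slope, x$r_squared, x$valid_range[1],
              x$valid_range[2], x$n_standards))
  invisible(x)
}

#' Quantify a sample by inverse prediction
#'
#' conc = ((response - intercept) / slope) * dilution_factor. The
#' back-calculated (undiluted-read) concentration must fall inside the
#' standard range; otherwise an error instructs re-dilution, mirroring
#' the lab rule that samples are diluted into the standard range.
#' Responses below the intercept are an error, never silently clamped
#' to zero.
#'
#' @param response detector response(s).
#' @param curve a `calibration_curve`.
#' @param dilution_factor dilution applied before measurement (>= 1);
#'   the amino-acid protocol uses 1:4, i.e. 4.
#' @return Concentration(s) in umol/L of the original sample.
#' @export
quantify <- function(response, curve, dilution_factor = 1) {
  stopifnot(inherits(curve, "calibration_curve"), is.numeric(response),
            is.numeric(dilution_factor), length(dilution_factor) == 1L,
            dilution_factor >= 1)
  back <- (response - curve$intercept) / curve$slope
  tol <- 1e-9 * max(1, abs(curve$valid_range[2]))
  # a response exactly at the intercept (concentration zero) is allowed
  out_of_range <- (back < -tol) |
    (back > 0 & (back < curve$valid_range[1] - tol | back > curve$valid_range[2] + tol))
  if (any(out_of_range)) {
    stop(sprintf(paste0("back-calculated concentration %.6g umol/L is outside the ",
                        "standard range [%g, %g]; re-dilute the sample into range"),
                 back[which(out_of_range)[1]],
                 curve$valid_range[1], curve$valid_range[2]))
  }
  pmax(back, 0) * dilution_factor
}

#' Amino-acid panel from peak areas
#'
#' Quantifies each reported amino acid against its own per-run external
#' standard curve. Valine and methionine are excluded by default: they
#' sit inside the ammonium signal-noise peak and cannot be evaluated in
#' high-NH4+ samples. Excluded codes are dropped from the panel and its
#' total, with a message.
#'
#' @param peak_areas named numeric vector of peak areas per amino acid.
#' @param curves named list of `calibration_curve` objects covering
#'   every reported (non-excluded) amino acid.
#' @param dilution_factor dilution applied to the samples (>= 1).
#' @param excluded codes to drop; default `c("Val", "Met")`.
#' @return An object of class `aa_panel` with `concentrations_umol_l`,
#'   `excluded`, `total_umol_l`.
#' @export
panel_from_peaks <- function(peak_areas, curves, dilution_factor = 1,
                             excluded = c("Val", "Met")) {
  stopifnot(is.numeric(peak_areas), !is.null(names(peak_areas)), is.list(curves))
  unknown <- setdiff(names(peak_areas), names(aa_molar_masses))
  if (length(unknown) > 0L) stop("unknown amino-acid code: ", paste(unknown, collapse = ", "))
  dropped <- intersect(names(peak_areas), excluded)
  if (length(dropped) > 0L) {
    message("excluding from evaluation (ammonium-peak interference): ",
            paste(dropped, collapse = ", "))
  }
  keep <- setdiff(names(peak_areas), excluded)
  missing_curve <- setdiff(keep, names(curves))
  if (length(missing_curve) > 0L) {
    stop("no calibration curve for: ", paste(missing_curve, collapse = ", "))
  }
  conc <- vapply(keep, function(a) {
    quantify(peak_areas[[a]], curves[[a]], dilution_factor)
  }, numeric(1))
  structure(list(
    concentrations_umol_l = conc,
    excluded = dropped,
    total_umol_l = sum(conc)
  ), class = "aa_panel")
}

#' @export
print.aa_panel <- function(x, ...) {
  cat("<aa_panel> total", signif(x$total_umol_l, 5), "umol/L over",
      length(x$concentrations_umol_l), "amino acids")
  if (length(x$excluded)) cat(" | excluded:", paste(x$excluded, collapse = ", "))
  cat("\n")
  invisible(x)
}
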