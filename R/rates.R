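#' Soil process-rate estimation
#'
#' Slurry assays for potential nitrification (PNR, NO3--N accumulation
#' over six sampling times) and denitrification enzyme activity (DEA,
#' gas accumulation under acetylene block at four time points) are
#' summarised as the slope of an ordinary least-squares fit of
#' concentration on time. qPCR absolute quantification applies a
#' log-linear standard curve with R-squared and amplification-efficiency
#' QC gates; RubisCO carboxylation activity is derived from NADH
#' oxidation at 340 nm in a coupled spectrophotometric assay.
#'
#' @name process_rates
NULL

#' OLS slope of an assay time series
#'
#' @param times sampling times (hours); >= 2 distinct values.
#' @param values measured concentrations.
#' @return list with `slope`, `se` (standard error; 0 for a perfect
#'   2-point or noiseless fit), `intercept`, `n`.
#' @export
linear_rate <- function(times, values) {
  if (length(times) != length(values)) stop("length mismatch")
  if (length(unique(times)) < 2) stop("need >= 2 distinct time points")
  fit <- stats::lm(values ~ times)
  se <- if (length(times) == 2) 0 else
    suppressWarnings(summary(fit))$coefficients[2, 2]
  list(slope = unname(coef(fit)[2]), se = unname(se),
       intercept = unname(coef(fit)[1]), n = length(times))
}

#' DEA rate from the latest four time points
#'
#' When more than four time points are supplied, the four latest are
#' used, honouring the four-point regression convention of the assay.
#'
#' @param times,values as in [linear_rate()].
#' @param n_points number of latest time points to use (default 4).
#' @return as [linear_rate()].
#' @export
dea_rate <- function(times, values, n_points = 4L) {
  ord <- order(times)
  times <- times[ord]; values <- values[ord]
  if (length(times) > n_points) {
    keep <- seq(length(times) - n_points + 1L, length(times))
    times <- times[keep]; values <- values[keep]
  }
  linear_rate(times, values)
}

#' Fit a qPCR standard curve
#'
#' OLS of Cq on log10 copy number. Amplification efficiency is
#' 10^(-1/slope) - 1 (1.0 = perfect doubling at slope -3.3219). QC
#' flags are raised when R-squared <= 0.98 or efficiency < 0.85.
#'
#' @param log10_copies log10 copy numbers of the dilution series
#'   (>= 3 points spanning >= 2 log10 units).
#' @param cq quantification-cycle values.
#' @return a `standard_curve`: `slope`, `intercept`, `r_squared`,
#'   `efficiency`, logical `qc_pass`, and `qc_flags`.
#' @export
qpcr_standard_curve <- function(log10_copies, cq) {
  if (length(log10_copies) < 3) stop("need >= 3 dilution points")
  if (diff(range(log10_copies)) < 2)
    stop("dilution series must span >= 2 log10 units")
  fit <- stats::lm(cq ~ log10_copies)
  slope <- unname(coef(fit)[2])
  if (slope >= 0) stop("positive slope: inverted dilution series?")
  r2 <- suppressWarnings(summary(fit))$r.squared
  eff <- 10^(-1 / slope) - 1
  flags <- c(if (r2 <= 0.98) "low_r_squared",
             if (eff < 0.85) "low_efficiency")
  structure(list(slope = slope, intercept = unname(coef(fit)[1]),
                 r_squared = r2, efficiency = eff,
                 qc_pass = length(flags) == 0,
                 qc_flags = flags %||% character(0)),
            class = "standard_curve")
}

#' Absolute quantification from a standard curve
#'
#' copies per reaction = 10^((Cq - intercept)/slope), scaled by the
#' dilution factor and normalised per gram of dry soil.
#'
#' @param cq observed Cq value(s).
#' @param curve a [qpcr_standard_curve()] that passed QC (or set
#'   `override_qc = TRUE`).
#' @param dilution_factor fold dilution of the template (default 1).
#' @param soil_mass_g grams of dry soil represented per reaction
#'   (default 1).
#' @param override_qc allow quantification from a failed curve.
#' @return copies per gram dry soil.
#' @export
qpcr_quantify <- function(cq, curve, dilution_factor = 1, soil_mass_g = 1,
                          override_qc = FALSE) {
  stopifnot(inherits(curve, "standard_curve"))
  if (!curve$qc_pass && !override_qc)
    stop("standard curve failed QC (",
         paste(curve$qc_flags, collapse = ", "),
         "); set override_qc = TRUE to force")
  if (soil_mass_g <= 0) stop("soil mass must be positive")
  copies_rxn <- 10^((cq - curve$intercept) / curve$slope)
  copies_rxn * dilution_factor / soil_mass_g
}

#' RubisCO activity from a coupled NADH-oxidation assay
#'
#' Carboxylation is followed as the decline of A340 (NADH oxidation) in
#' a coupled assay; a preparation lacking RuBP serves as the blank. The
#' blank-corrected absorbance slope is converted with the NADH molar
#' extinction coefficient (6.22 mM^-1 cm^-1) and the 2:1 NADH:CO2
#' stoichiometry of the coupled reaction:
#'
#'   rate = (|dA/dt|_sample - |dA/dt|_blank) / (eps * path) * volume /
#'          (2 * dry_mass * extract_fraction)
#'
#' in nmol CO2 min^-1 per kg dry soil. Negative blank-corrected rates
#' are clamped to 0 with a warning.
#'
#' @param sample_times,sample_a340 time (min) and A340 of the reaction.
#' @param blank_times,blank_a340 time and A340 of the RuBP-free blank.
#' @param volume_ml reaction volume (mL).
#' @param path_cm cuvette path length (cm).
#' @param dry_mass_kg dry soil mass represented by the extract (kg).
#' @param extract_fraction fraction of the extract assayed.
#' @param epsilon_mM NADH extinction coefficient (mM^-1 cm^-1).
#' @param nadh_per_co2 NADH oxidised per CO2 fixed.
#' @return activity in nmol CO2 min^-1 kg^-1 dry soil.
#' @export
rubisco_activity <- function(sample_times, sample_a340,
                             blank_times, blank_a340,
                             volume_ml = 1, path_cm = 1,
                             dry_mass_kg = 0.001, extract_fraction = 1,
                             epsilon_mM = 6.22, nadh_per_co2 = 2) {
  if (volume_ml <= 0 || path_cm <= 0 || dry_mass_kg <= 0 ||
      extract_fraction <= 0)
    stop("volume, path, mass and extract fraction must be positive")
  s_rate <- abs(linear_rate(sample_times, sample_a340)$slope)
  b_rate <- abs(linear_rate(blank_times, blank_a340)$slope)
  net <- s_rate - b_rate
  if (net < 0) {
    warning("blank rate exceeds sample rate; activity clamped at 0")
    return(0)
  }
  # dA/min / (mM^-1 cm^-1 * cm) = mM NADH/min = umol/mL/min = nmol/uL/min
  nadh_mM_min <- net / (epsilon_mM * path_cm)
  nmol_min <- nadh_mM_min * 1000 * volume_ml  # mM * mL = umol -> nmol
  nmol_min / (nadh_per_co2 * dry_mass_kg * extract_fraction)
}
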