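#' Conversion parameters for biomonitoring data
#'
#' Matrix fat contents and intake assumptions used to convert lipid-weight
#' biomonitoring measurements to molarity and daily intake: 5.8 g fat per
#' litre of serum (cord blood), 33 g fat per litre of breast milk, and a
#' breast-milk intake of 1 L/day. Molar masses default to the bundled
#' literature table (the flame-retardant panel of the battery).
#'
#' @param serumFat,milkFat fat contents, g/L.
#' @param intake daily breast-milk intake, L/day.
#' @param molarMass named numeric vector, g/mol per compound.
#' @return list of conversion parameters.
#' @export
conversionParams <- function(serumFat = 5.8, milkFat = 33, intake = 1,
                             molarMass = molarMasses()) {
  stopIfNot(serumFat > 0 && milkFat > 0 && intake > 0,
            "fat contents and intake must be strictly positive")
  stopIfNot(all(molarMass > 0), "molar masses must be strictly positive")
  list(serumFat = serumFat, milkFat = milkFat, intake = intake,
       molarMass = molarMass)
}

#' Bundled molar masses of the flame-retardant panel
#'
#' Literature molecular weights (g/mol) of the 15 flame retardants tested in
#' the battery, bundled because biomonitoring sources report mass
#' concentrations.
#'
#' @return Named numeric vector, g/mol.
#' @export
molarMasses <- function() {
  path <- system.file("extdata", "molar_masses.csv", package = "dntbattery")
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stats::setNames(df$molar_mass_g_mol, df$compound)
}

#' Bundled biomonitoring exposure records
#'
#' Published flame-retardant measurements in human breast milk and cord blood
#' (per region), as transcribed exposure records: lipid-weight concentrations
#' in ng/g lipid weight and plasma/milk concentrations in ng/mL, together
#' with the source's own printed micromolar conversion
#' (\code{uM_printed}). Note that the printed lipid-weight micromolar values
#' differ from the stated conversion formula by a consistent factor of ~10;
#' \code{\link{toMolar}} follows the formula, and intake computations that aim
#' to reproduce the source's daily-intake figures should start from
#' \code{uM_printed}.
#'
#' @return data.frame with columns \code{compound}, \code{matrix},
#'   \code{region}, \code{value}, \code{unit}, \code{uM_printed}.
#' @export
exposureRecords <- function() {
  path <- system.file("extdata", "exposure_table.csv", package = "dntbattery")
  utils::read.csv(path, stringsAsFactors = FALSE)
}

.matrixFat <- function(matrix, params) {
  switch(matrix,
    breast_milk = params$milkFat,
    cord_blood = params$serumFat,
    stop(sprintf("matrix '%s' has no defined fat content", matrix),
         call. = FALSE))
}

#' Convert a biomonitoring measurement to molarity
#'
#' Lipid-weight records (ng per g fat) are converted as
#' \code{uM = value * fat(g/L) / molarMass(g/mol) / 1000}; volumetric records
#' (ng/mL, i.e. ug/L) as \code{uM = value / molarMass}. No rounding is applied
#' (round only at reporting).
#'
#' @param compound compound label (must have a molar mass in \code{params}).
#' @param value measured concentration.
#' @param unit \code{"ng_per_g_lipid"} or \code{"ng_per_mL"}.
#' @param matrix \code{"breast_milk"}, \code{"cord_blood"} or
#'   \code{"other_fluid"} (lipid-weight units require a matrix with a defined
#'   fat content).
#' @param params conversion parameters, see \code{\link{conversionParams}}.
#' @return Concentration in uM. Vectorized over \code{compound},
#'   \code{value}, \code{unit} and \code{matrix}.
#' @examples
#' p <- conversionParams()
#' toMolar("TBOEP", 1.44, "ng_per_mL", "breast_milk", p)  # ~0.0036
#' @export
toMolar <- function(compound, value, unit, matrix, params = conversionParams()) {
  stopIfNot(all(value >= 0), "exposure values must be >= 0")
  n <- max(length(compound), length(value), length(unit), length(matrix))
  compound <- rep_len(compound, n); value <- rep_len(value, n)
  unit <- rep_len(unit, n); matrix <- rep_len(matrix, n)
  vapply(seq_len(n), function(i) {
    mm <- if (compound[i] %in% names(params$molarMass))
      params$molarMass[[compound[i]]] else NA_real_
    if (is.null(mm) || is.na(mm))
      stop(sprintf("no molar mass known for compound '%s'", compound[i]),
           call. = FALSE)
    switch(unit[i],
      ng_per_g_lipid = value[i] * .matrixFat(matrix[i], params) / mm / 1000,
      ng_per_mL = value[i] / mm,   # ng/mL = ug/L; ug/L / (g/mol) = umol/L
      stop(sprintf("unknown unit '%s'", unit[i]), call. = FALSE))
  }, numeric(1))
}

#' Daily intake from a breast-milk concentration
#'
#' \code{nmol/day = conc(umol/L) * intake(L/day) * 1000}. Linear in both the
#' concentration and the intake volume; report rounded to whole nmol/day.
#'
#' @param conc concentration, uM (umol/L).
#' @param params conversion parameters (\code{intake} in L/day).
#' @return Intake in nmol/day (unrounded).
#' @examples
#' dailyIntake(0.0554)  # ~55 nmol/day
#' @export
dailyIntake <- function(conc, params = conversionParams()) {
  stopIfNot(all(conc >= 0), "concentration must be >= 0")
  conc * params$intake * 1000
}

#' Margin between in vitro hazard and exposure
#'
#' Orders of magnitude separating the BMC of a compound's most sensitive
#' endpoint from an exposure concentration: \code{log10(bmc / exposure)}.
#' Positive values mean the hazard concentration lies above the exposure
#' estimate. This deliberately crude in vitro-to-exposure comparison assumes
#' 100% bioavailability and 1:1 blood-brain transfer and involves no kinetic
#' modelling.
#'
#' @param bmcMse MSE benchmark concentration, uM (> 0).
#' @param exposure exposure concentration, uM (> 0).
#' @return log10 ratio (vectorized).
#' @examples
#' exposureMargin(1, 0.1)  # 1.0: one order of magnitude separation
#' @export
exposureMargin <- function(bmcMse, exposure) {
  stopIfNot(all(bmcMse > 0) && all(exposure > 0),
            "bmcMse and exposure must be strictly positive")
  log10(bmcMse / exposure)
}

#' Exposure summary table
#'
#' Applies \code{\link{toMolar}} and \code{\link{dailyIntake}} to a set of
#' exposure records and, when MSE BMCs are supplied, adds the exposure margin.
#' Reported micromolar values are rounded to 4 decimals and intakes to whole
#' nmol/day, matching the conventional reporting precision; unrounded columns
#' are retained alongside.
#'
#' @param records data.frame as returned by \code{\link{exposureRecords}}.
#' @param params conversion parameters.
#' @param mse optional named numeric vector of MSE BMCs (uM) per compound.
#' @return data.frame with computed \code{uM}, \code{intake_nmol_day} and
#'   optional \code{margin_log10} columns; carries attribute
#'   \code{"assumptions"} recording the crude IVIVE caveats.
#' @export
exposureSummary <- function(records, params = conversionParams(), mse = NULL) {
  uM <- toMolar(records$compound, records$value, records$unit, records$matrix,
                params)
  intake <- ifelse(records$matrix == "breast_milk",
                   dailyIntake(uM, params), NA_real_)
  out <- cbind(records,
               uM = uM, uM_reported = round(uM, 4),
               intake_nmol_day = intake,
               intake_reported = round(intake))
  if (!is.null(mse)) {
    m <- unname(mse[out$compound])
    out$margin_log10 <- NA_real_
    ok <- !is.na(m) & m > 0 & uM > 0
    if (any(ok)) out$margin_log10[ok] <- exposureMargin(m[ok], uM[ok])
  }
  attr(out, "assumptions") <- paste(
    "crude in vitro-to-exposure comparison: 100% bioavailability,",
    "no kinetic modelling, 1:1 blood-brain transfer assumed")
  out
}
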