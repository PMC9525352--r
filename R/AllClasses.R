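#' @import methods
NULL

.CURVE_MODELS <- c("sigmoid_decreasing", "sigmoid_increasing", "bell", "flat")
.DIRECTIONS <- c("decrease_adverse", "increase_adverse", "both")
.LABELS <- c("specific", "borderline", "unspecific", "negative")
.CLASSIFICATIONS <- c("specific", "borderline", "unspecific", "no_hit")
.ROLES <- c("dnt", "viability", "cytotoxicity")
.ASSAYS <- c("NPC", "UKN2", "UKN4", "UKN5")

#' CurveSpec: a true concentration-response curve
#'
#' Parameterizes a noiseless concentration-response curve on the
#' percent-of-control scale, used by the synthetic screen generator as ground
#' truth. Monotone curves are four-parameter logistics (4PL); the bell shape is
#' an anchored double sigmoid that starts at control level (100%), rises to
#' \code{top} around \code{ec50} and falls to \code{bottom} around
#' \code{ec50Secondary} (the biphasic rise-then-fall response seen for some
#' developmental neurotoxicants).
#'
#' @slot model character, one of \code{"sigmoid_decreasing"},
#'   \code{"sigmoid_increasing"}, \code{"bell"}, \code{"flat"}.
#' @slot bottom,top asymptotes, percent of control.
#' @slot ec50 half-maximal concentration, uM (ascending limb for bell).
#' @slot hill Hill slope (dimensionless, > 0).
#' @slot ec50Secondary uM, descending-limb midpoint (bell only, > ec50).
#' @slot noiseSd additive Gaussian well noise, percent-of-control units.
#' @name CurveSpec-class
#' @aliases CurveSpec-class
#' @exportClass CurveSpec
setClass("CurveSpec",
  representation(
    model = "character",
    bottom = "numeric",
    top = "numeric",
    ec50 = "numeric",
    hill = "numeric",
    ec50Secondary = "numeric",
    noiseSd = "numeric"
  ),
  prototype(
    model = "flat", bottom = 100, top = 100, ec50 = 1, hill = 1,
    ec50Secondary = NA_real_, noiseSd = 0
  )
)

setValidity("CurveSpec", function(object) {
  msg <- character()
  if (!object@model %in% .CURVE_MODELS)
    msg <- c(msg, sprintf("model must be one of: %s",
                          paste(.CURVE_MODELS, collapse = ", ")))
  if (!is.na(object@ec50) && object@ec50 <= 0)
    msg <- c(msg, "ec50 must be > 0")
  if (identical(object@model, "bell")) {
    if (is.na(object@ec50Secondary) || object@ec50Secondary <= object@ec50)
      msg <- c(msg, "ec50Secondary must be > ec50 for bell curves")
  }
  if (object@bottom > object@top)
    msg <- c(msg, "bottom must be <= top")
  if (object@noiseSd < 0)
    msg <- c(msg, "noiseSd must be >= 0")
  if (!is.na(object@hill) && object@hill <= 0)
    msg <- c(msg, "hill must be > 0 (orientation is carried by `model`)")
  if (length(msg)) msg else TRUE
})

#' ScreenScenario: one compound x DNT endpoint simulation scenario
#'
#' Bundles the true DNT curve, the paired viability/cytotoxicity curves, the
#' dilution design and the intended ground-truth label for one compound in a
#' synthetic screen.
#'
#' @slot compound,endpoint character labels.
#' @slot assay assay family: \code{"NPC"}, \code{"UKN2"}, \code{"UKN4"},
#'   \code{"UKN5"}; decides the downstream classification route.
#' @slot dntCurve a \code{CurveSpec}.
#' @slot viabilityCurves named list of \code{CurveSpec} (names are the
#'   reference endpoint labels); the role of each reference endpoint is taken
#'   from its label (\code{"LDH*"} = cytotoxicity, otherwise viability).
#' @slot topConc,dilutionFactor,nConcentrations serial dilution design (uM,
#'   ratio > 1, count >= 5).
#' @slot nReplicates replicate wells per condition (>= 3).
#' @slot direction adversity direction of the DNT endpoint.
#' @slot intendedLabel ground truth: \code{"specific"}, \code{"borderline"},
#'   \code{"unspecific"}, \code{"negative"}.
#' @name ScreenScenario-class
#' @aliases ScreenScenario-class
#' @exportClass ScreenScenario
setClass("ScreenScenario",
  representation(
    compound = "character",
    endpoint = "character",
    assay = "character",
    dntCurve = "CurveSpec",
    viabilityCurves = "list",
    topConc = "numeric",
    dilutionFactor = "numeric",
    nConcentrations = "integer",
    nReplicates = "integer",
    direction = "character",
    intendedLabel = "character"
  )
)

setValidity("ScreenScenario", function(object) {
  msg <- character()
  if (object@dilutionFactor <= 1) msg <- c(msg, "dilutionFactor must be > 1")
  if (object@nConcentrations < 5L) msg <- c(msg, "nConcentrations must be >= 5")
  if (object@nReplicates < 3L) msg <- c(msg, "nReplicates must be >= 3")
  if (object@topConc <= 0) msg <- c(msg, "topConc must be > 0")
  if (!object@assay %in% .ASSAYS)
    msg <- c(msg, sprintf("assay must be one of: %s", paste(.ASSAYS, collapse = ", ")))
  if (!object@direction %in% .DIRECTIONS)
    msg <- c(msg, sprintf("direction must be one of: %s", paste(.DIRECTIONS, collapse = ", ")))
  if (!object@intendedLabel %in% .LABELS)
    msg <- c(msg, sprintf("intendedLabel must be one of: %s", paste(.LABELS, collapse = ", ")))
  if (length(object@viabilityCurves)) {
    if (is.null(names(object@viabilityCurves)) ||
        any(!nzchar(names(object@viabilityCurves))))
      msg <- c(msg, "viabilityCurves must be a named list")
    if (!all(vapply(object@viabilityCurves, is, logical(1), "CurveSpec")))
      msg <- c(msg, "viabilityCurves must contain CurveSpec objects")
  }
  if (length(msg)) msg else TRUE
})

#' FitResult: a fitted concentration-response model
#'
#' @slot model \code{"sigmoid"} or \code{"bell"}.
#' @slot bottom,top fitted asymptotes (percent of control). For the bell model
#'   \code{top} is the peak plateau and \code{bottom} the high-concentration
#'   plateau; the low-concentration baseline is anchored at 100.
#' @slot log10Ec50,hill primary limb parameters (uM scale; for the sigmoid the
#'   sign of \code{hill} carries the orientation, negative = decreasing).
#' @slot log10Ec50Secondary,hillSecondary descending-limb parameters (bell
#'   only; \code{NA} for sigmoid).
#' @slot rss residual sum of squares.
#' @slot nPoints number of fitted points.
#' @slot aicc small-sample corrected Akaike information criterion.
#' @slot converged logical.
#' @name FitResult-class
#' @aliases FitResult-class
#' @exportClass FitResult
setClass("FitResult",
  representation(
    model = "character",
    bottom = "numeric",
    top = "numeric",
    log10Ec50 = "numeric",
    hill = "numeric",
    log10Ec50Secondary = "numeric",
    hillSecondary = "numeric",
    rss = "numeric",
    nPoints = "integer",
    aicc = "numeric",
    converged = "logical"
  ),
  prototype(
    model = "sigmoid", bottom = NA_real_, top = NA_real_,
    log10Ec50 = NA_real_, hill = NA_real_,
    log10Ec50Secondary = NA_real_, hillSecondary = NA_real_,
    rss = NA_real_, nPoints = 0L, aicc = NA_real_, converged = FALSE
  )
)

setValidity("FitResult", function(object) {
  msg <- character()
  if (!object@model %in% c("sigmoid", "bell"))
    msg <- c(msg, "model must be 'sigmoid' or 'bell'")
  if (isTRUE(object@converged) &&
      any(!is.finite(c(object@bottom, object@top, object@log10Ec50, object@hill))))
    msg <- c(msg, "converged fits must have finite parameters")
  if (length(msg)) msg else TRUE
})

#' BMCEstimate: a benchmark concentration with confidence bounds
#'
#' @slot bmr benchmark response, percent effect relative to control (0-100).
#' @slot direction adversity direction used to read the BMC off the curve.
#' @slot bmc benchmark concentration (uM); \code{NA} when censored.
#' @slot ciLower,ciUpper percentile-bootstrap confidence bounds (uM);
#'   \code{NA} when censored or when no CI was computed.
#' @slot censored TRUE when the curve does not cross the benchmark response
#'   within the tested concentration range.
#' @slot nBoot number of bootstrap resamples behind the CI (0 = none).
#' @slot seed RNG seed used for the bootstrap.
#' @slot unreliable TRUE when more than half of the bootstrap refits failed or
#'   were censored.
#' @name BMCEstimate-class
#' @aliases BMCEstimate-class
#' @exportClass BMCEstimate
setClass("BMCEstimate",
  representation(
    bmr = "numeric",
    direction = "character",
    bmc = "numeric",
    ciLower = "numeric",
    ciUpper = "numeric",
    censored = "logical",
    nBoot = "integer",
    seed = "integer",
    unreliable = "logical"
  ),
  prototype(
    bmr = 20, direction = "decrease_adverse", bmc = NA_real_,
    ciLower = NA_real_, ciUpper = NA_real_, censored = TRUE,
    nBoot = 0L, seed = NA_integer_, unreliable = FALSE
  )
)

setValidity("BMCEstimate", function(object) {
  msg <- character()
  if (object@bmr <= 0 || object@bmr >= 100)
    msg <- c(msg, "bmr must lie in (0, 100)")
  if (!object@direction %in% .DIRECTIONS)
    msg <- c(msg, sprintf("direction must be one of: %s",
                          paste(.DIRECTIONS, collapse = ", ")))
  if (object@censored) {
    if (!is.na(object@bmc))
      msg <- c(msg, "censored estimates carry no point estimate")
    if (!is.na(object@ciLower) || !is.na(object@ciUpper))
      msg <- c(msg, "censored estimates carry no CI")
  } else {
    if (is.na(object@bmc) || object@bmc <= 0)
      msg <- c(msg, "non-censored estimates need bmc > 0")
    if (!is.na(object@ciLower) && !is.na(object@ciUpper)) {
      if (!(object@ciLower <= object@bmc && object@bmc <= object@ciUpper))
        msg <- c(msg, "ciLower <= bmc <= ciUpper must hold")
    }
  }
  if (length(msg)) msg else TRUE
})

#' HitCall: specificity classification of one DNT endpoint for one compound
#'
#' @slot compound,endpoint character labels.
#' @slot classification \code{"specific"}, \code{"borderline"},
#'   \code{"unspecific"} or \code{"no_hit"}.
#' @slot basis evidence used: \code{"ci_overlap"} (NPC-family CI overlap rule)
#'   or \code{"viability_ratio"} (UKN ratio rule, also the zero-variance
#'   fallback for exactly degenerate CIs).
#' @slot overlapFraction worst-case CI overlap fraction across reference
#'   endpoints (present when basis is \code{"ci_overlap"}).
#' @slot ratioValue viability-BMC / endpoint-BMC ratio (present when basis is
#'   \code{"viability_ratio"}; \code{Inf} when viability is censored).
#' @slot referenceEndpoint label of the reference endpoint that drove the call.
#' @slot flagged TRUE when a degenerate-interval fallback was used.
#' @name HitCall-class
#' @aliases HitCall-class
#' @exportClass HitCall
setClass("HitCall",
  representation(
    compound = "character",
    endpoint = "character",
    classification = "character",
    basis = "character",
    overlapFraction = "numeric",
    ratioValue = "numeric",
    referenceEndpoint = "character",
    flagged = "logical"
  ),
  prototype(
    compound = NA_character_, endpoint = NA_character_,
    classification = "no_hit", basis = "ci_overlap",
    overlapFraction = NA_real_, ratioValue = NA_real_,
    referenceEndpoint = NA_character_, flagged = FALSE
  )
)

setValidity("HitCall", function(object) {
  msg <- character()
  if (!object@classification %in% .CLASSIFICATIONS)
    msg <- c(msg, sprintf("classification must be one of: %s",
                          paste(.CLASSIFICATIONS, collapse = ", ")))
  if (!object@basis %in% c("ci_overlap", "viability_ratio", "none"))
    msg <- c(msg, "basis must be 'ci_overlap', 'viability_ratio' or 'none'")
  if (object@classification != "no_hit") {
    if (identical(object@basis, "ci_overlap") && is.na(object@overlapFraction))
      msg <- c(msg, "ci_overlap basis requires overlapFraction")
    if (identical(object@basis, "viability_ratio") && is.na(object@ratioValue))
      msg <- c(msg, "viability_ratio basis requires ratioValue")
  }
  if (!is.na(object@overlapFraction) &&
      (object@overlapFraction < 0 || object@overlapFraction > 1))
    msg <- c(msg, "overlapFraction must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' CompoundProfile: per-compound battery summary
#'
#' Maps each DNT endpoint of one compound to its \code{BMCEstimate} and
#' \code{HitCall}, and records the most sensitive endpoint (MSE): the specific
#' hit with the lowest BMC.
#'
#' @slot compound character label.
#' @slot bmcEstimates named list of \code{BMCEstimate} (names = endpoints).
#' @slot hitCalls named list of \code{HitCall} (names = endpoints).
#' @slot mseEndpoint MSE endpoint label; \code{NA} when no specific hit.
#' @slot mseBmc MSE benchmark concentration (uM); \code{NA} when no specific
#'   hit.
#' @name CompoundProfile-class
#' @aliases CompoundProfile-class
#' @exportClass CompoundProfile
setClass("CompoundProfile",
  representation(
    compound = "character",
    bmcEstimates = "list",
    hitCalls = "list",
    mseEndpoint = "character",
    mseBmc = "numeric"
  ),
  prototype(
    compound = NA_character_, bmcEstimates = list(), hitCalls = list(),
    mseEndpoint = NA_character_, mseBmc = NA_real_
  )
)

setValidity("CompoundProfile", function(object) {
  msg <- character()
  if (!identical(sort(names(object@bmcEstimates)), sort(names(object@hitCalls))))
    msg <- c(msg, "bmcEstimates and hitCalls must cover the same endpoints")
  specific <- vapply(object@hitCalls,
                     function(h) identical(h@classification, "specific"),
                     logical(1))
  if (!any(specific) && !is.na(object@mseEndpoint))
    msg <- c(msg, "mseEndpoint must be absent when no specific hit exists")
  if (length(msg)) msg else TRUE
})

#' ReportBundle: all pipeline outputs of one run
#'
#' @slot bmcTable data.frame, one row per compound x endpoint x BMR with BMC,
#'   CI, censoring, classification and MSE marker (Table-1-like semantics).
#' @slot hitTable data.frame of hit calls.
#' @slot sliceScores data.frame of ToxPi slice scores.
#' @slot toxpiTable data.frame of compound-level ToxPi scores.
#' @slot rankingTable data.frame of the merged MSE + ToxPi ranking.
#' @slot flagsTable data.frame of per-concentration ANOVA significance flags.
#' @slot exposureTable data.frame of exposure conversions (may have 0 rows).
#' @slot groundTruth data.frame of simulation ground truth (may have 0 rows).
#' @slot metadata list: config hash, seed, package version, stage timings.
#' @name ReportBundle-class
#' @aliases ReportBundle-class
#' @exportClass ReportBundle
setClass("ReportBundle",
  representation(
    bmcTable = "data.frame",
    hitTable = "data.frame",
    sliceScores = "data.frame",
    toxpiTable = "data.frame",
    rankingTable = "data.frame",
    flagsTable = "data.frame",
    exposureTable = "data.frame",
    groundTruth = "data.frame",
    metadata = "list"
  )
)
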