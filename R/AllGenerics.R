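#' Accessors for dntbattery S4 objects
#'
#' Small accessor generics so downstream code never touches slots directly.
#'
#' @param object a dntbattery S4 object.
#' @return The corresponding slot value.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("bmc", function(object) standardGeneric("bmc"))
#' @rdname accessors
#' @export
setGeneric("ciLower", function(object) standardGeneric("ciLower"))
#' @rdname accessors
#' @export
setGeneric("ciUpper", function(object) standardGeneric("ciUpper"))
#' @rdname accessors
#' @export
setGeneric("isCensored", function(object) standardGeneric("isCensored"))
#' @rdname accessors
#' @export
setGeneric("classification", function(object) standardGeneric("classification"))
#' @rdname accessors
#' @export
setGeneric("mseEndpoint", function(object) standardGeneric("mseEndpoint"))
#' @rdname accessors
#' @export
setGeneric("mseBmc", function(object) standardGeneric("mseBmc"))
#' @rdname accessors
#' @export
setGeneric("hitCalls", function(object) standardGeneric("hitCalls"))
#' @rdname accessors
#' @export
setGeneric("bmcEstimates", function(object) standardGeneric("bmcEstimates"))
#' @rdname accessors
#' @export
setGeneric("converged", function(object) standardGeneric("converged"))

#' @rdname accessors
#' @export
setMethod("bmc", "BMCEstimate", function(object) object@bmc)
#' @rdname accessors
#' @export
setMethod("ciLower", "BMCEstimate", function(object) object@ciLower)
#' @rdname accessors
#' @export
setMethod("ciUpper", "BMCEstimate", function(object) object@ciUpper)
#' @rdname accessors
#' @export
setMethod("isCensored", "BMCEstimate", function(object) object@censored)
#' @rdname accessors
#' @export
setMethod("classification", "HitCall", function(object) object@classification)
#' @rdname accessors
#' @export
setMethod("mseEndpoint", "CompoundProfile", function(object) object@mseEndpoint)
#' @rdname accessors
#' @export
setMethod("mseBmc", "CompoundProfile", function(object) object@mseBmc)
#' @rdname accessors
#' @export
setMethod("hitCalls", "CompoundProfile", function(object) object@hitCalls)
#' @rdname accessors
#' @export
setMethod("bmcEstimates", "CompoundProfile", function(object) object@bmcEstimates)
#' @rdname accessors
#' @export
setMethod("converged", "FitResult", function(object) object@converged)

setMethod("show", "CurveSpec", function(object) {
  cat(sprintf("CurveSpec [%s] bottom=%.4g top=%.4g ec50=%.4g uM hill=%.3g",
              object@model, object@bottom, object@top, object@ec50, object@hill))
  if (identical(object@model, "bell"))
    cat(sprintf(" ec50Secondary=%.4g uM", object@ec50Secondary))
  cat(sprintf(" noiseSd=%.3g\n", object@noiseSd))
  invisible(NULL)
})

setMethod("show", "BMCEstimate", function(object) {
  if (object@censored) {
    cat(sprintf("BMC%g: censored (not reached within tested range)\n", object@bmr))
  } else {
    ci <- if (is.na(object@ciLower)) "no CI" else
      sprintf("95%% CI [%.4g, %.4g]", object@ciLower, object@ciUpper)
    cat(sprintf("BMC%g = %.4g uM (%s, %s)%s\n", object@bmr, object@bmc, ci,
                object@direction,
                if (object@unreliable) " [CI unreliable]" else ""))
  }
  invisible(NULL)
})

setMethod("show", "FitResult", function(object) {
  cat(sprintf("FitResult [%s] converged=%s", object@model, object@converged))
  if (object@converged) {
    cat(sprintf(" bottom=%.3g top=%.3g ec50=%.4g uM hill=%.3g",
                object@bottom, object@top, 10^object@log10Ec50, object@hill))
    if (identical(object@model, "bell"))
      cat(sprintf(" ec50_2=%.4g uM hill_2=%.3g",
                  10^object@log10Ec50Secondary, object@hillSecondary))
    cat(sprintf(" AICc=%.2f", object@aicc))
  }
  cat("\n")
  invisible(NULL)
})

setMethod("show", "HitCall", function(object) {
  extra <- switch(object@basis,
    ci_overlap = sprintf("max CI overlap %.3f vs %s", object@overlapFraction,
                         object@referenceEndpoint),
    viability_ratio = sprintf("viability/endpoint BMC ratio %.3g vs %s",
                              object@ratioValue, object@referenceEndpoint),
    "no evidence")
  cat(sprintf("HitCall %s/%s: %s (%s)%s\n", object@compound, object@endpoint,
              object@classification, extra,
              if (object@flagged) " [degenerate-CI fallback]" else ""))
  invisible(NULL)
})

setMethod("show", "CompoundProfile", function(object) {
  cat(sprintf("CompoundProfile %s: %d endpoints\n", object@compound,
              length(object@hitCalls)))
  for (ep in names(object@hitCalls)) {
    est <- object@bmcEstimates[[ep]]
    cat(sprintf("  %-10s %-10s %s", ep, object@hitCalls[[ep]]@classification,
                if (est@censored) "censored" else sprintf("BMC%g=%.4g uM", est@bmr, est@bmc)))
    if (identical(ep, object@mseEndpoint)) cat("  <- MSE")
    cat("\n")
  }
  if (is.na(object@mseEndpoint)) cat("  no specific hit: MSE absent\n")
  invisible(NULL)
})

setMethod("show", "ReportBundle", function(object) {
  cat("ReportBundle\n")
  cat(sprintf("  bmcTable:      %d rows\n", nrow(object@bmcTable)))
  cat(sprintf("  hitTable:      %d rows\n", nrow(object@hitTable)))
  cat(sprintf("  rankingTable:  %d rows\n", nrow(object@rankingTable)))
  cat(sprintf("  exposureTable: %d rows\n", nrow(object@exposureTable)))
  cat(sprintf("  seed=%s configHash=%s\n",
              as.character(object@metadata$seed %||% NA),
              as.character(object@metadata$configHash %||% NA)))
  invisible(NULL)
})
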