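#' Overlap fraction of two BMC confidence intervals
#'
#' Length of the intersection of the DNT-endpoint CI with the reference
#' (viability/cytotoxicity) CI, divided by the length of the DNT-endpoint CI
#' (default) or of the shorter interval. The DNT denominator asks whether the
#' DNT effect is explainable by cytotoxicity within the DNT effect's own
#' concentration range. Returns 0 for disjoint intervals. A degenerate
#' (zero-length) DNT interval is computed against the reference interval
#' length instead and flagged; when both intervals are degenerate the fraction
#' is 1 for coincident points and 0 otherwise (also flagged).
#'
#' @param ciDnt,ciRef numeric length-2 intervals \code{c(lower, upper)}, uM.
#' @param denominator \code{"dnt"} or \code{"min"} (shorter interval).
#' @return Fraction in [0, 1]; attribute \code{"flagged"} is TRUE when a
#'   degenerate-interval rule was applied.
#' @examples
#' ciOverlapFraction(c(1, 2), c(1.95, 3))  # 0.05
#' @export
ciOverlapFraction <- function(ciDnt, ciRef, denominator = c("dnt", "min")) {
  denominator <- match.arg(denominator)
  stopIfNot(length(ciDnt) == 2 && length(ciRef) == 2 &&
              ciDnt[1] <= ciDnt[2] && ciRef[1] <= ciRef[2],
            "intervals must be c(lower, upper) with lower <= upper")
  inter <- max(0, min(ciDnt[2], ciRef[2]) - max(ciDnt[1], ciRef[1]))
  lenDnt <- ciDnt[2] - ciDnt[1]
  lenRef <- ciRef[2] - ciRef[1]
  flagged <- FALSE
  if (lenDnt == 0 && lenRef == 0) {
    frac <- if (isTRUE(all.equal(ciDnt[1], ciRef[1]))) 1 else 0
    flagged <- TRUE
  } else if (lenDnt == 0) {
    ## zero-length DNT interval: the intersection has measure zero whatever
    ## the denominator, so use the containment limit of intersection/DNT-length
    ## (1 when the point lies inside the reference interval, else 0)
    frac <- as.numeric(ciDnt[1] >= ciRef[1] && ciDnt[1] <= ciRef[2])
    flagged <- TRUE
  } else {
    den <- switch(denominator, dnt = lenDnt,
                  min = if (lenRef > 0) min(lenDnt, lenRef) else lenDnt)
    frac <- inter / den
  }
  structure(min(1, max(0, frac)), flagged = flagged)
}

.ciOrPoint <- function(est) {
  if (is.na(est@ciLower) || is.na(est@ciUpper)) c(est@bmc, est@bmc)
  else c(est@ciLower, est@ciUpper)
}

#' Classify an NPC-family DNT endpoint by CI overlap
#'
#' A DNT effect is specific when its BMC confidence interval does not overlap
#' any reference viability/cytotoxicity BMC interval, unspecific when the
#' worst-case overlap reaches \code{overlapThreshold} (default 10% of the DNT
#' interval), and borderline in between. A censored DNT BMC is no hit; if all
#' reference BMCs are censored (no viability loss in the tested range) the hit
#' is specific. When every interval involved is exactly degenerate (zero
#' width, which arises only for noise-free data where the bootstrap
#' collapses), the call falls back to the reference/DNT BMC ratio with window
#' ratio <= 1.3 unspecific, < 3 borderline, >= 3 specific, recorded with basis
#' \code{"viability_ratio"} and flagged.
#'
#' @param bmcDnt \linkS4class{BMCEstimate} of the DNT endpoint.
#' @param bmcRefs named list of \linkS4class{BMCEstimate} for the reference
#'   endpoints (names are endpoint labels).
#' @param overlapThreshold unspecific threshold on the overlap fraction.
#' @param denominator passed to \code{\link{ciOverlapFraction}}.
#' @param compound,endpoint labels stored in the returned call.
#' @return A \linkS4class{HitCall}.
#' @export
classifyNPC <- function(bmcDnt, bmcRefs, overlapThreshold = 0.10,
                        denominator = "dnt",
                        compound = NA_character_, endpoint = NA_character_) {
  stopifnot(is(bmcDnt, "BMCEstimate"))
  stopIfNot(length(bmcRefs) >= 1, "empty reference endpoint list")
  stopifnot(all(vapply(bmcRefs, is, logical(1), "BMCEstimate")))
  if (is.null(names(bmcRefs)))
    names(bmcRefs) <- sprintf("ref%d", seq_along(bmcRefs))
  mk <- function(cls, basis = "ci_overlap", overlap = NA_real_,
                 ratio = NA_real_, ref = NA_character_, flagged = FALSE)
    new("HitCall", compound = compound, endpoint = endpoint,
        classification = cls, basis = basis, overlapFraction = overlap,
        ratioValue = ratio, referenceEndpoint = ref, flagged = flagged)

  if (bmcDnt@censored) return(mk("no_hit", basis = "none"))
  active <- Filter(function(e) !e@censored, bmcRefs)
  if (!length(active))
    return(mk("specific", overlap = 0))

  ciDnt <- .ciOrPoint(bmcDnt)
  refCis <- lapply(active, .ciOrPoint)
  degDnt <- ciDnt[2] - ciDnt[1] == 0
  degRefs <- all(vapply(refCis, function(ci) ci[2] - ci[1] == 0, logical(1)))
  if (degDnt && degRefs) {
    ratio <- min(vapply(active, function(e) e@bmc, numeric(1))) / bmcDnt@bmc
    refLab <- names(active)[which.min(vapply(active, function(e) e@bmc, numeric(1)))]
    cls <- if (ratio >= 3) "specific" else if (ratio > 1.3) "borderline" else "unspecific"
    return(mk(cls, basis = "viability_ratio", ratio = ratio, ref = refLab,
              flagged = TRUE))
  }

  fracs <- vapply(refCis, function(ci)
    as.numeric(ciOverlapFraction(ciDnt, ci, denominator)), numeric(1))
  flagged <- any(vapply(refCis, function(ci)
    isTRUE(attr(ciOverlapFraction(ciDnt, ci, denominator), "flagged")),
    logical(1)))
  iMax <- which.max(fracs)
  frac <- fracs[iMax]
  cls <- if (frac == 0) "specific"
         else if (frac >= overlapThreshold) "unspecific"
         else "borderline"
  mk(cls, overlap = unname(frac), ref = names(active)[iMax], flagged = flagged)
}

#' Classify a UKN-assay endpoint by the viability/endpoint BMC ratio
#'
#' The UKN assays call a hit specific when the ratio of the viability BMC to
#' the endpoint BMC reaches the assay cutoff (boundary inclusive): 1.3 for
#' UKN2 (BMC10 viability / BMC25 migration), 4 for UKN4 and 3 for UKN5 (BMC25
#' viability / BMC25 neurite area). A censored endpoint BMC is no hit; a
#' censored viability BMC with a reached endpoint BMC is specific (the ratio
#' is effectively infinite). No borderline category exists for UKN assays.
#'
#' @param assay \code{"UKN2"}, \code{"UKN4"} or \code{"UKN5"}.
#' @param bmcEndpoint,bmcViability \linkS4class{BMCEstimate}s at the
#'   assay-appropriate BMRs.
#' @param cutoff ratio cutoff; defaults to the assay's standard cutoff.
#' @param checkBmr verify that the estimates carry the assay's standard BMRs
#'   (set \code{FALSE} when running with custom BMRs).
#' @param compound,endpoint labels stored in the returned call.
#' @return A \linkS4class{HitCall}.
#' @export
classifyUKN <- function(assay, bmcEndpoint, bmcViability, cutoff = NULL,
                        checkBmr = TRUE,
                        compound = NA_character_, endpoint = NA_character_) {
  stopIfNot(assay %in% c("UKN2", "UKN4", "UKN5"),
            "assay must be UKN2, UKN4 or UKN5")
  stopifnot(is(bmcEndpoint, "BMCEstimate"), is(bmcViability, "BMCEstimate"))
  defs <- assayDefaults(assay)
  if (is.null(cutoff)) cutoff <- defs$ratioCutoff
  if (checkBmr &&
      (bmcEndpoint@bmr != defs$endpoint || bmcViability@bmr != defs$viability))
    stop(sprintf("%s expects endpoint BMR %g and viability BMR %g (got %g / %g)",
                 assay, defs$endpoint, defs$viability, bmcEndpoint@bmr,
                 bmcViability@bmr), call. = FALSE)
  mk <- function(cls, ratio, basis = "viability_ratio")
    new("HitCall", compound = compound, endpoint = endpoint,
        classification = cls, basis = basis, ratioValue = ratio,
        referenceEndpoint = "viability")
  if (bmcEndpoint@censored)
    return(new("HitCall", compound = compound, endpoint = endpoint,
               classification = "no_hit", basis = "none"))
  if (bmcViability@censored) return(mk("specific", Inf))
  ratio <- bmcViability@bmc / bmcEndpoint@bmc
  mk(if (ratio >= cutoff) "specific" else "unspecific", ratio)
}

#' Most sensitive endpoint of a compound profile
#'
#' The MSE is the DNT-specific endpoint with the lowest BMC; endpoints whose
#' hits are borderline, unspecific or absent never qualify. Ties are broken by
#' lexicographic endpoint label. Returns \code{NULL} when the compound has no
#' specific hit.
#'
#' @param profile a \linkS4class{CompoundProfile}, or a named list of
#'   \linkS4class{HitCall} together with \code{bmcEstimates}.
#' @param bmcEstimates named list of \linkS4class{BMCEstimate} (only when
#'   \code{profile} is a list of hit calls).
#' @return list with \code{endpoint} and \code{bmc}, or \code{NULL}.
#' @export
mostSensitiveEndpoint <- function(profile, bmcEstimates = NULL) {
  if (is(profile, "CompoundProfile")) {
    calls <- profile@hitCalls
    ests <- profile@bmcEstimates
  } else {
    calls <- profile
    ests <- bmcEstimates
  }
  specific <- names(calls)[vapply(calls, function(h)
    identical(h@classification, "specific"), logical(1))]
  specific <- specific[!vapply(ests[specific], function(e) e@censored, logical(1))]
  if (!length(specific)) return(NULL)
  bmcs <- vapply(ests[specific], function(e) e@bmc, numeric(1))
  ord <- order(bmcs, specific)  # ties: lexicographic endpoint id
  list(endpoint = specific[ord[1]], bmc = unname(bmcs[ord[1]]))
}

#' Build a compound profile
#'
#' Collects the per-endpoint BMC estimates and hit calls of one compound and
#' determines its most sensitive endpoint.
#'
#' @param compound compound label.
#' @param bmcEstimates named list of \linkS4class{BMCEstimate} (names =
#'   DNT endpoints).
#' @param hitCalls named list of \linkS4class{HitCall} over the same
#'   endpoints.
#' @return A \linkS4class{CompoundProfile}.
#' @export
compoundProfile <- function(compound, bmcEstimates, hitCalls) {
  mse <- mostSensitiveEndpoint(hitCalls, bmcEstimates)
  new("CompoundProfile", compound = compound, bmcEstimates = bmcEstimates,
      hitCalls = hitCalls,
      mseEndpoint = if (is.null(mse)) NA_character_ else mse$endpoint,
      mseBmc = if (is.null(mse)) NA_real_ else mse$bmc)
}
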