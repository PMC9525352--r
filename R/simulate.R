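#' Default benchmark responses per assay family
#'
#' The benchmark response (BMR) is the percent deviation from control at which
#' the BMC is read off the fitted curve; it is chosen per endpoint family based
#' on assay variability. Defaults: NPC endpoints BMR 20 (endpoint and
#' viability/cytotoxicity references), UKN2 migration BMR 25 with viability BMR
#' 10, UKN4/UKN5 neurite area and viability BMR 25. All values are
#' configuration, not code, and can be overridden in the pipeline config.
#'
#' @param assay \code{"NPC"}, \code{"UKN2"}, \code{"UKN4"} or \code{"UKN5"}.
#' @return list with elements \code{endpoint} and \code{viability} (BMR values)
#'   and \code{ratioCutoff} (the viability/endpoint BMC ratio above which a UKN
#'   hit counts as specific; \code{NA} for NPC, which uses CI overlap).
#' @export
assayDefaults <- function(assay) {
  switch(assay,
    NPC = list(endpoint = 20, viability = 20, ratioCutoff = NA_real_),
    UKN2 = list(endpoint = 25, viability = 10, ratioCutoff = 1.3),
    UKN4 = list(endpoint = 25, viability = 25, ratioCutoff = 4),
    UKN5 = list(endpoint = 25, viability = 25, ratioCutoff = 3),
    stop("unknown assay family: ", assay)
  )
}

## Label implied by the analytic separation of the true curves; mirrors the
## downstream classifier in the zero-noise limit.
.impliedLabel <- function(scenario) {
  defs <- assayDefaults(scenario@assay)
  dntBmc <- trueBmc(scenario@dntCurve, defs$endpoint, scenario@direction,
                    maxConc = scenario@topConc)
  if (is.na(dntBmc)) return("negative")
  viabBmcs <- vapply(scenario@viabilityCurves, trueBmc, numeric(1),
                     bmr = defs$viability, direction = "decrease_adverse",
                     maxConc = scenario@topConc)
  viabBmcs <- viabBmcs[!is.na(viabBmcs)]
  if (!length(viabBmcs)) return("specific")
  ratio <- min(viabBmcs) / dntBmc
  if (scenario@assay == "NPC") {
    if (ratio >= 3) "specific" else if (ratio > 1.3) "borderline" else "unspecific"
  } else {
    if (ratio >= defs$ratioCutoff) "specific" else "unspecific"
  }
}

#' Construct a simulation scenario
#'
#' One compound x DNT endpoint scenario: the true DNT curve, its paired
#' viability/cytotoxicity reference curves, the serial-dilution plate design
#' and the intended ground-truth label. The constructor asserts that the
#' intended label is consistent with the analytic separation of the true
#' curves (the label the noise-free pipeline must recover).
#'
#' @param compound,endpoint character labels.
#' @param assay assay family (\code{"NPC"}, \code{"UKN2"}, \code{"UKN4"},
#'   \code{"UKN5"}).
#' @param dntCurve a \linkS4class{CurveSpec} for the DNT endpoint.
#' @param viabilityCurves named list of \linkS4class{CurveSpec}; names are the
#'   reference endpoint labels (labels starting with \code{"LDH"} are treated
#'   as cytotoxicity, others as viability).
#' @param topConc,dilutionFactor,nConcentrations serial dilution design.
#' @param nReplicates replicate wells per condition.
#' @param direction adversity direction of the DNT endpoint.
#' @param intendedLabel \code{"specific"}, \code{"borderline"},
#'   \code{"unspecific"} or \code{"negative"}.
#' @return A \linkS4class{ScreenScenario}.
#' @export
screenScenario <- function(compound, endpoint, assay, dntCurve,
                           viabilityCurves = list(),
                           topConc = 20, dilutionFactor = 3,
                           nConcentrations = 7L, nReplicates = 5L,
                           direction = "decrease_adverse",
                           intendedLabel = "specific") {
  obj <- new("ScreenScenario", compound = compound, endpoint = endpoint,
             assay = assay, dntCurve = dntCurve,
             viabilityCurves = viabilityCurves, topConc = topConc,
             dilutionFactor = dilutionFactor,
             nConcentrations = as.integer(nConcentrations),
             nReplicates = as.integer(nReplicates), direction = direction,
             intendedLabel = intendedLabel)
  implied <- .impliedLabel(obj)
  if (!identical(implied, intendedLabel))
    stop(sprintf(paste0("scenario %s/%s: intendedLabel '%s' is inconsistent ",
                        "with the true curve separation (implies '%s')"),
                 compound, endpoint, intendedLabel, implied), call. = FALSE)
  obj
}

#' Simulate replicate-level wells for one endpoint
#'
#' Draws well values as \code{curve(concentration) + Normal(0, noiseSd)} on the
#' percent-of-control scale; solvent-control wells (concentration 0) are drawn
#' around 100 with the same noise so downstream normalization is
#' non-degenerate. Deterministic for a fixed seed; the caller's RNG state is
#' left untouched.
#'
#' @param spec a \linkS4class{CurveSpec}.
#' @param concentrations numeric vector of non-zero concentrations, uM.
#' @param nReplicates wells per concentration (and per control).
#' @param seed integer RNG seed (mandatory).
#' @return data.frame with columns \code{concentration_uM}, \code{replicate},
#'   \code{value_pct_control}; control wells carry concentration 0.
#' @export
simulateEndpoint <- function(spec, concentrations, nReplicates, seed) {
  stopifnot(is(spec, "CurveSpec"))
  stopIfNot(all(concentrations > 0), "treated concentrations must be > 0")
  stopIfNot(isScalarNumber(nReplicates) && nReplicates >= 1,
            "`nReplicates` must be >= 1")
  conc <- c(sort(concentrations, decreasing = TRUE), 0)
  mu <- c(curveValue(spec, conc[conc > 0]), 100)
  df <- data.frame(
    concentration_uM = rep(conc, each = nReplicates),
    replicate = rep(seq_len(nReplicates), times = length(conc)),
    stringsAsFactors = FALSE
  )
  means <- rep(mu, each = nReplicates)
  df$value_pct_control <- withSeed(seed, means +
    if (spec@noiseSd > 0) stats::rnorm(nrow(df), 0, spec@noiseSd) else 0)
  df
}

#' Simulate a full synthetic screen
#'
#' Generates one well record per compound x endpoint x concentration x
#' replicate for a list of scenarios, together with a ground-truth table
#' carrying the intended label and the analytic true BMC of each DNT endpoint.
#' For bell-shaped curves the true BMC is the lowest adverse crossing, which
#' for a rise-then-fall response is the ascending-limb crossing unless only the
#' descending limb reaches the benchmark response; the limb used is documented
#' in the ground-truth table.
#'
#' @param scenarios list of \linkS4class{ScreenScenario}.
#' @param seed integer master seed; per-endpoint child seeds are derived from
#'   it, so the output is byte-identical across calls with the same seed.
#' @return list with \code{wells} (data.frame: compound, endpoint,
#'   concentration_uM, replicate, value_pct_control, role, plate_id) and
#'   \code{truth} (data.frame: compound, endpoint, assay, direction,
#'   intended_label, true_bmc_uM, bmr, limb).
#' @export
simulateBattery <- function(scenarios, seed) {
  stopIfNot(length(scenarios) >= 1, "need at least one scenario")
  stopifnot(all(vapply(scenarios, is, logical(1), "ScreenScenario")))
  keys <- vapply(scenarios, function(s) paste(s@compound, s@endpoint), "")
  if (anyDuplicated(keys))
    stop("duplicate compound/endpoint pairs in scenario list", call. = FALSE)

  wells <- vector("list", length(scenarios))
  truth <- vector("list", length(scenarios))
  streamId <- 0L
  for (i in seq_along(scenarios)) {
    sc <- scenarios[[i]]
    conc <- dilutionSeries(sc@topConc, sc@dilutionFactor, sc@nConcentrations)
    plate <- sprintf("P%02d", i)
    simOne <- function(spec, endpointLabel, role) {
      streamId <<- streamId + 1L
      d <- simulateEndpoint(spec, conc, sc@nReplicates,
                            seed = childSeed(seed, streamId))
      data.frame(compound = sc@compound, endpoint = endpointLabel,
                 concentration_uM = d$concentration_uM,
                 replicate = d$replicate,
                 value_pct_control = d$value_pct_control,
                 role = role, plate_id = plate, stringsAsFactors = FALSE)
    }
    parts <- list(simOne(sc@dntCurve, sc@endpoint, "dnt"))
    for (ref in names(sc@viabilityCurves)) {
      role <- if (startsWith(ref, "LDH")) "cytotoxicity" else "viability"
      parts <- c(parts, list(simOne(sc@viabilityCurves[[ref]], ref, role)))
    }
    wells[[i]] <- do.call(rbind, parts)

    defs <- assayDefaults(sc@assay)
    tb <- trueBmc(sc@dntCurve, defs$endpoint, sc@direction, maxConc = sc@topConc)
    limb <- NA_character_
    if (identical(sc@dntCurve@model, "bell") && !is.na(tb)) {
      asc <- .lowestCrossingNumeric(function(cc) curveValue(sc@dntCurve, cc),
                                    defs$endpoint, "increase_adverse",
                                    maxConc = sc@topConc,
                                    minConc = sc@dntCurve@ec50 * 1e-6)
      limb <- if (!is.na(asc) && asc <= tb * (1 + 1e-9)) "ascending" else "descending"
    }
    truth[[i]] <- data.frame(
      compound = sc@compound, endpoint = sc@endpoint, assay = sc@assay,
      direction = sc@direction, intended_label = sc@intendedLabel,
      true_bmc_uM = tb, bmr = defs$endpoint, limb = limb,
      stringsAsFactors = FALSE)
  }
  list(wells = do.call(rbind, wells), truth = do.call(rbind, truth))
}

#' Reference 12-compound synthetic battery
#'
#' A fixed set of 12 scenarios spanning the four ground-truth constructions
#' (specific, borderline, unspecific, negative) across the battery's assay
#' families and plate designs (NPC: 1:3 series, 7 concentrations, 5 replicate
#' wells; UKN2: 1:2, 6 concentrations, 4 replicates; UKN4: 1:3, 10
#' concentrations, 3 replicates; UKN5: 1:3, 6 concentrations, 3 replicates;
#' top concentration 20 uM throughout). The borderline construction places the
#' viability BMC at twice the DNT BMC, inside the window that is neither
#' clearly separated nor coincident.
#'
#' @param noiseSd additive well noise SD (percent of control) applied to every
#'   curve; 0 gives the noise-free battery.
#' @return list of \linkS4class{ScreenScenario}.
#' @export
defaultBattery <- function(noiseSd = 5) {
  sig <- function(ec50, hill, bottom = 0, top = 100)
    curveSpec("sigmoid_decreasing", bottom = bottom, top = top, ec50 = ec50,
              hill = hill, noiseSd = noiseSd)
  fl <- function() flatCurve(100, noiseSd = noiseSd)
  npc <- function(...) screenScenario(..., topConc = 20, dilutionFactor = 3,
                                      nConcentrations = 7L, nReplicates = 5L)
  list(
    npc("FR01", "NPC5", "NPC", sig(0.1, 2),
        list(CTB = fl(), LDH_120h = fl()), intendedLabel = "specific"),
    npc("FR02", "NPC2a", "NPC", sig(0.3, 1.5),
        list(LDH_120h = fl()), intendedLabel = "specific"),
    npc("FR03", "NPC1b", "NPC", sig(0.5, 2),
        list(CTB = sig(25, 2)), intendedLabel = "specific"),
    screenScenario("FR04", "UKN2", "UKN2", sig(1, 2),
                   list(UKN2_viability = sig(8, 2)),
                   topConc = 20, dilutionFactor = 2, nConcentrations = 6L,
                   nReplicates = 4L, intendedLabel = "specific"),
    npc("FR05", "NPC5", "NPC", sig(1, 1.5),
        list(CTB = sig(2, 1.5)), intendedLabel = "borderline"),
    npc("FR06", "NPC5", "NPC", sig(1, 2),
        list(CTB = sig(1, 2)), intendedLabel = "unspecific"),
    npc("FR07", "NPC3", "NPC", sig(2, 2),
        list(CTB = sig(2.2, 2)), intendedLabel = "unspecific"),
    screenScenario("FR08", "UKN4", "UKN4", sig(2, 2),
                   list(UKN4_viability = sig(4, 2)),
                   topConc = 20, dilutionFactor = 3, nConcentrations = 10L,
                   nReplicates = 3L, intendedLabel = "unspecific"),
    npc("FR09", "NPC5", "NPC", fl(),
        list(CTB = fl()), intendedLabel = "negative"),
    npc("FR10", "NPC1b", "NPC", fl(),
        list(CTB = sig(5, 2)), intendedLabel = "negative"),
    screenScenario("FR11", "UKN5", "UKN5", fl(),
                   list(UKN5_viability = fl()),
                   topConc = 20, dilutionFactor = 3, nConcentrations = 6L,
                   nReplicates = 3L, intendedLabel = "negative"),
    npc("FR12", "NPC5", "NPC",
        curveSpec("bell", bottom = 10, top = 150, ec50 = 0.05, hill = 2,
                  ec50Secondary = 5, noiseSd = noiseSd),
        list(CTB = fl(), LDH_120h = fl()),
        direction = "both", intendedLabel = "specific")
  )
}
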