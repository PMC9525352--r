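.stage <- function(name, quiet, expr) {
  t0 <- proc.time()[["elapsed"]]
  res <- tryCatch(force(expr), error = function(e)
    stop(sprintf("stage '%s': %s", name, conditionMessage(e)), call. = FALSE))
  if (!quiet)
    message(sprintf("[%s] done in %.2fs", name, proc.time()[["elapsed"]] - t0))
  res
}

.configHash <- function(config) {
  keep <- config[setdiff(names(config), c("quiet"))]
  keep <- keep[order(names(keep))]
  tf <- tempfile(fileext = ".rds")
  on.exit(unlink(tf))
  saveRDS(keep, tf, version = 2)
  unname(tools::md5sum(tf))
}

#' Run the full hazard-characterization pipeline
#'
#' Orchestrates simulate/ingest, percent-of-control normalization, ANOVA
#' significance flagging, curve fitting with AICc model selection, BMC and
#' bootstrap-CI estimation, specificity classification, most-sensitive
#' endpoint determination, ToxPi slice scaling, profile clustering, the merged
#' MSE + ToxPi ranking, and (optionally) the exposure comparison. All
#' thresholds are configuration, not code. A fixed config and seed yield an
#' identical bundle.
#'
#' @param config a list with components:
#'   \describe{
#'     \item{scenarios}{list of \linkS4class{ScreenScenario} to simulate, or}
#'     \item{screenFile}{path to a well-level screen table (then
#'       \code{pairing} is required: a pairing configuration list with
#'       \code{pairing}, \code{assay} and optional \code{direction} maps),}
#'     \item{nBoot}{bootstrap resamples per CI (default 200),}
#'     \item{alpha}{significance level for concentration flags (default
#'       0.05),}
#'     \item{overlapThreshold}{CI-overlap fraction above which an NPC hit is
#'       unspecific (default 0.10),}
#'     \item{bmrs}{optional per-assay BMR overrides, as
#'       \code{list(NPC = list(endpoint =, viability =), ...)},}
#'     \item{sentinel}{ToxPi sentinel concentration (default 1e6 uM),}
#'     \item{exposure}{TRUE to append the bundled biomonitoring comparison,}
#'     \item{quiet}{suppress stage logging (default TRUE).}
#'   }
#' @param seed integer master seed for simulation and bootstrap.
#' @return A \linkS4class{ReportBundle}.
#' @export
runPipeline <- function(config, seed) {
  stopIfNot(is.list(config), "`config` must be a list")
  quiet <- isTRUE(config$quiet %||% TRUE)
  nBoot <- as.integer(config$nBoot %||% 200L)
  alpha <- config$alpha %||% 0.05
  overlapThreshold <- config$overlapThreshold %||% 0.10
  sentinel <- config$sentinel %||% 1e6
  bmrs <- config$bmrs %||% list()
  getBmrs <- function(assay) {
    d <- assayDefaults(assay)
    o <- bmrs[[assay]]
    if (!is.null(o)) {
      d$endpoint <- o$endpoint %||% d$endpoint
      d$viability <- o$viability %||% d$viability
      d$ratioCutoff <- o$ratioCutoff %||% d$ratioCutoff
    }
    d
  }
  timings <- list()

  ## ---- acquire wells + endpoint metadata -------------------------------
  truth <- data.frame()
  if (!is.null(config$scenarios)) {
    sim <- .stage("simulate", quiet,
                  simulateBattery(config$scenarios, seed = seed))
    wells <- sim$wells
    truth <- sim$truth
    assayMap <- stats::setNames(truth$assay, paste(truth$compound, truth$endpoint))
    dirMap <- stats::setNames(truth$direction, paste(truth$compound, truth$endpoint))
  } else if (!is.null(config$screenFile)) {
    if (is.null(config$pairing))
      stop("stage 'ingest': config is missing the pairing map", call. = FALSE)
    wells <- .stage("ingest", quiet,
                    readScreenTable(config$screenFile, config$pairing))
    dnt <- unique(wells[wells$role == "dnt", c("compound", "endpoint")])
    assayMap <- stats::setNames(
      vapply(dnt$endpoint, function(ep)
        config$pairing$assay[[ep]] %||%
          stop(sprintf("no assay family configured for endpoint %s", ep)), ""),
      paste(dnt$compound, dnt$endpoint))
    dirMap <- stats::setNames(
      vapply(dnt$endpoint, function(ep)
        config$pairing$direction[[ep]] %||% "decrease_adverse", ""),
      paste(dnt$compound, dnt$endpoint))
  } else {
    stop("config must provide either `scenarios` or `screenFile`", call. = FALSE)
  }

  ## ---- normalize + flag -------------------------------------------------
  wells <- .stage("normalize", quiet, percentOfControl(wells))
  flags <- .stage("flag_significant", quiet, flagSignificant(wells, alpha))

  ## ---- fit + BMC --------------------------------------------------------
  fitOne <- function(d, bmr, direction, fitBell, sd) {
    rng <- range(d$concentration_uM[d$concentration_uM > 0])
    fits <- list(tryCatch(fitCurve(d, "sigmoid"), error = function(e) NULL))
    if (fitBell && length(unique(d$concentration_uM[d$concentration_uM > 0])) >= 5)
      fits <- c(fits, list(tryCatch(fitCurve(d, "bell"), error = function(e) NULL)))
    fits <- Filter(Negate(is.null), fits)
    fit <- selectModel(fits)
    point <- bmcFromFit(fit, bmr, direction, rng)
    est <- if (point@censored || nBoot < 1L) point
           else bmcCI(d, fit, bmr, direction, rng, nBoot = nBoot, seed = sd)
    list(fit = fit, est = est)
  }

  bmcRows <- list(); estStore <- list()
  streamId <- 1000L
  dntKeys <- names(assayMap)
  dntTab <- unique(wells[wells$role == "dnt", c("compound", "endpoint")])
  .stage("fit_bmc", quiet, {
    for (i in seq_len(nrow(dntTab))) {
      cmp <- dntTab$compound[i]; ep <- dntTab$endpoint[i]
      key <- paste(cmp, ep)
      assay <- assayMap[[key]]
      defs <- getBmrs(assay)
      direction <- dirMap[[key]] %||% "decrease_adverse"
      cw <- wells[wells$compound == cmp, , drop = FALSE]
      refsAvail <- unique(cw$endpoint[cw$role %in% c("viability", "cytotoxicity")])
      if (!is.null(config$pairing))
        refsAvail <- intersect(config$pairing$pairing[[ep]] %||% refsAvail,
                               refsAvail)
      ## DNT endpoint
      d <- cw[cw$endpoint == ep, , drop = FALSE]
      streamId <- streamId + 1L
      r <- tryCatch(
        fitOne(d, defs$endpoint, direction, fitBell = TRUE,
               sd = childSeed(seed, streamId)),
        error = function(e) stop(sprintf("%s/%s: %s", cmp, ep,
                                         conditionMessage(e)), call. = FALSE))
      estStore[[key]] <- list(dnt = r$est, refs = list())
      bmcRows[[length(bmcRows) + 1L]] <- data.frame(
        compound = cmp, endpoint = ep, role = "dnt", assay = assay,
        model = r$fit@model, bmr = defs$endpoint, direction = direction,
        bmc_uM = if (r$est@censored) NA_real_ else r$est@bmc,
        ci_lower = r$est@ciLower, ci_upper = r$est@ciUpper,
        censored = r$est@censored, ci_unreliable = r$est@unreliable,
        stringsAsFactors = FALSE)
      ## reference endpoints
      for (ref in refsAvail) {
        dref <- cw[cw$endpoint == ref, , drop = FALSE]
        streamId <- streamId + 1L
        rr <- tryCatch(
          fitOne(dref, defs$viability, "decrease_adverse", fitBell = FALSE,
                 sd = childSeed(seed, streamId)),
          error = function(e) stop(sprintf("%s/%s: %s", cmp, ref,
                                           conditionMessage(e)), call. = FALSE))
        estStore[[key]]$refs[[ref]] <- rr$est
        bmcRows[[length(bmcRows) + 1L]] <- data.frame(
          compound = cmp, endpoint = ref,
          role = cw$role[cw$endpoint == ref][1], assay = assay,
          model = rr$fit@model, bmr = defs$viability,
          direction = "decrease_adverse",
          bmc_uM = if (rr$est@censored) NA_real_ else rr$est@bmc,
          ci_lower = rr$est@ciLower, ci_upper = rr$est@ciUpper,
          censored = rr$est@censored, ci_unreliable = rr$est@unreliable,
          stringsAsFactors = FALSE)
      }
    }
    invisible(NULL)
  })
  bmcTable <- do.call(rbind, bmcRows)

  ## ---- classify ---------------------------------------------------------
  profiles <- .stage("classify", quiet, {
    byCompound <- split(seq_len(nrow(dntTab)), dntTab$compound)
    lapply(byCompound, function(idx) {
      cmp <- dntTab$compound[idx[1]]
      ests <- list(); calls <- list()
      for (i in idx) {
        ep <- dntTab$endpoint[i]
        key <- paste(cmp, ep)
        assay <- assayMap[[key]]
        st <- estStore[[key]]
        calls[[ep]] <- if (assay == "NPC") {
          if (length(st$refs) == 0)
            stop(sprintf("%s/%s has no reference endpoints", cmp, ep),
                 call. = FALSE)
          classifyNPC(st$dnt, st$refs, overlapThreshold,
                      compound = cmp, endpoint = ep)
        } else {
          viab <- st$refs[[which.min(vapply(st$refs, function(e)
            if (e@censored) Inf else e@bmc, numeric(1)))]]
          classifyUKN(assay, st$dnt, viab, cutoff = getBmrs(assay)$ratioCutoff,
                      checkBmr = FALSE, compound = cmp, endpoint = ep)
        }
        ests[[ep]] <- st$dnt
      }
      compoundProfile(cmp, ests, calls)
    })
  })

  hitTable <- do.call(rbind, lapply(profiles, function(p) {
    do.call(rbind, lapply(names(p@hitCalls), function(ep) {
      h <- p@hitCalls[[ep]]
      data.frame(compound = p@compound, endpoint = ep,
                 classification = h@classification, basis = h@basis,
                 overlap_fraction = h@overlapFraction,
                 ratio_value = h@ratioValue,
                 reference_endpoint = h@referenceEndpoint,
                 flagged = h@flagged, is_mse = identical(ep, p@mseEndpoint),
                 stringsAsFactors = FALSE)
    }))
  }))
  rownames(hitTable) <- NULL
  bmcTable$classification <- NA_character_
  bmcTable$is_mse <- FALSE
  for (i in seq_len(nrow(hitTable))) {
    j <- bmcTable$compound == hitTable$compound[i] &
      bmcTable$endpoint == hitTable$endpoint[i] & bmcTable$role == "dnt"
    bmcTable$classification[j] <- hitTable$classification[i]
    bmcTable$is_mse[j] <- hitTable$is_mse[i]
  }

  ## ---- prioritize -------------------------------------------------------
  ranking <- .stage("prioritize", quiet, {
    compounds <- sort(unique(dntTab$compound))
    endpoints <- sort(unique(dntTab$endpoint))
    bmcMat <- matrix(NA_real_, length(compounds), length(endpoints),
                     dimnames = list(compounds, endpoints))
    for (key in names(estStore)) {
      parts <- strsplit(key, " ", fixed = TRUE)[[1]]
      est <- estStore[[key]]$dnt
      if (!est@censored) bmcMat[parts[1], parts[2]] <- est@bmc
    }
    sl <- scaleBmcs(bmcMat, sentinel = sentinel)
    scores <- toxpiScores(sl$scaled)
    mse <- vapply(profiles, function(p) p@mseBmc, numeric(1))[compounds]
    names(mse) <- compounds
    tree <- clusterProfiles(sl$scaled)
    list(slices = sl, scores = scores, mse = mse,
         rank = mergedRank(mse, scores), tree = tree)
  })

  sliceScores <- do.call(rbind, lapply(colnames(ranking$slices$scaled),
    function(ep) data.frame(
      compound = rownames(ranking$slices$scaled), endpoint = ep,
      raw_transform = ranking$slices$raw[, ep],
      scaled = ranking$slices$scaled[, ep], stringsAsFactors = FALSE)))
  rownames(sliceScores) <- NULL
  toxpiTable <- data.frame(compound = names(ranking$scores),
                           toxpi_score = unname(ranking$scores),
                           stringsAsFactors = FALSE)

  ## ---- exposure ---------------------------------------------------------
  exposureTable <- data.frame()
  if (isTRUE(config$exposure)) {
    exposureTable <- .stage("exposure", quiet,
      exposureSummary(exposureRecords(), mse = ranking$mse))
  }

  new("ReportBundle",
      bmcTable = bmcTable, hitTable = hitTable, sliceScores = sliceScores,
      toxpiTable = toxpiTable, rankingTable = ranking$rank,
      flagsTable = flags, exposureTable = exposureTable, groundTruth = truth,
      metadata = list(seed = as.integer(seed), configHash = .configHash(config),
                      nBoot = nBoot, alpha = alpha,
                      overlapThreshold = overlapThreshold,
                      sentinel = sentinel,
                      version = as.character(utils::packageVersion("dntbattery")),
                      nWells = nrow(wells), nCompounds = nrow(ranking$rank)))
}

#' Write the report bundle to delimited-text files
#'
#' Writes every table of the bundle as a tab-delimited file plus a
#' human-readable summary, and returns a manifest listing each file with its
#' MD5 checksum.
#'
#' @param bundle a \linkS4class{ReportBundle}.
#' @param outDir output directory (created if missing).
#' @return data.frame manifest (file, md5), invisibly written as
#'   \code{manifest.tsv} alongside.
#' @export
writeReports <- function(bundle, outDir) {
  stopifnot(is(bundle, "ReportBundle"))
  if (!dir.exists(outDir))
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  if (file.access(outDir, mode = 2) != 0)
    stop("output directory is not writable: ", outDir, call. = FALSE)
  tables <- list(
    bmc_table.tsv = bundle@bmcTable,
    hit_table.tsv = bundle@hitTable,
    slice_scores.tsv = bundle@sliceScores,
    toxpi_scores.tsv = bundle@toxpiTable,
    ranking_table.tsv = bundle@rankingTable,
    flags_table.tsv = bundle@flagsTable,
    exposure_table.tsv = bundle@exposureTable,
    ground_truth.tsv = bundle@groundTruth)
  files <- character()
  for (nm in names(tables)) {
    path <- file.path(outDir, nm)
    utils::write.table(tables[[nm]], path, sep = "\t", row.names = FALSE,
                       quote = FALSE)
    files <- c(files, path)
  }
  summaryPath <- file.path(outDir, "summary.txt")
  con <- file(summaryPath, "w")
  writeLines(c(
    "dntbattery run summary",
    sprintf("package version: %s", bundle@metadata$version),
    sprintf("seed: %s", bundle@metadata$seed),
    sprintf("config hash: %s", bundle@metadata$configHash),
    sprintf("compounds ranked: %s", bundle@metadata$nCompounds),
    sprintf("wells processed: %s", bundle@metadata$nWells),
    "",
    "ranking (merged MSE + ToxPi):",
    utils::capture.output(print(bundle@rankingTable, row.names = FALSE))),
    con)
  close(con)
  files <- c(files, summaryPath)
  manifest <- data.frame(file = basename(files),
                         md5 = unname(tools::md5sum(files)),
                         stringsAsFactors = FALSE)
  utils::write.table(manifest, file.path(outDir, "manifest.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  manifest
}
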