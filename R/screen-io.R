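.REQUIRED_COLS <- c("compound", "endpoint", "concentration_uM", "replicate",
                    "value_pct_control", "role")

#' Read and validate an endpoint-pairing configuration
#'
#' The pairing configuration assigns each DNT endpoint its reference
#' viability/cytotoxicity endpoints (e.g. migration endpoints can be
#' configured LDH-only, since an inhibited migration area depresses the CTB
#' readout without a true viability loss), the assay family per endpoint, and
#' the adversity direction. Read from YAML with top-level keys
#' \code{pairing}, \code{assay}, \code{direction}, and optional scalar
#' settings (\code{alpha}, \code{overlapThreshold}).
#'
#' @param path path to a YAML file.
#' @return A validated list.
#' @export
readPairingConfig <- function(path) {
  stopIfNot(file.exists(path), sprintf("config file not found: %s", path))
  cfg <- yaml::read_yaml(path)
  validatePairing(cfg)
  cfg
}

#' @rdname readPairingConfig
#' @param cfg a pairing configuration list.
#' @export
validatePairing <- function(cfg) {
  stopIfNot(is.list(cfg$pairing) && length(cfg$pairing) > 0,
            "pairing config must contain a non-empty `pairing` map")
  for (ep in names(cfg$pairing)) {
    refs <- cfg$pairing[[ep]]
    if (!is.character(refs) || !length(refs))
      stop(sprintf("endpoint %s has no reference endpoints in the pairing map", ep),
           call. = FALSE)
  }
  if (!is.null(cfg$assay)) {
    bad <- setdiff(unlist(cfg$assay), .ASSAYS)
    if (length(bad))
      stop("unknown assay families in config: ", paste(bad, collapse = ", "),
           call. = FALSE)
  }
  invisible(TRUE)
}

#' Read a screen table
#'
#' Reads a delimited well-level screen table (one row per well) and validates
#' it against a pairing configuration: every DNT endpoint must have reference
#' endpoints assigned, and endpoints that appear in neither the pairing keys
#' nor the reference lists are rejected.
#'
#' @param path path to a tab- or comma-delimited file with columns
#'   \code{compound}, \code{endpoint}, \code{concentration_uM},
#'   \code{replicate}, \code{value_pct_control}, \code{role} and optionally
#'   \code{plate_id}.
#' @param pairing a pairing configuration list (see
#'   \code{\link{readPairingConfig}}).
#' @param sep field separator (default tab).
#' @return data.frame of validated well records.
#' @export
readScreenTable <- function(path, pairing, sep = "\t") {
  stopIfNot(file.exists(path), sprintf("screen table not found: %s", path))
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  validateWells(df, pairing)
}

#' @rdname readScreenTable
#' @param wells a data.frame of well records.
#' @export
validateWells <- function(wells, pairing = NULL) {
  missing <- setdiff(.REQUIRED_COLS, names(wells))
  if (length(missing))
    stop("screen table is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  if (!"plate_id" %in% names(wells)) wells$plate_id <- NA_character_
  stopIfNot(all(wells$concentration_uM >= 0), "concentrations must be >= 0")
  stopIfNot(all(wells$replicate >= 1), "replicate indices must be >= 1")
  bad <- setdiff(unique(wells$role), .ROLES)
  if (length(bad))
    stop("unknown well roles: ", paste(bad, collapse = ", "), call. = FALSE)
  if (!is.null(pairing)) {
    validatePairing(pairing)
    dntEps <- unique(wells$endpoint[wells$role == "dnt"])
    unpaired <- setdiff(dntEps, names(pairing$pairing))
    if (length(unpaired))
      stop("DNT endpoint(s) without pairing: ",
           paste(unpaired, collapse = ", "), call. = FALSE)
    known <- union(names(pairing$pairing), unlist(pairing$pairing))
    unknown <- setdiff(unique(wells$endpoint), known)
    if (length(unknown))
      stop("unknown endpoint(s) in screen table: ",
           paste(unknown, collapse = ", "), call. = FALSE)
  }
  wells
}

#' Write a screen table
#'
#' @param wells data.frame of well records.
#' @param path output path.
#' @param sep field separator.
#' @export
writeScreenTable <- function(wells, path, sep = "\t") {
  utils::write.table(wells, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Normalize raw well signals to percent of control
#'
#' Divides each well value by the mean of the matched solvent-control wells
#' (concentration 0) and multiplies by 100, so the control mean maps to 100
#' exactly. Controls are matched per compound x endpoint x plate; when plate
#' ids are absent the controls are pooled per compound x endpoint. The
#' operation is idempotent on data whose controls already average 100.
#'
#' @param wells data.frame of well records (column \code{value_pct_control}
#'   holds the signal to normalize, raw or already normalized).
#' @param minControls minimum number of solvent-control wells required per
#'   normalization group (default 2).
#' @return The wells data.frame with \code{value_pct_control} normalized.
#' @export
percentOfControl <- function(wells, minControls = 2L) {
  wells <- validateWells(wells)
  grp <- paste(wells$compound, wells$endpoint,
               ifelse(is.na(wells$plate_id), "", wells$plate_id), sep = "\r")
  for (g in unique(grp)) {
    idx <- grp == g
    ctrl <- wells$value_pct_control[idx & wells$concentration_uM == 0]
    if (length(ctrl) < minControls)
      stop(sprintf("fewer than %d solvent-control wells for group '%s'",
                   minControls, gsub("\r", "/", g)), call. = FALSE)
    m <- mean(ctrl)
    if (!is.finite(m) || m <= 0)
      stop(sprintf("non-positive control mean for group '%s'",
                   gsub("\r", "/", g)), call. = FALSE)
    wells$value_pct_control[idx] <- wells$value_pct_control[idx] / m * 100
  }
  wells
}

#' Aggregate replicate wells into a response series
#'
#' Per-concentration mean, SEM (sample SD / sqrt(n)) and n for each compound x
#' endpoint. Series with n < 3 anywhere are carried but marked
#' (\code{low_n = TRUE}), mirroring the reporting of n = 2 conditions as
#' mean +/- SD.
#'
#' @param wells data.frame of (normalized) well records.
#' @return data.frame with one row per compound x endpoint x concentration.
#' @export
aggregateSeries <- function(wells) {
  wells <- validateWells(wells)
  sp <- split(wells, paste(wells$compound, wells$endpoint, sep = "\r"))
  out <- lapply(sp, function(d) {
    byConc <- split(d$value_pct_control, d$concentration_uM)
    conc <- as.numeric(names(byConc))
    n <- vapply(byConc, length, integer(1))
    data.frame(
      compound = d$compound[1], endpoint = d$endpoint[1], role = d$role[1],
      concentration_uM = conc,
      mean_pct_control = vapply(byConc, mean, numeric(1)),
      sem = vapply(byConc, function(v)
        if (length(v) > 1) stats::sd(v) / sqrt(length(v)) else NA_real_,
        numeric(1)),
      n = n, low_n = any(n < 3L), stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  res <- res[order(res$compound, res$endpoint, res$concentration_uM), ]
  rownames(res) <- NULL
  res
}

#' Flag statistically significant concentrations
#'
#' One-way ANOVA across concentration groups per compound x endpoint, followed
#' by Bonferroni-corrected pairwise comparisons of each concentration against
#' the solvent control (pooled-variance t tests on the ANOVA residual
#' variance). The correction spans the concentration-vs-control comparisons
#' only, not all pairwise group contrasts. A concentration is flagged when its
#' adjusted p-value is less than or equal to \code{alpha} (boundary
#' inclusive).
#'
#' @param wells data.frame of replicate-level well records including solvent
#'   controls (concentration 0).
#' @param alpha significance level (default 0.05).
#' @return data.frame with one row per compound x endpoint x non-control
#'   concentration: mean difference to control, adjusted p-value and flag.
#' @export
flagSignificant <- function(wells, alpha = 0.05) {
  wells <- validateWells(wells)
  sp <- split(wells, paste(wells$compound, wells$endpoint, sep = "\r"))
  out <- lapply(sp, function(d) {
    groups <- split(d$value_pct_control, d$concentration_uM)
    if (length(groups) < 2L || sum(vapply(groups, length, integer(1)) >= 2L) < 2L)
      stop(sprintf("insufficient replication for %s/%s (need >= 2 groups with >= 2 wells)",
                   d$compound[1], d$endpoint[1]), call. = FALSE)
    if (!"0" %in% names(groups))
      stop(sprintf("no solvent-control wells for %s/%s", d$compound[1],
                   d$endpoint[1]), call. = FALSE)
    conc <- as.numeric(names(groups))
    ns <- vapply(groups, length, integer(1))
    means <- vapply(groups, mean, numeric(1))
    ## pooled within-group variance = ANOVA residual mean square
    dfRes <- sum(ns) - length(groups)
    ssRes <- sum(vapply(groups, function(v) sum((v - mean(v))^2), numeric(1)))
    s2 <- ssRes / dfRes
    ctrl <- which(conc == 0)
    treated <- which(conc != 0)
    k <- length(treated)
    pAdj <- vapply(treated, function(i) {
      if (s2 == 0) {
        ## degenerate constant data: identical means are not significant
        return(if (means[i] == means[ctrl]) 1 else 0)
      }
      tstat <- (means[i] - means[ctrl]) / sqrt(s2 * (1 / ns[i] + 1 / ns[ctrl]))
      min(1, 2 * stats::pt(abs(tstat), dfRes, lower.tail = FALSE) * k)
    }, numeric(1))
    data.frame(
      compound = d$compound[1], endpoint = d$endpoint[1],
      concentration_uM = conc[treated],
      mean_diff = means[treated] - means[ctrl],
      p_adjusted = pAdj, significant = pAdj <= alpha,
      stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  res <- res[order(res$compound, res$endpoint, res$concentration_uM), ]
  rownames(res) <- NULL
  res
}
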