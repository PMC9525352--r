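#' Scale a BMC matrix to ToxPi slice scores
#'
#' Each BMC is transformed with \code{-log10(BMC uM) + 6}; a censored BMC
#' (not reached within the tested range) is first replaced by the sentinel
#' concentration 1e6 uM, whose transform is exactly 0. The raw transforms are
#' then scaled into [0, 1] within each endpoint by dividing by the endpoint's
#' maximum across compounds (default) or by the global maximum, so that 1
#' represents the lowest BMC (most potent compound) of that endpoint.
#'
#' @param bmcMatrix numeric matrix, compounds x endpoints, BMC in uM with
#'   \code{NA} for censored entries. Dimnames are carried through.
#' @param sentinel sentinel concentration for censored entries (uM).
#' @param scaleBy \code{"endpoint"} (per-endpoint maximum) or \code{"global"}.
#' @return list with matrices \code{raw} and \code{scaled}.
#' @examples
#' m <- matrix(c(1, 10, NA, 0.1), 2, 2,
#'             dimnames = list(c("A", "B"), c("e1", "e2")))
#' scaleBmcs(m)$scaled
#' @export
scaleBmcs <- function(bmcMatrix, sentinel = 1e6,
                      scaleBy = c("endpoint", "global")) {
  scaleBy <- match.arg(scaleBy)
  stopifnot(is.matrix(bmcMatrix))
  if (any(bmcMatrix <= 0, na.rm = TRUE))
    stop("BMC values must be > 0 (use NA for censored entries)", call. = FALSE)
  filled <- bmcMatrix
  filled[is.na(filled)] <- sentinel
  raw <- -log10(filled) + 6
  raw[is.na(bmcMatrix)] <- 0   # sentinel entries contribute exactly 0
  raw <- pmax(raw, 0)          # BMCs above the sentinel would go negative
  if (scaleBy == "endpoint") {
    mx <- apply(raw, 2, max)
    scaled <- sweep(raw, 2, ifelse(mx > 0, mx, 1), "/")
  } else {
    mx <- max(raw)
    scaled <- if (mx > 0) raw / mx else raw
  }
  list(raw = raw, scaled = scaled)
}

#' Compound-level ToxPi scores
#'
#' Weighted mean of the scaled slice scores per compound; equal weights by
#' default (each DNT endpoint is one slice of the pie).
#'
#' @param scaled scaled slice-score matrix (compounds x endpoints, in [0, 1]).
#' @param weights optional named numeric vector of nonnegative endpoint
#'   weights; names must match the matrix columns.
#' @return Named numeric vector of scores per compound.
#' @export
toxpiScores <- function(scaled, weights = NULL) {
  stopifnot(is.matrix(scaled))
  if (is.null(weights)) {
    weights <- stats::setNames(rep(1, ncol(scaled)), colnames(scaled))
  } else {
    unknown <- setdiff(names(weights), colnames(scaled))
    if (length(unknown))
      stop("weights refer to unknown endpoint(s): ",
           paste(unknown, collapse = ", "), call. = FALSE)
    missing <- setdiff(colnames(scaled), names(weights))
    if (length(missing))
      stop("weights missing for endpoint(s): ",
           paste(missing, collapse = ", "), call. = FALSE)
    weights <- weights[colnames(scaled)]
  }
  stopIfNot(all(weights >= 0) && sum(weights) > 0,
            "weights must be nonnegative and not all zero")
  drop(scaled %*% (weights / sum(weights)))
}

#' Hierarchically cluster compound slice profiles
#'
#' Agglomerative clustering of the compounds' scaled slice-score vectors using
#' Euclidean distance and average linkage (both configurable). Leaves are
#' ordered deterministically: compounds are sorted by label before clustering,
#' so permuting the input row order does not change the tree.
#'
#' @param scaled scaled slice-score matrix (compounds x endpoints).
#' @param method linkage method for \code{\link[stats]{hclust}}.
#' @param distMethod distance for \code{\link[stats]{dist}}.
#' @return An \code{hclust} object (a single compound gives a one-leaf
#'   degenerate tree represented as a list with the compound label).
#' @export
clusterProfiles <- function(scaled, method = "average",
                            distMethod = "euclidean") {
  stopifnot(is.matrix(scaled))
  if (nrow(scaled) < 2)
    return(structure(list(labels = rownames(scaled), n = nrow(scaled)),
                     class = "trivialDendrogram"))
  ord <- order(rownames(scaled))
  stats::hclust(stats::dist(scaled[ord, , drop = FALSE], method = distMethod),
                method = method)
}

## 3-fold potency ranges [bmc/3, bmc*3] overlap iff the BMC ratio is <= 9.
.foldOverlap <- function(b1, b2, fold = 3) {
  max(b1, b2) / min(b1, b2) <= fold^2
}

## Transitive closure of pairwise 3-fold range overlap into tie groups,
## on BMCs sorted ascending.
.tieGroups <- function(bmcs, fold = 3) {
  n <- length(bmcs)
  if (n == 0) return(integer(0))
  adj <- outer(bmcs, bmcs, function(a, b)
    pmax(a, b) / pmin(a, b) <= fold^2)
  group <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) {
      linked <- which(adj[i, ])
      g <- min(group[linked], group[i])
      if (any(group[c(i, linked)] != g)) {
        group[c(i, linked)] <- g
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  match(group, unique(group))
}

#' Merged MSE + ToxPi prioritization ranking
#'
#' First priority is the most sensitive endpoint (MSE): compounds with
#' specific hits are sorted ascending by MSE BMC. Compounds whose 3-fold MSE
#' ranges \code{[BMC/3, BMC*3]} overlap are merged (transitively) into tie
#' groups, within which the descending ToxPi score decides; remaining ties
#' fall back to ascending MSE BMC and then the compound label. Compounds
#' without a specific hit rank last, ordered by descending ToxPi score.
#'
#' @param mse named numeric vector of MSE BMCs (uM) per compound; \code{NA}
#'   for compounds without a specific hit.
#' @param toxpi named numeric vector of ToxPi scores per compound.
#' @param fold fold factor of the tie ranges (default 3).
#' @return data.frame with columns \code{rank}, \code{compound},
#'   \code{mse_bmc_uM}, \code{toxpi_score}, \code{tie_group} (\code{NA} for
#'   compounds ranked by ToxPi fallback only).
#' @export
mergedRank <- function(mse, toxpi, fold = 3) {
  stopIfNot(!is.null(names(mse)) && !is.null(names(toxpi)),
            "`mse` and `toxpi` must be named vectors")
  compounds <- names(mse)
  stopIfNot(all(compounds %in% names(toxpi)),
            "every compound in `mse` needs a ToxPi score")
  toxpi <- toxpi[compounds]

  withMse <- compounds[!is.na(mse)]
  noMse <- compounds[is.na(mse)]
  out <- list()
  if (length(withMse)) {
    b <- mse[withMse]
    ordAsc <- order(b, withMse)
    withMse <- withMse[ordAsc]
    b <- b[ordAsc]
    grp <- .tieGroups(unname(b), fold)
    ## within a tie group: descending ToxPi, then ascending MSE, then label
    ordFinal <- order(grp, -toxpi[withMse], b, withMse)
    out$mse <- data.frame(
      compound = withMse[ordFinal],
      mse_bmc_uM = unname(b[ordFinal]),
      toxpi_score = unname(toxpi[withMse][ordFinal]),
      tie_group = grp[ordFinal], stringsAsFactors = FALSE)
  }
  if (length(noMse)) {
    ordT <- order(-toxpi[noMse], noMse)
    out$fallback <- data.frame(
      compound = noMse[ordT], mse_bmc_uM = NA_real_,
      toxpi_score = unname(toxpi[noMse][ordT]), tie_group = NA_integer_,
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  res <- cbind(rank = seq_len(nrow(res)), res)
  rownames(res) <- NULL
  res
}
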