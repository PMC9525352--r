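## Model functions on x = log10(concentration / uM).
## Sigmoid (variable slope 4PL): the sign of `h` carries the orientation
## (h < 0: response falls from `top` to `bottom` with concentration).
.sigmoidFun <- function(x, bottom, top, L, h) {
  bottom + (top - bottom) / (1 + 10^((L - x) * h))
}

## Bell: anchored double sigmoid. Baseline fixed at the control level (100),
## rising to `top` around 10^L1 and falling to `bottom` around 10^L2.
.bellFun <- function(x, bottom, top, L1, h1, L2, h2) {
  s1 <- 1 / (1 + 10^((L1 - x) * h1))
  s2 <- 1 / (1 + 10^((L2 - x) * h2))
  100 + (top - 100) * s1 + (bottom - top) * s2
}

.aicc <- function(rss, n, npar) {
  k <- npar + 1  # + residual variance
  if (n - k - 1 <= 0) return(Inf)
  n * log(max(rss, 1e-300) / n) + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

.nlsControl <- function(tight) {
  if (tight) minpack.lm::nls.lm.control(maxiter = 1024, ftol = 1e-15,
                                        ptol = 1e-15, gtol = 0)
  else minpack.lm::nls.lm.control(maxiter = 100, ftol = 1e-10, ptol = 1e-10)
}

## Levenberg-Marquardt least squares via nls.lm on an explicit residual
## function (robust on zero-residual, i.e. noise-free, data).
.lmFit <- function(residFun, startList, lower = NULL, upper = NULL, tight) {
  best <- NULL
  for (st in startList) {
    if (!is.null(lower)) st <- pmin(pmax(st, lower + 1e-9), upper - 1e-9)
    fit <- tryCatch(suppressWarnings(minpack.lm::nls.lm(
      par = st, fn = residFun, lower = lower, upper = upper,
      control = .nlsControl(tight))),
      error = function(e) NULL)
    if (is.null(fit) || any(!is.finite(unlist(fit$par)))) next
    rss <- fit$deviance
    if (is.null(best) || rss < best$rss - 1e-12)
      best <- list(par = unlist(fit$par), rss = rss)
    if (!is.null(best) && best$rss < 1e-18) break
  }
  best
}

## Least-squares sigmoid fit on (x, y); returns list(par, rss) or NULL.
.fitSigmoidXY <- function(x, y, starts = NULL, tight = TRUE) {
  means <- tapply(y, x, mean)
  xs <- as.numeric(names(means))
  top0 <- max(means); bot0 <- min(means)
  decreasing <- means[[1]] >= means[[length(means)]]
  startList <- list()
  if (!is.null(starts)) startList <- c(startList, list(starts))
  for (h0 in c(1.5, 0.5, 4)) {
    startList <- c(startList, list(c(
      bottom = unname(bot0), top = unname(top0),
      L = unname(stats::median(xs)), h = if (decreasing) -h0 else h0)))
  }
  ## also try the opposite orientation in case the trend test misleads
  startList <- c(startList, list(c(bottom = unname(bot0), top = unname(top0),
                                   L = unname(stats::median(xs)),
                                   h = if (decreasing) 1.5 else -1.5)))
  residFun <- function(p)
    .sigmoidFun(x, p[["bottom"]], p[["top"]], p[["L"]], p[["h"]]) - y
  .lmFit(residFun, startList, tight = tight)
}

.fitBellXY <- function(x, y, starts = NULL, tight = TRUE) {
  means <- tapply(y, x, mean)
  xs <- as.numeric(names(means))
  xpk <- xs[which.max(means)]
  top0 <- max(max(means), 105)
  bot0 <- min(means)
  lo <- c(bottom = -500, top = 100 + 1e-6, L1 = min(xs) - 4, h1 = 0.05,
          L2 = min(xs) - 4, h2 = 0.05)
  hi <- c(bottom = 500, top = 1000, L1 = max(xs) + 4, h1 = 20,
          L2 = max(xs) + 4, h2 = 20)
  startList <- list()
  if (!is.null(starts)) startList <- c(startList, list(starts))
  for (off in c(0.5, 1, 1.5)) {
    startList <- c(startList, list(c(
      bottom = unname(bot0), top = unname(top0),
      L1 = unname(xpk) - off, h1 = 1.5, L2 = unname(xpk) + off, h2 = 1.5)))
  }
  residFun <- function(p)
    .bellFun(x, p[["bottom"]], p[["top"]], p[["L1"]], p[["h1"]], p[["L2"]],
             p[["h2"]]) - y
  .lmFit(residFun, startList, lower = lo, upper = hi, tight = tight)
}

#' Fit a concentration-response model
#'
#' Least-squares fit of a variable-slope sigmoid (4PL) or a bell-shaped
#' (anchored double sigmoid) model to replicate-level percent-of-control
#' responses. Concentrations are fitted on the log10 scale; solvent-control
#' wells (concentration 0) are excluded from the fit and serve only for
#' normalization. Optimizer failure is reported as \code{converged = FALSE}
#' rather than an error; exactly constant responses are represented by a
#' degenerate converged fit with \code{top == bottom} (whose BMC is censored
#' downstream).
#'
#' @param data data.frame with columns \code{concentration_uM} and
#'   \code{value_pct_control} (replicate-level, percent of control).
#' @param model \code{"sigmoid"} or \code{"bell"}.
#' @param starts optional named numeric vector of starting values
#'   (\code{bottom, top, L, h} for sigmoid; \code{bottom, top, L1, h1, L2, h2}
#'   for bell); used to speed up bootstrap refits.
#' @param tight logical; use tight optimizer tolerances (exact-data parameter
#'   recovery) at some speed cost.
#' @return A \linkS4class{FitResult}.
#' @examples
#' sp <- curveSpec("sigmoid_decreasing", bottom = 0, top = 100, ec50 = 1, hill = 1)
#' d <- simulateEndpoint(sp, dilutionSeries(20, 3, 7), 5, seed = 1)
#' fitCurve(d, "sigmoid")
#' @export
fitCurve <- function(data, model = c("sigmoid", "bell"), starts = NULL,
                     tight = TRUE) {
  model <- match.arg(model)
  stopIfNot(all(c("concentration_uM", "value_pct_control") %in% names(data)),
            "`data` needs columns concentration_uM and value_pct_control")
  d <- data[data$concentration_uM > 0, , drop = FALSE]
  nConc <- length(unique(d$concentration_uM))
  minConc <- if (model == "sigmoid") 4L else 5L
  if (nConc < minConc)
    stop(sprintf("fit infeasible: %s model needs >= %d distinct non-control concentrations, got %d",
                 model, minConc, nConc), call. = FALSE)
  x <- log10(d$concentration_uM)
  y <- d$value_pct_control
  n <- length(y)

  res <- if (model == "sigmoid") .fitSigmoidXY(x, y, starts, tight)
         else .fitBellXY(x, y, starts, tight)

  if (is.null(res)) {
    ## constant-response fallback: degenerate but converged flat fit
    mu <- mean(y)
    rss <- sum((y - mu)^2)
    if (stats::sd(y) < 1e-8 || model == "sigmoid") {
      return(new("FitResult", model = "sigmoid", bottom = mu, top = mu,
                 log10Ec50 = stats::median(x), hill = -1,
                 rss = rss, nPoints = as.integer(n),
                 aicc = .aicc(rss, n, 4L), converged = stats::sd(y) < 1e-8))
    }
    return(new("FitResult", model = "bell", nPoints = as.integer(n),
               converged = FALSE))
  }
  p <- res$par
  if (model == "sigmoid") {
    ## orientation normalization: report top >= bottom
    bottom <- min(p[["bottom"]], p[["top"]])
    top <- max(p[["bottom"]], p[["top"]])
    h <- if (p[["top"]] >= p[["bottom"]]) p[["h"]] else -p[["h"]]
    new("FitResult", model = "sigmoid", bottom = bottom, top = top,
        log10Ec50 = p[["L"]], hill = h, rss = res$rss,
        nPoints = as.integer(n), aicc = .aicc(res$rss, n, 4L),
        converged = TRUE)
  } else {
    new("FitResult", model = "bell", bottom = p[["bottom"]], top = p[["top"]],
        log10Ec50 = p[["L1"]], hill = p[["h1"]],
        log10Ec50Secondary = p[["L2"]], hillSecondary = p[["h2"]],
        rss = res$rss, nPoints = as.integer(n),
        aicc = .aicc(res$rss, n, 6L), converged = TRUE)
  }
}

#' Select the best converged fit by AICc
#'
#' Returns the converged fit with the lowest small-sample corrected AIC; ties
#' (within \code{1e-9}) are broken toward the sigmoid, which has fewer
#' parameters.
#'
#' @param fits list of \linkS4class{FitResult}.
#' @return A \linkS4class{FitResult}.
#' @export
selectModel <- function(fits) {
  stopifnot(length(fits) >= 1, all(vapply(fits, is, logical(1), "FitResult")))
  conv <- Filter(function(f) isTRUE(f@converged), fits)
  if (!length(conv)) stop("no converged fit to select from", call. = FALSE)
  aiccs <- vapply(conv, function(f) f@aicc, numeric(1))
  best <- min(aiccs)
  cand <- conv[aiccs <= best + 1e-9]
  sig <- Filter(function(f) identical(f@model, "sigmoid"), cand)
  if (length(sig)) sig[[1]] else cand[[1]]
}

## Predicted response of a FitResult at concentrations `conc` (uM).
.fitValue <- function(fit, conc) {
  x <- log10(conc)
  if (identical(fit@model, "sigmoid"))
    .sigmoidFun(x, fit@bottom, fit@top, fit@log10Ec50, fit@hill)
  else
    .bellFun(x, fit@bottom, fit@top, fit@log10Ec50, fit@hill,
             fit@log10Ec50Secondary, fit@hillSecondary)
}

#' Benchmark concentration from a fitted curve
#'
#' The BMC is the lowest concentration at which the fitted curve deviates from
#' the control level (100%) by at least \code{bmr} percentage points in the
#' adverse direction. Solved in closed form for the sigmoid; for the bell
#' model each monotone limb is searched by root-bracketing. When the curve
#' does not cross the benchmark response within the tested range the estimate
#' is censored (a valid outcome, not an error).
#'
#' @param fit a converged \linkS4class{FitResult}.
#' @param bmr benchmark response, percent effect (0-100).
#' @param direction \code{"decrease_adverse"}, \code{"increase_adverse"} or
#'   \code{"both"}.
#' @param testedRange numeric length-2, lowest and highest tested
#'   concentration (uM); crossings above the highest tested concentration are
#'   censored.
#' @return A \linkS4class{BMCEstimate} (point estimate only, no CI).
#' @examples
#' sp <- curveSpec("sigmoid_decreasing", bottom = 0, top = 100, ec50 = 1, hill = 1)
#' d <- simulateEndpoint(sp, dilutionSeries(20, 3, 7), 5, seed = 1)
#' f <- fitCurve(d, "sigmoid")
#' bmcFromFit(f, bmr = 20, direction = "decrease_adverse", testedRange = c(0.027, 20))
#' @export
bmcFromFit <- function(fit, bmr, direction = "decrease_adverse",
                       testedRange) {
  stopifnot(is(fit, "FitResult"))
  stopIfNot(isTRUE(fit@converged), "BMC requires a converged fit")
  stopIfNot(isScalarNumber(bmr) && bmr > 0 && bmr < 100, "`bmr` must be in (0, 100)")
  stopIfNot(direction %in% .DIRECTIONS, "invalid `direction`")
  stopIfNot(length(testedRange) == 2 && all(testedRange > 0) &&
              testedRange[1] <= testedRange[2],
            "`testedRange` must be c(min, max) with 0 < min <= max")
  censored <- function() new("BMCEstimate", bmr = bmr, direction = direction,
                             bmc = NA_real_, censored = TRUE)
  est <- function(val) {
    if (is.na(val) || val > testedRange[2]) censored()
    else new("BMCEstimate", bmr = bmr, direction = direction, bmc = val,
             censored = FALSE)
  }

  if (identical(fit@model, "sigmoid")) {
    B <- fit@bottom; T <- fit@top; L <- fit@log10Ec50; h <- fit@hill
    if (!is.finite(h) || h == 0 || T - B < 1e-9) return(censored())
    increasing <- h > 0
    target <- if (increasing) 100 + bmr else 100 - bmr
    wanted <- switch(direction,
      decrease_adverse = !increasing,
      increase_adverse = increasing,
      both = TRUE)
    if (!wanted) return(censored())
    if (!(target > B && target < T)) return(censored())
    r <- (T - target) / (target - B)
    x <- L - log10(r) / h
    return(est(10^x))
  }
  ## bell: lowest adverse crossing on either limb
  val <- .lowestCrossingNumeric(function(cc) .fitValue(fit, cc), bmr, direction,
                                maxConc = testedRange[2],
                                minConc = testedRange[1] * 1e-6)
  est(val)
}

#' Bootstrap confidence interval for a BMC
#'
#' Nonparametric bootstrap over replicate wells: wells are resampled with
#' replacement within each concentration group, the curve is refitted (same
#' model, warm-started at the original parameters), and the BMC recomputed.
#' The CI is the 2.5/97.5 percentile of the bootstrap BMC distribution,
#' widened if necessary to contain the plug-in point estimate. Because the
#' concentration groups are small (3-5 wells), plain case resampling
#' underestimates the within-group variance by the factor (n-1)/n; by default
#' the resampled values are shift-and-rescaled around their group mean by
#' sqrt(n/(n-1)) to remove this bias (the standard stratified-bootstrap
#' correction; disable with \code{varianceCorrected = FALSE}). When more than
#' half of the bootstrap refits are censored or fail to converge the CI is
#' flagged unreliable. Deterministic for a fixed seed.
#'
#' @param data replicate-level data.frame (\code{concentration_uM},
#'   \code{value_pct_control}) used for the original fit.
#' @param fit the original converged \linkS4class{FitResult}.
#' @param bmr,direction,testedRange as in \code{\link{bmcFromFit}}.
#' @param nBoot number of bootstrap resamples (default 200).
#' @param seed integer RNG seed (mandatory).
#' @param varianceCorrected apply the small-stratum variance correction
#'   (default TRUE).
#' @return A \linkS4class{BMCEstimate} with \code{ciLower}/\code{ciUpper}.
#' @export
bmcCI <- function(data, fit, bmr, direction = "decrease_adverse", testedRange,
                  nBoot = 200L, seed, varianceCorrected = TRUE) {
  point <- bmcFromFit(fit, bmr, direction, testedRange)
  stopIfNot(!point@censored,
            "bmcCI requires a non-censored point estimate")
  d <- data[data$concentration_uM > 0, , drop = FALSE]
  groups <- split(seq_len(nrow(d)), d$concentration_uM)
  groupMean <- vapply(groups, function(g)
    mean(d$value_pct_control[g]), numeric(1))
  inflate <- vapply(groups, function(g)
    if (length(g) > 1 && varianceCorrected)
      sqrt(length(g) / (length(g) - 1)) else 1, numeric(1))
  starts <- if (identical(fit@model, "sigmoid"))
    c(bottom = fit@bottom, top = fit@top, L = fit@log10Ec50, h = fit@hill)
  else
    c(bottom = fit@bottom, top = fit@top, L1 = fit@log10Ec50, h1 = fit@hill,
      L2 = fit@log10Ec50Secondary, h2 = fit@hillSecondary)

  bmcs <- withSeed(seed, {
    vapply(seq_len(nBoot), function(b) {
      pieces <- lapply(seq_along(groups), function(gi) {
        g <- groups[[gi]]
        take <- g[sample.int(length(g), length(g), replace = TRUE)]
        v <- d$value_pct_control[take]
        data.frame(
          concentration_uM = d$concentration_uM[take],
          value_pct_control = groupMean[gi] + inflate[gi] * (v - groupMean[gi]))
      })
      db <- do.call(rbind, pieces)
      fb <- tryCatch(
        fitCurve(db, model = fit@model, starts = starts, tight = FALSE),
        error = function(e) NULL)
      if (is.null(fb) || !fb@converged) return(NA_real_)
      eb <- bmcFromFit(fb, bmr, direction, testedRange)
      if (eb@censored) NA_real_ else eb@bmc
    }, numeric(1))
  })

  ok <- bmcs[!is.na(bmcs)]
  unreliable <- length(ok) < nBoot / 2
  if (length(ok) == 0) {
    ci <- c(point@bmc, point@bmc)
  } else {
    ci <- unname(stats::quantile(ok, c(0.025, 0.975)))
  }
  ci[1] <- min(ci[1], point@bmc)
  ci[2] <- max(ci[2], point@bmc)
  new("BMCEstimate", bmr = bmr, direction = direction, bmc = point@bmc,
      ciLower = ci[1], ciUpper = ci[2], censored = FALSE,
      nBoot = as.integer(nBoot), seed = as.integer(seed),
      unreliable = unreliable)
}
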