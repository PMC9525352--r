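#' Construct a true concentration-response curve
#'
#' Constructors for the ground-truth curves used by the synthetic screen
#' generator. All responses are on the percent-of-control scale, where the
#' solvent control sits at 100.
#'
#' @param model one of \code{"sigmoid_decreasing"}, \code{"sigmoid_increasing"},
#'   \code{"bell"}, \code{"flat"}.
#' @param bottom,top asymptotes (percent of control; \code{bottom <= top}).
#' @param ec50 half-maximal concentration in uM (ascending-limb midpoint for
#'   the bell model).
#' @param hill Hill slope, > 0; orientation is carried by \code{model}.
#' @param ec50Secondary descending-limb midpoint in uM (bell only,
#'   \code{> ec50}).
#' @param noiseSd additive Gaussian well-to-well noise SD in percent-of-control
#'   units.
#' @param level flat-curve response level.
#' @return A \linkS4class{CurveSpec}.
#' @examples
#' curveSpec("sigmoid_decreasing", bottom = 0, top = 100, ec50 = 1, hill = 1)
#' flatCurve()
#' @export
curveSpec <- function(model, bottom = 0, top = 100, ec50 = 1, hill = 1,
                      ec50Secondary = NA_real_, noiseSd = 0) {
  new("CurveSpec", model = model, bottom = bottom, top = top, ec50 = ec50,
      hill = hill, ec50Secondary = ec50Secondary, noiseSd = noiseSd)
}

#' @rdname curveSpec
#' @export
flatCurve <- function(level = 100, noiseSd = 0) {
  new("CurveSpec", model = "flat", bottom = level, top = level, ec50 = 1,
      hill = 1, ec50Secondary = NA_real_, noiseSd = noiseSd)
}

#' Serial dilution series
#'
#' Geometric dilution series as used on the battery's plates (e.g. 1:3 with 7
#' concentrations). Concentrations are returned in descending order; the
#' solvent control (concentration 0) is not part of the series and is emitted
#' by the simulator as distinct well records.
#'
#' @param topConc highest tested concentration, uM (> 0).
#' @param factor dilution factor (> 1), e.g. 3 for a 1:3 series.
#' @param n number of concentrations (>= 1).
#' @return Numeric vector of length \code{n}, descending.
#' @examples
#' dilutionSeries(20, 3, 7)
#' @export
dilutionSeries <- function(topConc, factor, n) {
  stopIfNot(isScalarNumber(topConc) && topConc > 0, "`topConc` must be > 0")
  stopIfNot(isScalarNumber(factor) && factor > 1, "`factor` must be > 1")
  stopIfNot(isScalarNumber(n) && n >= 1 && n == round(n), "`n` must be a count >= 1")
  topConc / factor^(seq_len(n) - 1)
}

#' Evaluate a noiseless concentration-response curve
#'
#' Monotone curves follow the four-parameter logistic
#' \code{bottom + (top - bottom) / (1 + (c/ec50)^hill)} (decreasing) or its
#' mirror (increasing). The bell model is an anchored double sigmoid,
#' \code{100 + (top - 100) * S1(c) + (bottom - top) * S2(c)}, which starts at
#' the control level, rises to \code{top} around \code{ec50} and falls to
#' \code{bottom} around \code{ec50Secondary}. At concentration 0 every model
#' returns its control-level value.
#'
#' @param spec a \linkS4class{CurveSpec}.
#' @param conc numeric vector of concentrations, uM (0 allowed).
#' @return Numeric vector of percent-of-control responses.
#' @examples
#' sp <- curveSpec("sigmoid_decreasing", bottom = 0, top = 100, ec50 = 1, hill = 1)
#' curveValue(sp, c(0, 0.25, 1, 4))
#' @export
curveValue <- function(spec, conc) {
  stopifnot(is(spec, "CurveSpec"))
  stopIfNot(all(conc >= 0), "concentrations must be >= 0")
  m <- spec@model
  b <- spec@bottom; t <- spec@top; e <- spec@ec50; h <- spec@hill
  up <- function(c, e50) ifelse(c == 0, 0, 1 / (1 + (e50 / c)^h))
  switch(m,
    flat = rep(t, length(conc)),
    sigmoid_decreasing = b + (t - b) * (1 - up(conc, e)),
    sigmoid_increasing = b + (t - b) * up(conc, e),
    bell = 100 + (t - 100) * up(conc, e) + (b - t) * up(conc, spec@ec50Secondary),
    stop("unknown curve model: ", m)
  )
}

## Lowest concentration in (0, maxConc] at which `f` deviates from control
## (100) by >= bmr in the adverse direction. Root-bracketing on a dense log10
## grid refined by uniroot; used for bell-shaped (non-invertible) curves.
.lowestCrossingNumeric <- function(f, bmr, direction, maxConc,
                                   minConc = maxConc * 1e-9) {
  lowTarget <- 100 - bmr
  highTarget <- 100 + bmr
  adverse <- switch(direction,
    decrease_adverse = function(y) y <= lowTarget,
    increase_adverse = function(y) y >= highTarget,
    both = function(y) y <= lowTarget | y >= highTarget)
  xs <- seq(log10(minConc), log10(maxConc), length.out = 4096L)
  ys <- f(10^xs)
  hit <- which(adverse(ys))
  if (!length(hit)) return(NA_real_)
  i <- hit[1L]
  if (i == 1L) return(10^xs[1L])
  ## refine the bracket on the crossed threshold
  g <- function(x) {
    y <- f(10^x)
    if (direction == "decrease_adverse") y - lowTarget
    else if (direction == "increase_adverse") y - highTarget
    else if (ys[i] >= highTarget) y - highTarget else y - lowTarget
  }
  r <- tryCatch(
    stats::uniroot(g, lower = xs[i - 1L], upper = xs[i], tol = 1e-13),
    error = function(e) NULL)
  if (is.null(r)) 10^xs[i] else 10^r$root
}

#' Analytic benchmark concentration of a true curve
#'
#' The true BMC of a noiseless \linkS4class{CurveSpec}: the lowest
#' concentration at which the curve deviates from the control level (100%) by
#' at least \code{bmr} percentage points in the adverse direction. Solved in
#' closed form for monotone sigmoids and by monotone root-bracketing on each
#' limb for the bell model. Returns \code{NA} (censored) when the curve never
#' reaches the benchmark response within \code{(0, maxConc]}.
#'
#' @param spec a \linkS4class{CurveSpec}.
#' @param bmr benchmark response, percent effect (0-100).
#' @param direction \code{"decrease_adverse"}, \code{"increase_adverse"} or
#'   \code{"both"}.
#' @param maxConc highest tested concentration, uM; crossings above it are
#'   censored.
#' @return BMC in uM, or \code{NA_real_} when censored.
#' @examples
#' sp <- curveSpec("sigmoid_decreasing", bottom = 0, top = 100, ec50 = 1, hill = 1)
#' trueBmc(sp, bmr = 20, direction = "decrease_adverse", maxConc = 20) # 0.25
#' @export
trueBmc <- function(spec, bmr, direction = "decrease_adverse", maxConc = Inf) {
  stopifnot(is(spec, "CurveSpec"))
  stopIfNot(isScalarNumber(bmr) && bmr > 0 && bmr < 100, "`bmr` must be in (0, 100)")
  stopIfNot(direction %in% .DIRECTIONS, "invalid `direction`")
  b <- spec@bottom; t <- spec@top; e <- spec@ec50; h <- spec@hill
  lowTarget <- 100 - bmr
  highTarget <- 100 + bmr
  cens <- function(x) if (is.na(x) || x > maxConc) NA_real_ else x

  solveDec <- function(target) {
    ## bottom + (top-bottom)/(1 + (c/e)^h) = target, curve falls from top
    if (!(target > b && target < t)) return(NA_real_)
    e * ((t - target) / (target - b))^(1 / h)
  }
  solveInc <- function(target) {
    ## bottom + (top-bottom)/(1 + (e/c)^h) = target, curve rises from bottom
    if (!(target > b && target < t)) return(NA_real_)
    e * ((target - b) / (t - target))^(1 / h)
  }

  if (spec@model == "flat") return(NA_real_)
  if (spec@model == "sigmoid_decreasing") {
    x <- switch(direction,
      decrease_adverse = solveDec(lowTarget),
      increase_adverse = NA_real_,          # curve never rises above its start
      both = solveDec(lowTarget))
    return(cens(x))
  }
  if (spec@model == "sigmoid_increasing") {
    x <- switch(direction,
      decrease_adverse = NA_real_,
      increase_adverse = solveInc(highTarget),
      both = solveInc(highTarget))
    return(cens(x))
  }
  ## bell: first adverse crossing on either limb within the tested range
  mx <- if (is.finite(maxConc)) maxConc else spec@ec50Secondary * 1e4
  x <- .lowestCrossingNumeric(function(cc) curveValue(spec, cc), bmr, direction,
                              maxConc = mx, minConc = spec@ec50 * 1e-6)
  cens(x)
}
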