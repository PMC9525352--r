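refSigmoid <- curveSpec("sigmoid_decreasing", bottom = 0, top = 100,
                        ec50 = 1, hill = 1)
refConc <- dilutionSeries(20, 3, 7)

test_that("fitting recovers exact sigmoid parameters and flags flat data", {
  d <- simulateEndpoint(refSigmoid, refConc, 5, seed = 21)
  f <- fitCurve(d, "sigmoid")
  expect_true(f@converged)
  expect_lt(abs(10^f@log10Ec50 - 1), 1e-6)

  flat <- simulateEndpoint(flatCurve(), refConc, 5, seed = 22)
  ff <- fitCurve(flat, "sigmoid")
  expect_true(ff@converged)
  expect_lt(abs(ff@top - 100), 1e-6)
  expect_lt(abs(ff@bottom - 100), 1e-6)
  e <- bmcFromFit(ff, 20, "decrease_adverse", range(refConc))
  expect_true(isCensored(e))

  expect_error(fitCurve(simulateEndpoint(refSigmoid, c(1, 3, 9), 3, seed = 1),
                        "sigmoid"), "fit infeasible")
  expect_error(fitCurve(simulateEndpoint(refSigmoid, c(1, 2, 4, 8), 3, seed = 1),
                        "bell"), "fit infeasible")
})

test_that("the bell model wins AICc on a rise-then-fall response", {
  bell <- curveSpec("bell", bottom = 5, top = 150, ec50 = 0.08, hill = 2,
                    ec50Secondary = 5, noiseSd = 3)
  d <- simulateEndpoint(bell, refConc, 5, seed = 23)
  fb <- fitCurve(d, "bell")
  fs <- fitCurve(d, "sigmoid")
  expect_true(fb@converged)
  expect_lt(fb@aicc, fs@aicc)
  expect_identical(selectModel(list(fs, fb))@model, "bell")
})

test_that("model selection follows AICc with sigmoid tie-break", {
  mk <- function(model, aicc, conv = TRUE)
    new("FitResult", model = model, bottom = 0, top = 100, log10Ec50 = 0,
        hill = -1, log10Ec50Secondary = 1, hillSecondary = 1, rss = 1,
        nPoints = 20L, aicc = aicc, converged = conv)
  expect_identical(selectModel(list(mk("sigmoid", 20), mk("bell", 10)))@model,
                   "bell")
  expect_identical(selectModel(list(mk("sigmoid", 20), mk("bell", 20)))@model,
                   "sigmoid")
  expect_identical(selectModel(list(mk("sigmoid", 5),
                                    mk("bell", 2, conv = FALSE)))@model,
                   "sigmoid")
  expect_error(selectModel(list(mk("sigmoid", 5, conv = FALSE))),
               "no converged fit")
})

test_that("sigmoid BMC solves the benchmark response in closed form", {
  d <- simulateEndpoint(refSigmoid, refConc, 3, seed = 24)
  f <- fitCurve(d, "sigmoid")
  e20 <- bmcFromFit(f, 20, "decrease_adverse", range(refConc))
  expect_false(isCensored(e20))
  expect_lt(abs(bmc(e20) - 0.25), 1e-6)      # solve 100/(1+c) = 80
  e50 <- bmcFromFit(f, 50, "decrease_adverse", range(refConc))
  expect_lt(abs(bmc(e50) - 1), 1e-6)         # EC50 = BMC50 when bottom = 0
  ## wrong adverse direction on a monotone decreasing curve is censored
  expect_true(isCensored(bmcFromFit(f, 20, "increase_adverse",
                                    range(refConc))))
})

test_that("analytic BMC equals brute-force grid search to 0.1%", {
  set.seed(31)
  for (k in 1:8) {
    sp <- curveSpec("sigmoid_decreasing", bottom = runif(1, 0, 30),
                    top = 100, ec50 = runif(1, 0.2, 3),
                    hill = runif(1, 0.7, 3), noiseSd = 4)
    d <- simulateEndpoint(sp, refConc, 5, seed = 300 + k)
    f <- fitCurve(d, "sigmoid", tight = FALSE)
    e <- bmcFromFit(f, 20, "decrease_adverse", range(refConc))
    if (isCensored(e)) next
    oracle <- gridBmc(function(cc) {
      x <- log10(cc)
      f@bottom + (f@top - f@bottom) / (1 + 10^((f@log10Ec50 - x) * f@hill))
    }, 20, "decrease_adverse", maxConc = 20, minConc = 20 * 1e-7, nGrid = 1e6)
    expect_lt(abs(bmc(e) - oracle) / oracle, 1e-3)
  }
})

test_that("BMC is monotone in the benchmark response for monotone fits", {
  sp <- curveSpec("sigmoid_decreasing", 0, 100, 0.8, 1.6, noiseSd = 5)
  d <- simulateEndpoint(sp, refConc, 5, seed = 25)
  f <- fitCurve(d, "sigmoid", tight = FALSE)
  bmrs <- c(5, 10, 20, 30, 50, 70)
  vals <- vapply(bmrs, function(b) {
    e <- bmcFromFit(f, b, "decrease_adverse", c(min(refConc), 1e6))
    if (isCensored(e)) Inf else bmc(e)
  }, numeric(1))
  expect_true(all(diff(vals) >= -1e-12))
})

test_that("bootstrap CIs are deterministic, ordered, and collapse without noise", {
  spn <- curveSpec("sigmoid_decreasing", 0, 100, 1, 1, noiseSd = 5)
  d <- simulateEndpoint(spn, refConc, 5, seed = 26)
  f <- fitCurve(d, "sigmoid", tight = FALSE)
  e1 <- bmcCI(d, f, 20, "decrease_adverse", range(refConc), nBoot = 100,
              seed = 9)
  e2 <- bmcCI(d, f, 20, "decrease_adverse", range(refConc), nBoot = 100,
              seed = 9)
  expect_identical(c(ciLower(e1), ciUpper(e1)), c(ciLower(e2), ciUpper(e2)))
  expect_true(ciLower(e1) <= bmc(e1) && bmc(e1) <= ciUpper(e1))

  d0 <- simulateEndpoint(refSigmoid, refConc, 5, seed = 27)
  f0 <- fitCurve(d0, "sigmoid")
  e0 <- bmcCI(d0, f0, 20, "decrease_adverse", range(refConc), nBoot = 50,
              seed = 1)
  expect_equal(ciLower(e0), bmc(e0))
  expect_equal(ciUpper(e0), bmc(e0))

  flat <- simulateEndpoint(flatCurve(), refConc, 5, seed = 28)
  ffit <- fitCurve(flat, "sigmoid")
  expect_error(bmcCI(flat, ffit, 20, "decrease_adverse", range(refConc),
                     nBoot = 10, seed = 1), "non-censored")
})

test_that("BMC point estimation stays accurate under screen-level noise", {
  ## scaled-down version of the recovery experiment (full size runs in the
  ## acceptance suite)
  errs <- vapply(1:40, function(i) {
    set.seed(4000 + i)
    sp <- curveSpec("sigmoid_decreasing", 0, 100, runif(1, 0.3, 3),
                    runif(1, 1, 3), noiseSd = 5)
    tb <- trueBmc(sp, 20, "decrease_adverse", 20)
    d <- simulateEndpoint(sp, refConc, 5, seed = 5000 + i)
    f <- fitCurve(d, "sigmoid", tight = FALSE)
    e <- bmcFromFit(f, 20, "decrease_adverse", range(refConc))
    if (isCensored(e)) return(NA_real_)
    abs(log10(bmc(e) / tb))
  }, numeric(1))
  expect_lt(median(errs, na.rm = TRUE), 0.15)
})
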