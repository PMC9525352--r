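test_that("dilution series follows the plate design geometry", {
  s <- dilutionSeries(20, 3, 7)
  expect_length(s, 7)
  expect_equal(s, 20 / 3^(0:6))
  expect_equal(round(s, 2)[1:3], c(20, 6.67, 2.22))
  expect_equal(dilutionSeries(20, 2, 1), 20)
  expect_equal(dilutionSeries(10, 10, 3), c(10, 1, 0.1))
  expect_error(dilutionSeries(-1, 3, 7), "topConc")
  expect_error(dilutionSeries(20, 1, 7), "factor")
  expect_error(dilutionSeries(20, 3, 0), "count")
})

test_that("curve specs enforce their invariants", {
  expect_error(curveSpec("bell", ec50 = 1, ec50Secondary = 0.5),
               "ec50Secondary")
  expect_error(curveSpec("sigmoid_decreasing", bottom = 120, top = 100),
               "bottom")
  expect_error(curveSpec("sigmoid_decreasing", ec50 = -1), "ec50")
  expect_error(curveSpec("sigmoid_decreasing", noiseSd = -1), "noiseSd")
  expect_s4_class(curveSpec("bell", bottom = 10, top = 150, ec50 = 0.1,
                            hill = 2, ec50Secondary = 5), "CurveSpec")
})

test_that("noiseless curves evaluate to their algebraic values", {
  sp <- curveSpec("sigmoid_decreasing", bottom = 0, top = 100, ec50 = 1,
                  hill = 1)
  expect_equal(curveValue(sp, 1), 50)        # symmetric midpoint
  expect_equal(curveValue(sp, 0.25), 80)     # 100 / (1 + 0.25)
  expect_equal(curveValue(sp, 0), 100)
  spi <- curveSpec("sigmoid_increasing", bottom = 100, top = 150, ec50 = 2,
                   hill = 1)
  expect_equal(curveValue(spi, 2), 125)
  expect_equal(curveValue(spi, 0), 100)
  bell <- curveSpec("bell", bottom = 10, top = 150, ec50 = 0.05, hill = 2,
                    ec50Secondary = 5)
  expect_equal(curveValue(bell, 0), 100)
  ## peak between the limbs exceeds control, far tail falls to bottom
  expect_gt(curveValue(bell, 0.5), 140)
  expect_lt(curveValue(bell, 500), 12)
})

test_that("endpoint simulation is exact without noise and seed-deterministic", {
  sp <- curveSpec("sigmoid_decreasing", bottom = 0, top = 100, ec50 = 1,
                  hill = 1)
  conc <- dilutionSeries(20, 3, 7)
  d <- simulateEndpoint(sp, conc, 3, seed = 11)
  expect_equal(nrow(d), 8 * 3)   # 7 concentrations + solvent control
  treated <- d[d$concentration_uM > 0, ]
  expect_equal(treated$value_pct_control,
               curveValue(sp, treated$concentration_uM))
  ctrl <- d$value_pct_control[d$concentration_uM == 0]
  expect_equal(ctrl, rep(100, 3))

  spn <- curveSpec("sigmoid_decreasing", bottom = 0, top = 100, ec50 = 1,
                   hill = 1, noiseSd = 5)
  d1 <- simulateEndpoint(spn, conc, 5, seed = 42)
  d2 <- simulateEndpoint(spn, conc, 5, seed = 42)
  expect_identical(d1, d2)
  d3 <- simulateEndpoint(spn, conc, 5, seed = 43)
  expect_false(identical(d1$value_pct_control, d3$value_pct_control))
})

test_that("battery simulation is reproducible and rejects duplicates", {
  sc <- defaultBattery(noiseSd = 5)
  s1 <- simulateBattery(sc, seed = 7)
  s2 <- simulateBattery(sc, seed = 7)
  expect_identical(s1, s2)
  expect_setequal(unique(s1$wells$role), c("dnt", "viability", "cytotoxicity"))
  expect_equal(nrow(s1$truth), 12)
  expect_setequal(unique(s1$truth$intended_label),
                  c("specific", "borderline", "unspecific", "negative"))
  expect_error(simulateBattery(c(sc, sc[1]), seed = 1), "duplicate")
})

test_that("scenario constructor rejects labels inconsistent with the curves", {
  ## flat DNT curve cannot be a specific hit
  expect_error(
    screenScenario("X", "NPC5", "NPC", flatCurve(),
                   list(CTB = flatCurve()), intendedLabel = "specific"),
    "inconsistent")
  ## coincident viability cannot be specific either
  sig <- curveSpec("sigmoid_decreasing", 0, 100, 1, 2)
  expect_error(
    screenScenario("X", "NPC5", "NPC", sig, list(CTB = sig),
                   intendedLabel = "specific"),
    "inconsistent")
})

test_that("analytic true BMC matches dense-grid evaluation of the curve", {
  cases <- list(
    list(sp = curveSpec("sigmoid_decreasing", 0, 100, 1, 1), bmr = 20,
         dir = "decrease_adverse", expected = 0.25),
    list(sp = curveSpec("sigmoid_decreasing", 0, 100, 1, 1), bmr = 50,
         dir = "decrease_adverse", expected = 1),
    list(sp = curveSpec("sigmoid_decreasing", 10, 100, 0.4, 2.5), bmr = 25,
         dir = "decrease_adverse", expected = NULL),
    list(sp = curveSpec("sigmoid_increasing", 100, 180, 0.7, 1.3), bmr = 20,
         dir = "increase_adverse", expected = NULL),
    list(sp = curveSpec("bell", bottom = 10, top = 150, ec50 = 0.05, hill = 2,
                        ec50Secondary = 5), bmr = 20, dir = "both",
         expected = NULL)
  )
  for (cs in cases) {
    analytic <- trueBmc(cs$sp, cs$bmr, cs$dir, maxConc = 20)
    oracle <- gridBmc(function(cc) curveValue(cs$sp, cc), cs$bmr, cs$dir,
                      maxConc = 20, minConc = 1e-5, nGrid = 2e5,
                      refine = TRUE)
    expect_lt(abs(analytic - oracle), 1e-9)
    if (!is.null(cs$expected)) expect_equal(analytic, cs$expected)
  }
  ## censoring: crossing beyond the tested range
  far <- curveSpec("sigmoid_decreasing", 0, 100, 500, 2)
  expect_true(is.na(trueBmc(far, 20, "decrease_adverse", maxConc = 20)))
  expect_true(is.na(trueBmc(flatCurve(), 20, "decrease_adverse", 20)))
})

test_that("noiseless simulation followed by fitting recovers the parameters", {
  conc <- dilutionSeries(20, 3, 7)
  sp <- curveSpec("sigmoid_decreasing", bottom = 0, top = 100, ec50 = 1,
                  hill = 1.7)
  d <- simulateEndpoint(sp, conc, 3, seed = 5)
  f <- fitCurve(d, "sigmoid")
  expect_true(f@converged)
  expect_lt(abs(10^f@log10Ec50 - 1), 1e-6)
  expect_lt(abs(abs(f@hill) - 1.7) / 1.7, 1e-6)
  expect_lt(abs(f@top - 100) / 100, 1e-6)
  expect_lt(abs(f@bottom), 1e-4)

  bell <- curveSpec("bell", bottom = 10, top = 150, ec50 = 0.08, hill = 2,
                    ec50Secondary = 5)
  db <- simulateEndpoint(bell, conc, 3, seed = 6)
  fb <- fitCurve(db, "bell")
  expect_true(fb@converged)
  expect_lt(abs(10^fb@log10Ec50 - 0.08) / 0.08, 1e-6)
  expect_lt(abs(10^fb@log10Ec50Secondary - 5) / 5, 1e-6)
})
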