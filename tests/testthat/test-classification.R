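mkEst <- function(bmc, lo = NA_real_, hi = NA_real_, bmr = 20,
                  censored = FALSE) {
  if (censored)
    new("BMCEstimate", bmr = bmr, direction = "decrease_adverse",
        bmc = NA_real_, censored = TRUE)
  else
    new("BMCEstimate", bmr = bmr, direction = "decrease_adverse", bmc = bmc,
        ciLower = lo, ciUpper = hi, censored = FALSE)
}

test_that("CI overlap fraction equals direct interval arithmetic", {
  expect_equal(as.numeric(ciOverlapFraction(c(1, 2), c(3, 4))), 0)
  expect_equal(as.numeric(ciOverlapFraction(c(1, 2), c(1, 2))), 1)
  expect_equal(as.numeric(ciOverlapFraction(c(1, 2), c(1.95, 3))), 0.05)
  expect_equal(as.numeric(ciOverlapFraction(c(1, 2), c(1.5, 2.5))), 0.5)
  ## property: always in [0,1], equal to the oracle, monotone in intersection
  set.seed(8)
  for (i in 1:50) {
    a <- sort(runif(2, 0, 10)); b <- sort(runif(2, 0, 10))
    if (diff(a) == 0 || diff(b) == 0) next
    frac <- as.numeric(ciOverlapFraction(a, b))
    expect_gte(frac, 0); expect_lte(frac, 1)
    expect_equal(frac, min(1, directOverlap(a, b)))
  }
  expect_error(ciOverlapFraction(c(2, 1), c(1, 2)), "lower <= upper")
})

test_that("NPC classification follows the CI-overlap rule", {
  dnt <- mkEst(0.7, 0.5, 1.0)
  ## all references censored: no interval to overlap -> specific
  h1 <- classifyNPC(dnt, list(CTB = mkEst(NA, censored = TRUE)))
  expect_identical(classification(h1), "specific")
  ## borderline: overlap 0.05 of the DNT interval
  h2 <- classifyNPC(mkEst(1.5, 1, 2), list(LDH = mkEst(2.2, 1.95, 3)))
  expect_identical(classification(h2), "borderline")
  expect_equal(h2@overlapFraction, 0.05)
  ## unspecific: overlap 0.5
  h3 <- classifyNPC(mkEst(1.5, 1, 2), list(CTB = mkEst(2, 1.5, 2.5)))
  expect_identical(classification(h3), "unspecific")
  expect_equal(h3@overlapFraction, 0.5)
  ## censored DNT BMC is never a hit
  h4 <- classifyNPC(mkEst(NA, censored = TRUE), list(CTB = mkEst(1, 0.9, 1.1)))
  expect_identical(classification(h4), "no_hit")
  expect_error(classifyNPC(dnt, list()), "empty reference")
  ## threshold is a configuration value
  h5 <- classifyNPC(mkEst(1.5, 1, 2), list(LDH = mkEst(2.2, 1.95, 3)),
                    overlapThreshold = 0.04)
  expect_identical(classification(h5), "unspecific")
})

test_that("worst-case reference drives the NPC call, order-invariantly", {
  dnt <- mkEst(1.5, 1, 2)
  refs <- list(CTB = mkEst(5, 4, 6), LDH_72h = mkEst(2, 1.5, 2.5),
               LDH_120h = mkEst(2.2, 1.95, 3))
  hA <- classifyNPC(dnt, refs)
  hB <- classifyNPC(dnt, rev(refs))
  expect_identical(classification(hA), "unspecific")
  expect_identical(classification(hA), classification(hB))
  expect_equal(hA@overlapFraction, hB@overlapFraction)
  expect_identical(hA@referenceEndpoint, "LDH_72h")
})

test_that("degenerate zero-width CIs fall back to the BMC ratio window", {
  ## noise-free pipeline limit: every CI collapses to its point estimate
  h <- classifyNPC(mkEst(1, 1, 1), list(CTB = mkEst(2, 2, 2)))
  expect_identical(classification(h), "borderline")
  expect_identical(h@basis, "viability_ratio")
  expect_true(h@flagged)
  expect_identical(classification(classifyNPC(mkEst(1, 1, 1),
                                              list(CTB = mkEst(1, 1, 1)))),
                   "unspecific")
  expect_identical(classification(classifyNPC(mkEst(1, 1, 1),
                                              list(CTB = mkEst(50, 50, 50)))),
                   "specific")
})

test_that("UKN ratio rule uses inclusive assay cutoffs", {
  e5 <- mkEst(5, bmr = 25); v65 <- mkEst(6.5, bmr = 10)
  h <- classifyUKN("UKN2", e5, v65)
  expect_identical(classification(h), "specific")   # ratio exactly 1.3
  expect_equal(h@ratioValue, 1.3)
  h2 <- classifyUKN("UKN4", mkEst(5, bmr = 25), mkEst(10, bmr = 25))
  expect_identical(classification(h2), "unspecific")  # ratio 2 < 4
  h3 <- classifyUKN("UKN5", mkEst(2, bmr = 25),
                    mkEst(NA, bmr = 25, censored = TRUE))
  expect_identical(classification(h3), "specific")   # no viability loss
  expect_identical(h3@ratioValue, Inf)
  h4 <- classifyUKN("UKN5", mkEst(NA, bmr = 25, censored = TRUE),
                    mkEst(2, bmr = 25))
  expect_identical(classification(h4), "no_hit")
  expect_error(classifyUKN("UKN2", mkEst(5, bmr = 25), mkEst(6.5, bmr = 25)),
               "viability BMR")
  expect_error(classifyUKN("NPC1", e5, v65), "UKN")
})

test_that("the most sensitive endpoint is the lowest specific BMC", {
  ests <- list(NPC5 = mkEst(0.5, 0.4, 0.6), UKN2 = mkEst(2, 1.5, 2.5),
               NPC1b = mkEst(0.1, 0.05, 0.2))
  mkCall <- function(ep, cls) new("HitCall", compound = "C", endpoint = ep,
                                  classification = cls, basis = "ci_overlap",
                                  overlapFraction = 0)
  calls <- list(NPC5 = mkCall("NPC5", "specific"),
                UKN2 = mkCall("UKN2", "specific"),
                NPC1b = mkCall("NPC1b", "unspecific"))
  mse <- mostSensitiveEndpoint(calls, ests)
  expect_identical(mse$endpoint, "NPC5")   # unspecific 0.1 never wins
  expect_equal(mse$bmc, 0.5)

  noneSpec <- lapply(calls, function(h) {
    h@classification <- "unspecific"; h
  })
  expect_null(mostSensitiveEndpoint(noneSpec, ests))

  prof <- compoundProfile("C", ests, calls)
  expect_identical(mseEndpoint(prof), "NPC5")
  expect_equal(mseBmc(prof), 0.5)
  profNone <- compoundProfile("C", ests, noneSpec)
  expect_true(is.na(mseEndpoint(profNone)))
  ## ties break lexicographically
  ests2 <- list(B = mkEst(1, 0.9, 1.1), A = mkEst(1, 0.9, 1.1))
  calls2 <- list(B = mkCall("B", "specific"), A = mkCall("A", "specific"))
  expect_identical(mostSensitiveEndpoint(calls2, ests2)$endpoint, "A")
})
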