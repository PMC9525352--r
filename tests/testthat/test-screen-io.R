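makeWells <- function(values, conc = c(0, 0, 1, 1), compound = "C1",
                      endpoint = "NPC5", role = "dnt", plate = NA_character_) {
  data.frame(compound = compound, endpoint = endpoint,
             concentration_uM = conc,
             replicate = stats::ave(conc, conc, FUN = seq_along),
             value_pct_control = values, role = role, plate_id = plate,
             stringsAsFactors = FALSE)
}

test_that("screen tables round-trip and schema errors name the column", {
  wells <- simulateBattery(defaultBattery(noiseSd = 5)[1], seed = 3)$wells
  pairing <- list(pairing = list(NPC5 = c("CTB", "LDH_120h")),
                  assay = list(NPC5 = "NPC"))
  tf <- tempfile(fileext = ".tsv")
  writeScreenTable(wells, tf)
  back <- readScreenTable(tf, pairing)
  expect_equal(nrow(back), nrow(wells))
  expect_equal(back$value_pct_control, wells$value_pct_control)

  broken <- wells[, setdiff(names(wells), "concentration_uM")]
  tf2 <- tempfile(fileext = ".tsv")
  writeScreenTable(broken, tf2)
  expect_error(readScreenTable(tf2, pairing), "concentration_uM")
})

test_that("pairing validation rejects unknown and unpaired endpoints", {
  pairing <- list(pairing = list(NPC2a = c("LDH_72h", "LDH_120h")),
                  assay = list(NPC2a = "NPC"))
  expect_setequal(pairing$pairing$NPC2a, c("LDH_72h", "LDH_120h"))
  wells <- makeWells(c(100, 100, 60, 60), endpoint = "NPC2a")
  expect_silent(validateWells(rbind(wells), pairing))
  ## DNT endpoint absent from the pairing map
  orphan <- makeWells(c(100, 100, 60, 60), endpoint = "NPC9")
  expect_error(validateWells(orphan, pairing), "without pairing")
  ## endpoint unknown to both pairing keys and reference lists
  stray <- rbind(wells, makeWells(c(1, 1, 1, 1), endpoint = "CTB",
                                  role = "viability"))
  expect_error(validateWells(stray, pairing), "unknown endpoint")
  expect_error(validatePairing(list(pairing = list(NPC5 = character(0)))),
               "no reference endpoints")
})

test_that("percent-of-control normalization anchors controls at 100", {
  w <- makeWells(c(90, 110, 80, 80))
  n <- percentOfControl(w)
  expect_equal(n$value_pct_control, c(90, 110, 80, 80))  # control mean = 100
  w2 <- makeWells(c(45, 55, 40, 40))   # raw units, control mean 50
  n2 <- percentOfControl(w2)
  expect_equal(n2$value_pct_control[3:4], c(80, 80))
  expect_equal(mean(n2$value_pct_control[1:2]), 100)
  ## idempotence on already-normalized data
  expect_equal(percentOfControl(n2)$value_pct_control, n2$value_pct_control)
  ## treated value equal to the control mean maps to 100
  w3 <- makeWells(c(50, 50, 50, 50))
  expect_equal(percentOfControl(w3)$value_pct_control[3], 100)
  expect_error(percentOfControl(makeWells(c(0, 0, 10, 10))), "control mean")
  expect_error(percentOfControl(makeWells(c(100, 60, 60), conc = c(0, 1, 1))),
               "fewer than 2")
})

test_that("normalization groups controls per plate when plate ids exist", {
  a <- makeWells(c(200, 200, 100, 100), plate = "P1")
  b <- makeWells(c(50, 50, 50, 50), plate = "P2")
  n <- percentOfControl(rbind(a, b))
  expect_equal(n$value_pct_control, c(100, 100, 50, 50, 100, 100, 100, 100))
})

test_that("ANOVA flags respond to real shifts and ignore flat data", {
  conc <- c(rep(0, 5), rep(0.1, 5), rep(1, 5))
  flat <- makeWells(rep(100, 15), conc = conc)
  f0 <- flagSignificant(flat)
  expect_false(any(f0$significant))

  set.seed(91)
  shifted <- makeWells(c(rnorm(5, 100, 2), rnorm(5, 100, 2), rnorm(5, 80, 2)),
                       conc = conc)
  f1 <- flagSignificant(shifted)
  expect_true(f1$significant[f1$concentration_uM == 1])
  expect_false(f1$significant[f1$concentration_uM == 0.1])

  ## the boundary is inclusive: alpha equal to the adjusted p still flags
  pEdge <- f1$p_adjusted[f1$concentration_uM == 0.1]
  fEdge <- flagSignificant(shifted, alpha = pEdge)
  expect_true(fEdge$significant[fEdge$concentration_uM == 0.1])

  expect_error(flagSignificant(makeWells(c(100, 60), conc = c(0, 1))),
               "insufficient replication")
})

test_that("significance flags are invariant under affine raw-unit rescaling", {
  conc <- c(rep(0, 4), rep(0.5, 4), rep(5, 4))
  set.seed(17)
  raw <- c(rnorm(4, 1000, 40), rnorm(4, 950, 40), rnorm(4, 700, 40))
  w <- makeWells(raw, conc = conc)
  f1 <- flagSignificant(w)
  w2 <- w; w2$value_pct_control <- raw * 3.7 + 250
  f2 <- flagSignificant(w2)
  expect_equal(f1$p_adjusted, f2$p_adjusted)
  expect_identical(f1$significant, f2$significant)
})

test_that("replicate aggregation reports mean, SEM and low-n marking", {
  w <- makeWells(c(98, 102, 60, 70), conc = c(0, 0, 1, 1))
  s <- aggregateSeries(w)
  expect_equal(s$mean_pct_control[s$concentration_uM == 1], 65)
  expect_equal(s$sem[s$concentration_uM == 1],
               sd(c(60, 70)) / sqrt(2))
  expect_true(all(s$low_n))   # n = 2 everywhere
  expect_equal(s$n, c(2L, 2L))
})
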