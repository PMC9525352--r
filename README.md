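# dntbattery

Hazard characterization for a human cell–based developmental neurotoxicity
(DNT) in vitro testing battery.

DNT screening batteries measure neurodevelopmental key events — progenitor
proliferation, migration of neural crest cells, radial glia, neurons and
oligodendrocytes, neuronal/oligodendrocyte differentiation, neurite
morphology — with viability (CTB) and cytotoxicity (LDH) assays multiplexed
into every endpoint. Turning such screens into hazard statements requires a
chain of statistics that this package implements end to end, for
toxicologists and NAM (new approach methodologies) practitioners:

1. **Normalization & flagging** — percent-of-control normalization against
   solvent-control wells; one-way ANOVA with Bonferroni-corrected
   concentration-vs-control comparisons (*p* ≤ α flags).
2. **Concentration–response fitting** — variable-slope four-parameter
   logistic `f(c) = bottom + (top − bottom)/(1 + 10^((log10 EC50 − log10 c)·h))`
   and an anchored double-sigmoid bell for biphasic responses; AICc model
   selection.
3. **Benchmark concentrations** — BMC at an endpoint-specific benchmark
   response (BMR: the % deviation from control), censored when not reached
   in the tested range; percentile-bootstrap 95% CIs over replicate wells
   with a small-stratum variance correction.
4. **Specificity classification** — NPC endpoints by BMC-CI overlap with
   their viability/cytotoxicity references (specific / borderline at < 10% /
   unspecific at ≥ 10% overlap); UKN assays by the viability/endpoint BMC
   ratio (≥ 1.3 / ≥ 4 / ≥ 3 for UKN2/4/5); most sensitive endpoint (MSE) =
   lowest specific BMC.
5. **Prioritization** — ToxPi slice scores `−log10(BMC) + 6` (censored →
   sentinel 10⁶ µM → exactly 0), scaled per endpoint to [0, 1]; hierarchical
   profile clustering; merged ranking with MSE first and ToxPi deciding
   within transitive 3-fold BMC tie groups.
6. **Exposure margins** — biomonitoring records (ng/g lipid, ng/mL) to
   molarity via matrix fat contents (5.8 g/L serum, 33 g/L breast milk),
   daily intake at 1 L milk/day, and `log10(BMC_MSE / exposure)` margins.
7. **Synthetic screens** — a ground-truth-labelled generator that emulates
   the battery's plate designs (serial dilutions, replicate wells, solvent
   controls, paired viability shifts) so the whole chain is testable.

## Worked example

```r
library(dntbattery)

## one endpoint: simulate, fit, estimate a BMC with CI
sp  <- curveSpec("sigmoid_decreasing", bottom = 0, top = 100,
                 ec50 = 1, hill = 1.5, noiseSd = 5)
d   <- simulateEndpoint(sp, dilutionSeries(20, 3, 7), 5, seed = 101)
f   <- fitCurve(d, "sigmoid")
f
#> FitResult [sigmoid] converged=TRUE bottom=1.04 top=102 ec50=0.8915 uM hill=-1.42 AICc=112.26
bmcCI(d, f, bmr = 20, direction = "decrease_adverse",
      testedRange = c(0.027, 20), nBoot = 200, seed = 202)
#> BMC20 = 0.3566 uM (95% CI [0.3093, 0.4033], decrease_adverse)
```

The true curve crosses the 20% benchmark response at
`trueBmc(sp, 20, "decrease_adverse", 20)` = 0.397 µM; the estimate 0.357 µM
with CI [0.309, 0.403] recovers it within the interval.

```r
## the full pipeline on the reference 12-scenario battery
b <- runPipeline(list(scenarios = defaultBattery(noiseSd = 5),
                      nBoot = 200, quiet = TRUE), seed = 42)
head(b@rankingTable, 6)
#>   rank compound mse_bmc_uM toxpi_score tie_group
#> 1    1     FR12 0.03967327   0.1428571         1
#> 2    2     FR02 0.12213971   0.1428571         1
#> 3    3     FR03 0.24073699   0.1428571         1
#> 4    4     FR04 0.56698188   0.1428571         1
#> 5    5     FR01 0.04760220   0.1413299         1
#> 6    6     FR05 0.34426328   0.1247451         1
```

Compounds with specific hits rank first, ascending by their MSE BMC; because
these six BMCs fall in overlapping 3-fold ranges they form one tie group in
which the ToxPi score (and then the BMC) decides. Compounds without any
specific hit follow, ordered by ToxPi score. `writeReports(b, "out/")`
writes all tables as TSV with a checksum manifest.

```r
## exposure: biomonitoring to molarity, intake, margin
p <- conversionParams()
toMolar("TBOEP", 1.44, "ng_per_mL", "breast_milk", p)   # 0.0036 µM
dailyIntake(0.0554, p)                                  # 55.4 nmol/day (TCEP)
exposureMargin(0.02, 0.002)                             # 1.0 order of magnitude
```

## Scope

The package analyzes well-level screen tables; image quantification,
transcriptomics pipelines and kinetic (PBPK) modelling are out of scope. The
exposure comparison is deliberately crude — 100% bioavailability, no
metabolism, 1:1 blood–brain transfer — and is labelled as such in its
outputs. See the methods vignette (`vignettes/dntbattery-methods.Rmd`) for
the models, conventions and known limitations.
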