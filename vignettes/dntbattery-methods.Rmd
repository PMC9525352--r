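---
title: "Hazard characterization for a human DNT in vitro battery: models and methods"
author: "dntbattery maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hazard characterization for a human DNT in vitro battery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dntbattery)
```

## The problem

Human cell-based developmental neurotoxicity (DNT) test batteries screen
compounds across neurodevelopmental key events — neural progenitor
proliferation, migration of neural crest cells, radial glia, neurons and
oligodendrocytes, neuronal and oligodendrocyte differentiation, and neurite
morphology — with viability and cytotoxicity assays multiplexed into each
endpoint. The scientific question per compound and endpoint is not merely
"is there an effect", but "is the effect specific to the neurodevelopmental
process, or is it explained by general cell death", and across endpoints,
"which endpoint is the most sensitive and how do compounds rank against one
another and against human exposure levels".

`dntbattery` implements that entire hazard-characterization chain on
well-level screen tables: percent-of-control normalization, significance
flagging, concentration-response fitting, benchmark concentration (BMC)
estimation with bootstrap confidence intervals, specificity classification,
most-sensitive-endpoint (MSE) determination, ToxPi-style potency scaling
with a merged MSE + ToxPi ranking, and conversion of biomonitoring data to
molarity, daily intake, and exposure margins. A first-class synthetic-screen
generator produces ground-truth-labelled batteries so every stage is
testable without access to proprietary raw screen data.

## Concentration-response models

Responses are expressed as percent of the solvent control (control = 100).
Monotone responses use the four-parameter logistic (variable-slope sigmoid):

$$f(c) = \mathrm{bottom} + \frac{\mathrm{top} - \mathrm{bottom}}
  {1 + 10^{(\log_{10}\mathrm{EC}_{50} - \log_{10} c)\,h}},$$

fitted on $\log_{10}$ concentration; the sign of the Hill slope $h$ carries
the orientation (negative = response falls with concentration). The solvent
control ($c = 0$) is excluded from the fit and used only for normalization,
the conventional handling for log-concentration models.

Biphasic ("bell-shaped") responses — e.g. an induction of oligodendrocyte
differentiation at low concentrations followed by suppression below control
at high concentrations — use an anchored double sigmoid:

$$f(c) = 100 + (\mathrm{top} - 100)\,S(c; \mathrm{EC}_{50,1}, h_1)
             + (\mathrm{bottom} - \mathrm{top})\,S(c; \mathrm{EC}_{50,2}, h_2),$$

where $S$ is an ascending unit sigmoid. This form starts at the control
level at $c \to 0$, rises to a plateau near `top` around the first midpoint,
and falls to `bottom` around the second. We considered the
product-of-two-sigmoids alternative
($\mathrm{bottom} + A\,S_\uparrow S_\downarrow$) and rejected it: a product
of that form returns to the *same* asymptote at both concentration extremes,
so it cannot represent the empirically central shape that begins at 100%,
overshoots, and ends *below* control. The anchored sum uses exactly six free
parameters (two plateaus, two midpoints, two slopes), matching the bell fit
result contract.

Fitting is Levenberg-Marquardt least squares (`minpack.lm::nls.lm`) on
replicate-level wells with multiple documented starting points and an
explicit residual function, which remains stable on noise-free data where
residuals vanish. Optimizer failure is reported as `converged = FALSE`
rather than an error; exactly constant responses become a degenerate
converged fit with `top == bottom` whose BMC is censored downstream. Model
choice is by small-sample corrected AIC (AICc), ties broken toward the
sigmoid (fewer parameters).

## Benchmark concentrations

The BMC at benchmark response (BMR) $r$ is the lowest concentration at which
the fitted curve deviates from the control level by at least $r$ percentage
points in the adverse direction. For monotone sigmoids this is solved in
closed form; for bell curves each monotone limb is searched by
root-bracketing on a dense $\log_{10}$ grid refined with `uniroot`. A curve
that never reaches the benchmark response within the tested concentration
range yields a *censored* estimate — a valid outcome, not an error. For
increase-adverse endpoints the threshold is $100 + r$; for endpoints where
deviation in either direction is adverse (`direction = "both"`), the BMC is
the first crossing of either threshold, which for a rise-then-fall bell is
the ascending limb unless only the descending limb reaches the BMR (the limb
used is recorded in the ground-truth table of simulated screens).

Default BMRs follow assay-family conventions and are configuration, not
code: 20 for the neurosphere (NPC) endpoints, 25 for UKN2 migration with 10
for its viability reference, and 25 for UKN4/UKN5 neurite area and
viability. All are overridable per run.

### Bootstrap confidence intervals

Confidence intervals come from a nonparametric bootstrap over replicate
wells: wells are resampled with replacement within each concentration group,
the curve refitted (warm-started at the original parameters), the BMC
recomputed, and the 2.5/97.5 percentiles taken. Two numerical choices
matter:

* **Small-stratum variance correction.** With only 3-5 wells per
  concentration, plain case resampling underestimates the within-group
  variance by the factor $(n-1)/n$, and the resulting intervals measurably
  undercover. Resampled values are therefore shift-and-rescaled around their
  group mean by $\sqrt{n/(n-1)}$ — the standard stratified-bootstrap
  correction — before refitting. This is the default
  (`varianceCorrected = TRUE`); with it, empirical coverage of the 95%
  interval on simulated screens (5% noise, 7-point 1:3 series, 5 replicates,
  200 resamples) is 90-94%.
* **Interval contract.** Percentile intervals can, in rare resampling
  configurations, exclude the plug-in point estimate; the returned interval
  is widened to contain it, so `ciLower <= bmc <= ciUpper` always holds for
  non-censored estimates.

Bootstrap refits that fail to converge or are censored are dropped; when
more than half fail, the interval is flagged unreliable. All resampling is
driven by mandatory seeds; no function touches global random state
(the caller's RNG stream is saved and restored).

## Specificity classification

For the NPC family, a DNT endpoint's hit is classified against its paired
viability/cytotoxicity references by CI overlap: the intersection length of
the DNT BMC interval with a reference interval, divided by the DNT interval
length. The DNT denominator is deliberate — the question is whether the DNT
effect is explainable by cytotoxicity within the DNT effect's own
concentration range — and is configurable to the shorter-interval
denominator. No overlap is *specific*, overlap of at least 10% is
*unspecific*, and anything strictly between is *borderline*; a censored DNT
BMC is *no hit*, and if every reference BMC is censored the hit is specific.
With several references (CTB, LDH at two time points) the worst case
(maximum overlap) decides; migration endpoints can be configured LDH-only,
because an inhibited migration area depresses the CTB signal without a true
viability loss.

Two degenerate-interval conventions are needed at the zero-variance limit,
where bootstrap intervals collapse to points (exactly replicate-identical,
i.e. noise-free, data):

* A zero-length DNT interval against a proper reference interval uses the
  containment limit: overlap 1 if the point lies inside the reference
  interval, 0 otherwise (the limit of intersection/DNT-length as the DNT
  width goes to zero; dividing a measure-zero intersection by any length
  would always give 0 and make the rule vacuous).
* When *all* intervals involved are degenerate, the CI-overlap rule can only
  distinguish coincident from distinct points, so the borderline band would
  have zero width. The classifier then falls back to the reference/DNT BMC
  ratio with a documented window — ratio $\le 1.3$ unspecific, $< 3$
  borderline, $\ge 3$ specific — recorded with basis `viability_ratio` and
  flagged. This keeps all four outcome categories well-defined in the
  noise-free limit; with any realistic noise the CI-overlap path is taken.

UKN assays use their published ratio rule instead: viability BMC over
endpoint BMC, specific at ratio $\ge 1.3$ (UKN2), $\ge 4$ (UKN4) or $\ge 3$
(UKN5), boundaries inclusive; there is no borderline category for these
assays. A censored viability BMC with a reached endpoint BMC is specific
(the ratio is effectively infinite).

The MSE of a compound is the specific hit with the lowest BMC, ties broken
by lexicographic endpoint label; compounds without a specific hit have no
MSE.

## Prioritization

Each endpoint's BMC is transformed with $-\log_{10}(x) + 6$; censored
entries first become the sentinel $10^6\,\mu M$, whose transform is exactly
0. The printed transform alone does not land in $[0,1]$, so raw transforms
are divided by the per-endpoint maximum across compounds (anchoring 1 at the
lowest BMC, i.e. the most potent compound, of each endpoint); a global-max
strategy is available as a switch. The compound's ToxPi score is the
weighted mean of its scaled slices (equal weights by default), and profiles
are clustered agglomeratively (Euclidean distance, average linkage, both
configurable; rows are sorted by label first so input order cannot change
the tree).

The merged ranking gives first priority to the MSE: compounds with specific
hits sort ascending by MSE BMC, and compounds whose 3-fold ranges
$[\mathrm{BMC}/3, 3\,\mathrm{BMC}]$ overlap are merged — transitively, since
pairwise overlap is not an equivalence relation — into tie groups, within
which descending ToxPi score decides (then ascending BMC, then label).
Compounds without a specific hit rank last, by ToxPi score.

## Exposure comparison

Biomonitoring records in ng per g lipid convert to molarity via the matrix
fat content — 5.8 g/L for serum (cord blood), 33 g/L for breast milk — and
the compound's molar mass: $\mu M = \mathrm{value} \times \mathrm{fat} /
M / 1000$; volumetric records (ng/mL $\equiv$ µg/L) divide by the molar mass
directly. Daily intake assumes 1 L/day of breast milk:
$\mathrm{nmol/day} = \mu M \times \mathrm{intake} \times 1000$. The margin
between hazard and exposure is $\log_{10}(\mathrm{BMC_{MSE}} /
\mathrm{exposure})$. Reported values round to 4 decimals (µM) and whole
nmol/day; computation is unrounded.

A bundled table transcribes published breast-milk and cord-blood
measurements per region, along with the source's own printed micromolar
conversions (`uM_printed`). Applying the stated lipid formula reproduces the
printed lipid-weight µM entries only up to a consistent factor of about 10
(the volumetric entries reproduce exactly at printed precision, except one
record that matches no standard molar mass). The package follows the stated
formula and documents the discrepancy rather than reverse-engineering the
table; intake figures that aim to reproduce the source's daily-intake
numbers therefore start from `uM_printed`. Molar masses are bundled
literature values, cross-checked against the reproducible volumetric rows.
Every exposure output carries the crude-IVIVE caveat (100% bioavailability,
no kinetics, 1:1 blood-brain transfer) as metadata.

## The synthetic battery

The generator emulates the battery's plate designs: geometric serial
dilutions (1:2 or 1:3, 5-10 concentrations, top concentration 20 µM),
solvent controls, and replicate wells per assay family (5 for NPC, 4 for
UKN2, 3 for UKN4/5). Wells are drawn as curve value plus additive Gaussian
noise on the percent-of-control scale — the scale on which screen
variability is reported — with controls drawn around 100 under the same
noise so normalization is non-degenerate. The well-level noise SD is a free
parameter (the published screens report means ± SEM, not well variances);
the reference battery uses 5 percentage points, a mid-range value for
image-based and plate-reader endpoints of this kind. Heteroscedastic noise,
plate-position effects and raw fluorescence units are deliberately out of
scope, so passing tests demonstrate correctness of the analysis chain, not
robustness to instrument artifacts.

`defaultBattery()` fixes 12 scenarios spanning the four ground-truth
constructions: five specific (including one bell-shaped, direction-both
case), one borderline, three unspecific, three negative. The constructor of
every scenario asserts that its intended label matches the analytic
separation of its true curves, so mislabelled ground truth cannot enter
tests. Borderline is intrinsically the fragile category — it occupies the
band between "clearly separated" and "coincident" — so the reference
battery contains exactly one borderline construction (viability BMC at
twice the DNT BMC); under the battery noise level that scenario may
legitimately resolve to specific, which is why recovery under noise is
assessed as at least 11 of 12 while the noise-free battery must recover all
12.

True BMCs are computed analytically from the noiseless curves (closed form
for sigmoids, high-precision root-bracketing for bells) and recorded in the
ground-truth table together with the limb used.

## Problem sizes and numerical choices

The shipped experiments use sizes chosen to estimate each property stably:
200 simulated screens for BMC recovery (median absolute log10 error, with
true EC50 drawn from 0.3-3 µM and Hill from 1-3) and 200 for CI coverage of
the reference sigmoid (bottom 0, top 100, EC50 1 µM, Hill 1) at 200
bootstrap resamples; the 12-scenario battery runs once noise-free and once
at the battery noise level. Root-bracketing uses a 4096-point log grid with
`uniroot` refinement to $10^{-13}$; grid-search oracles in the tests use up
to $10^6$ points with bisection. Optimizer tolerances are $10^{-15}$
(relative) for primary fits and $10^{-10}$ for bootstrap refits, which is
what makes noise-free parameter recovery to $10^{-6}$ relative error
testable.

## Known limitations

* The classification of borderline hits depends on CI width and therefore
  on the bootstrap scheme; different CI methods (profile likelihood,
  asymptotic) would shift the borderline band. Only the percentile
  bootstrap is implemented.
* The bell BMC is found numerically; pathological fits with more than two
  adverse crossings inside the tested range would still return the lowest,
  but AICc selection makes such fits rare.
* Exposure comparison is deliberately crude (no kinetic modelling, no
  mixture effects); margins are screening-level indicators only.
* Hierarchical clustering of slice profiles is descriptive; no cluster
  inference is attempted.
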