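---
title: "Multi-proxy paleoecology from fossil tooth assemblages: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-proxy paleoecology from fossil tooth assemblages: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(paleomolar)
```

`paleomolar` reconstructs diet, climate and population structure for fossil
large-herbivore assemblages — built around the two rhinocerotid species of
the Early Miocene locality of Ulm-Westtangente (Germany) — from nothing but
tabular tooth records: locus, wear, measurements, pathology and enamel
carbonate isotope values. This vignette explains each method as implemented,
the tunable parameters and their defaults, the numerical choices made where
the literature leaves the design open, and what the packaged synthetic-data
generator can and cannot tell you about real assemblages.

## Tooth-wear ageing and mortality curves

Age estimation follows the wear-stage protocol calibrated on the extant
white rhinoceros: each cheek tooth locus carries an ordinal wear stage 1–10,
and a per-locus table maps every (locus, stage) pair to one or more of the
seventeen age classes 0–XVI that tile a conventional 40-year lifespan.

Two configuration artifacts drive this:

* **Age class table** (`default_age_classes()`). Published correlations
  anchor many bounds (class I begins at 1.5 months; II ends at 4 months;
  IV spans 1–1.5 y; V ends at 3 y at weaning; VI–VII span 3–4 y; VIII ends
  at 7 y; IX spans 7–9 y; X ends at 11 y; XVI ends at 40 y). Bounds the
  anchors do not fix are interpolated — I/II split at their midpoint,
  III spans 4 months–1 y, VI/VII split at 3.5 y, 11–20 y split at 15 y,
  and 20–40 y tiled in 5-y steps — and flagged `provenance =
  "interpolated"` so downstream users can see which bounds are convention
  rather than calibration.
* **Wear–age lookup** (`default_wear_age_lookup()`). The original
  locus-by-locus correspondence table is not reprinted in the accessible
  literature, so the shipped lookup is a deterministic reconstruction: each
  locus's active span (eruption class to last functional class) is
  partitioned in order across the ten wear stages. The eruption anchors are
  respected — m1/M1 erupt at class VI, the juvenile/subadult boundary;
  m3/M3 are functional from class VIII; milk teeth do not survive past
  class VII. This is a configuration file, not a biological claim; a
  laboratory with a locus-specific calibration should replace it via
  `read_wear_age_lookup()`.

Ageing then proceeds exactly as the field protocol prescribes: an isolated
tooth is one individual of total weight 1, spread equally over its
admissible classes (1 if one, 1/2 if two, and so on); associated teeth form
a single individual whose admissible set is the *intersection* of the
members' sets. An empty intersection is treated as an error, not silently
unioned: an association whose members cannot share an age is a data problem
the analyst must see. The raw mortality curve sums weights per class; the
corrected curve divides by class duration in years, which is what makes a
death count in a 2.5-month class comparable with one in a 5-year class.
Ontogenetic stages partition the classes (juveniles 0–V, subadults VI–VIII,
adults IX–XVI) and the age structure routes each individual's weight mass
through that partition.

Curve comparison (`compare_curves()`) is a two-sample Kolmogorov–Smirnov
test on the per-class corrected rates, each class contributing one value.
The published analysis reports such a test but not its exact input
convention, so the statistic here is a contract over `stats::ks.test`,
cross-checked in the test suite against a brute-force maximum-ECDF-gap
oracle, and no published D value is asserted.

## Minimum number of individuals

The simple MNI is the most abundant sided element (associated teeth counted
once; unsided teeth excluded from the sided maxima, though a non-empty
assemblage always implies at least one individual). Dental
eruption-incompatibility groups refine it: no individual holds a
functioning row with both milk teeth and third molars (group a), milk teeth
and fourth premolars (group b), or third milk molars and third premolars
(group d). For each group the best single sided-locus count within one side
of the incompatibility plus the best within the other is also a lower
bound; sides are chosen independently because the incompatibility is
ontogenetic, not bilateral. A group "c" sometimes mentioned in eruption
schemes is not defined in our source material and is not shipped; groups
are plain lists and fully configurable.

## Body mass

Eight published dental regressions are implemented exactly on their native
scales (`mass_equations()`): Janis' equations take length in cm and return
kg; Damuth's, Legendre's and Fortelius & Kappelman's take mm and return g.
All outputs are normalised to kg, the unit in which species means are
reported. Every equation is inverse-consistent to 1e-6 relative error over
10–5000 kg (property-tested), which the synthetic generator exploits to
manufacture tooth lengths from a target mass. Species summaries keep one
tooth per specimen per equation — left preferred, then right; an arbitrary
but deterministic tie-break — before averaging. Rhinoceros first lower
molars shorten with wear, so estimates from teeth at wear stage 8+ carry a
`worn_flag`; we flag rather than correct because no published correction
exists.

## The enamel-carbonate climate chain

The chain, per specimen:

1. **Enrichment.** The diet–bioapatite carbon enrichment scales with body
   mass: ε\* = exp(2.42 + 0.032 ln *m*) ‰ with *m* in kg. The mass unit
   matters (only kg reproduces published diet values) and is validated in
   tests. The mass fed to ε\* defaults to the species mean from the Damuth
   upper-M2 proxy, regarded as the most accurate dental proxy in extant
   rhinoceros; it is an explicit argument because the choice among the
   dental proxies shifts MAP by roughly 2% and diet by under 0.1 ‰.
2. **Diet.** δ13C_diet = δ13C_enamel − ε\* − corr, where corr is the
   difference between paleo-atmosphere and modern (−8 ‰) CO2 δ13C. It is
   computed from the two atmospheric values held by `site_config()` — for
   an Aquitanian site with a −6.1 ‰ paleo-atmosphere, corr = 1.9 ‰ — so
   other sites and ages work without code changes.
3. **Precipitation (MAP).** We invert Kohn's (2010) aridity relation for C3
   plant δ13C: MAP = 10^((−δ13C_diet − 10.29 − 0.0124·|lat| +
   1.9e-4·alt)/5.61) − 300 mm/yr. Printed versions of this inversion
   circulate with inconsistent interior signs; the form above is the
   algebraic inverse of the original relation and is the only sign
   convention that reproduces plausible Neogene values (tens to hundreds of
   mm/yr) rather than astronomically large ones. The inversion can return
   negative MAP when the diet signal is isotopically heavier than the local
   C3 baseline; negative values are *flagged and excluded from MAP means
   but never clamped*, since they are diagnostic of exactly that situation.
4. **Oxygen.** δ18O converts from VPDB to VSMOW (1.03091·δ + 30.91), then
   to precipitation δ18O with the modern-elephant calibration composed with
   the phosphate–carbonate relation. The rounded combined form (1.02·δ −
   33.3) is the default; the explicit two-step route (PO4 = 0.96·δ − 8.05;
   precip = (PO4 − 23.3)/0.94) is available and agrees with it within
   0.06 ‰ across the physiological enamel range 15–35 ‰ VSMOW — the
   combined coefficients are simply the rounding of the composition, and
   the agreement bound is asserted in the acceptance tests.
5. **Temperature.** MAT = (δ18O_precip + 14.178)/0.442 °C. The whole
   oxygen chain is affine, so MAT is linear in enamel δ18O (VPDB) with
   slope 1.03091 × 1.02 / 0.442 ≈ 2.379 °C per ‰ — asserted numerically as
   a regression guard.

**Outlier screening.** Enamel δ18O outliers (typically pre-weaning enamel,
whose milk signal is 18O-enriched and 13C-depleted) are flagged with Tukey
boxplot fences at 1.5 IQR beyond the hinges. Quartiles are Tukey's hinges
(`stats::fivenum`, the convention behind R's `boxplot.stats`), not
interpolated sample quantiles: the fence position is sensitive to the
quartile convention in samples this small (n = 8), and the hinge convention
is the one a boxplot-based screening decision actually uses. The
`quantile_type` argument exposes the interpolated alternatives for
sensitivity analysis. Screening refuses samples of fewer than four values.

**Aggregation policy** (`climate_summary()`): diet means are reported with
and without flagged outliers; the precipitation/MAT aggregate removes
outliers; the MAP aggregate is the mean of per-specimen MAPs — not the MAP
of the mean diet, a distinction that matters because the inversion is
convex — excluding flagged outliers and negative-MAP specimens, which are
counted separately.

## Dental-health proxies

* **Hypsodonty**: HI = unworn m3 crown height / width, classed brachyodont
  (< 1.5), mesodont (1.5–2.5), hypsodont (≥ 2.5). The thresholds are
  configurable; the defaults are consistent with published classifications
  of species means of 1.31 (brachyodont) and 1.55 (mesodont).
* **Mesowear** is ingested as data (the visual ruler scoring, 0 high-sharp
  to 6 low-blunt, is out of scope); the package enforces eligibility —
  upper molars only, average wear stages 4–7, undamaged — and one tooth per
  specimen with second molars preferred.
* **Hypoplasia**: a tooth is affected if it bears at least one defect.
  Very worn teeth (stages 9–10) and damaged teeth are excluded before
  prevalence is computed, to limit false negatives. Frequencies are exact
  count ratios, recomputable from the table.
* **DMTA** texture variables (NewepLsar, Asfc, HAsfc9/81) are ingested and
  summarised per species and facet; computing them from 3D surface scans is
  explicitly out of scope. Group comparisons delegate to standard rank
  tests (`rank_compare()` over `stats::kruskal.test`, tie-corrected,
  degenerate all-tied input returning H = 0, p = 1).

## The synthetic-assemblage generator

`simulate_assemblage()` provides ground-truth data so every stage of the
pipeline is testable without any external download. Its defaults *are* the
study conditions the package was built around: two species in a 337:155
tooth ratio with Damuth-M2 masses 532.53 and 1811.66 kg; a mortality
mixture with peaks at classes I–II (post-natal), IV (juvenile disease),
VI–VII (weaning) and IX (sexual maturity) plus an adult background, giving
10/20/70 juvenile/subadult/adult percentages in expectation; per-locus
hypoplasia probabilities equal to the observed merged prevalences; species
isotope means and dispersions matching the published enamel values; 5%
multiplicative (lognormal) measurement noise; a mean of 3 preserved teeth
per individual with 25% of individuals kept as associated sets. A packaged
preset (`ulm_params()`) sizes the sample at 164 individuals, about 490
teeth.

Internal consistency is by construction: a tooth's wear stage is sampled
uniformly among the stages whose lookup class set contains the individual's
death class, so associated teeth always intersect to a non-empty class set
and the ageing pipeline recovers the simulated structure (within 5
percentage points at n = 300, verified under a fixed seed).
`simulate_isotope_samples()` inverts the full climate chain from a target
(MAT, MAP) and adds 0.3 ‰ Gaussian analytical noise — the typical
within-run precision of carbonate analyses — so the forward chain's
parameter recovery (MAT within 1 °C, MAP within 15% at n = 20) is testable
end to end.

What the generator does *not* emulate: taphonomic transport, fragmentation
and preservation bias; spatial structure; covariance between wear and
measurement error (worn teeth measuring short); seasonal or serial
isotopic variation within a tooth; inter-observer scoring error. Passing
recovery tests therefore demonstrates the *pipeline's* correctness on data
that satisfy its assumptions, not robustness of the methods to real
taphonomy.

## Numerical choices and degenerate inputs

* Weights and percentages are conserved exactly (sums asserted to 1e-9);
  percentages always sum to 100.
* Empty inputs: MNI of an empty assemblage is 0; curves and structures from
  empty assignments are errors, not silent zeros; empty score groups are
  absent from summaries rather than reported as NaN.
* Tie-breaks are deterministic everywhere (left-then-right specimen
  deduplication; M2-then-M1-then-M3 mesowear preference).
* The wear–age lookup builder uses `round()` (banker's rounding) when
  partitioning class spans; the result is frozen as a shipped CSV and the
  test suite asserts CSV/builder identity, so the convention cannot drift.
* All simulations are seeded and seeds are mandatory; identical seeds give
  byte-identical assemblages and reports.

Problem sizes used by the test and acceptance suites — 1000 small
assemblages for the weight-conservation property, 300 individuals for
structure recovery, 30 teeth for mass recovery, 20 samples for climate
recovery, 1000 replicates for the rank test's type-I rate — were chosen as
the smallest sizes at which the corresponding statistical statements are
stable, and are stated here as the package's own reproducibility contract.

## Known limitations

The wear–age lookup is a constrained reconstruction, not the original
calibration table; absolute ages (not stage shares) inherit that
uncertainty. The 40-year lifespan and all class bounds are transferred from
an extant species, which is why percent-of-lifespan output
(`lifespan_fraction()`) is offered alongside years. MAP from a single taxon
is known to be noisy — robust estimates average over multiple taxa — and
the MAT relation carries the usual caveats of transferring a modern
meteoric-water calibration into deep time. The KS and Kruskal–Wallis
contracts use asymptotic or small-sample approximations as provided by
base R; exact permutation inference is out of scope.
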