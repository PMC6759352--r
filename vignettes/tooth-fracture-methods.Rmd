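---
title: "Dental fracture frequency and carcass utilization: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dental fracture frequency and carcass utilization: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The scientific problem

Large carnivores consume more of each kill — including bone — when prey are
hard to acquire, and bone consumption raises tooth wear and the probability
of tooth fracture. Fracture frequency in skull collections can therefore
serve as an index of prey availability and energetic stress, in extant
populations as well as in the fossil record. `wolftooth` implements the
cross-sectional analysis chain behind that inference for gray wolf
(*Canis lupus*) samples: per-individual and per-tooth fracture frequencies,
tooth-class and age-class breakdowns, wear-stage distributions,
contingency-table comparisons between samples, and a skeletal utilization
index computed from kill-site necropsies.

Because the underlying museum and field data sets are not bundled, the
package ships a synthetic-data subsystem with two distinct generators,
described below. Everything downstream of data entry is deterministic.

## Data model

A skull sample is a flat table, one row per tooth per skull
(`dental_records`). Tooth positions use the canonical 42-position wolf
dentition (I3/3 C1/1 P4/4 M2/3 per side) with codes `{U|L}_{L|R}_{I|C|P|M}{n}`
and five functional classes: incisors, canines, premolars, carnassials
(upper P4, lower m1) and post-carnassial molars. Three tooth statuses are
admitted: `intact`, `broken` and `missing`. `broken` means broken **in
life** — fracture evidence plus subsequent wear on the break surface.
Missing teeth never count as broken and are excluded from both numerator
and denominator of every frequency; teeth damaged post mortem must be
encoded as `missing` by the data preparer. This keeps the status vocabulary
minimal while matching the in-life counting rule, and it makes every
reported fracture frequency a conservative estimate.

Whole-dentition wear is an ordinal three-stage score (`slight`, `moderate`,
`heavy`). Ages at death, when known, are floored to whole years and binned
into the three adult classes 1–3, 4–6 and 7+ used for age-controlled
comparisons; ages below one year are flagged with a warning and treated as
unknown, since the analysis concerns adults but field files may contain
pups. Fractional ages are floored rather than rounded — the conservative
reading of whole-year age classes.

Kill-site necropsies are one row per carcass with found-counts per skeletal
element. The utilization index is one minus the ratio of indexed elements
found to the number expected from complete skeletons, pooled over
carcasses. The default index set is the eight paired mandible and limb
elements (16 units per carcass); skull and pelvis are always excluded (they
are nearly always present at kill sites), and vertebrae are recorded but
left out of the default index because the index is defined over mandibles
and limb bones. Elements recorded as presence/absence in the field
(metacarpus, metatarsus) map presence to the full paired count of 2. The
index set is an explicit argument everywhere, so alternative definitions
are one keyword away.

## Descriptive statistics and rounding

Two headline frequencies are computed per sample, each with and without
canine teeth: the percentage of individuals with at least one broken tooth,
and the percentage of all observed teeth broken. Canine teeth break in
combat and prey capture as well as in feeding, so the canine-excluded
variant isolates the bone-processing signal.

All printed percentages use **half-up** decimal rounding (`round_half_up`),
not base R's round-to-even: sample-summary columns at 1 decimal, in-text
style fractions at 0 decimals. Published tables print some values at one
decimal (71.9) and some at zero (33, 64); the package treats the printed
string as carrying its own precision, which matters when inverting
percentages back into counts (below). A printed value such as 64 from a
denominator of 83 is only consistent with 0-decimal rounding (53/83 =
63.855), which fixes the convention.

Wear-stage percentages are computed over skulls with a recorded stage only,
since historic specimens may lack one. Cross-sample means of percentages
are unweighted: each sample counts once regardless of size.

## Inference

Sample contrasts use the Pearson chi-square test of independence on count
tables, two-sided, **without** Yates continuity correction, with
`df = (r-1)(c-1)`. The uncorrected convention is the one that reproduces
the published sample contrasts at printed precision; the corrected version
gives larger p-values on the key 2×2 comparison. The two-period carcass
comparison uses the pooled two-proportion z-test on missing/expected
element counts (the statistical unit is the indexed skeletal element);
`z²` equals the uncorrected 2×2 chi-square, an identity the test suite
checks on random tables. p-values are reported at three decimals with
values below 0.001 printed as `<0.001`. No multiple-testing adjustment is
applied, matching the source analysis style; users running many contrasts
(`pairs = "all"`) should adjust downstream.

Linear regression of breakage against age is deliberately absent: the
underlying data are non-normal and heteroscedastic, so the package follows
the age-class stratification route instead, and the yearly utilization
series is summarized with a centered 3-year simple moving average rather
than a fitted trend. At the series edges the window truncates to the
available years, so output length equals input length and every smoothed
value stays within its window's min/max. Centered (rather than trailing)
placement is the common convention for visual trend lines; the window is
an argument and must be odd so the window has a center.

## Synthetic data

**Marginal-constrained fixtures** (`marginal_spec`, `generate_fixture`)
invert printed aggregates into exact integer data sets.
`solve_count_from_percent` finds, by exhaustive search, the smallest count
`k` whose half-up rounding of `100k/n` at the printed precision equals the
printed percent, and flags non-uniqueness (e.g. 8.6% of 1866 admits both
160 and 161; fixtures use the smallest, and the reproduced percentage is
invariant across the ambiguity set by construction). Observed teeth are
spread as evenly as possible across skulls, and broken teeth are placed
deterministically — one per broken skull, then round-robin in canonical
tooth order — so identical specs yield byte-identical files. Determinism
is preferred over realism here: the fixtures exist to round-trip printed
marginals, not to emulate per-skull variability, which is not published
(sample tables imply roughly 29–39 observed teeth per skull on average but
no distribution). Optional per-skull ages and wear-stage counts are honored
exactly, which is how the age-stratified and wear-stage worked fractions
are reproduced.

**The hazard simulator** (`hazard_spec`, `simulate_population`) generates
cross-sectional samples under a constant annual per-tooth fracture hazard:
a tooth of class `c` in a wolf aged `a` years is broken with probability
`1 − (1 − h_c)^⌊a⌋`, independently across teeth, and the wear score is
`wear_rate · a + ε`, `ε ~ N(0, wear_sd²)`, thresholded into the three
stages. The age distribution is always explicit in the spec — there is no
default demography, because age structures differ sharply between real
samples. Tooth-level independence is a simplification: broken teeth may
well beget further breakage via malocclusion, but that dependence is
speculative and independence keeps the recovery problem well-posed; it is
an extension point. `estimate_tooth_hazard` recovers `h` by maximizing the
binomial log-likelihood with one-dimensional search on (0, 1)
(`stats::optimise`, tolerance 1e-10); the all-intact and all-broken
boundary cases return 0 and 1 exactly, and teeth from skulls younger than
one year are uninformative under the floor and are excluded. The test
suite verifies the optimum against a dense grid and checks mean recovery
error ≤ 0.01 at 1000 skulls over 20 replicates for hazards 0.01–0.05.

`simulate_necropsies` removes each indexed element unit with a specified
probability (whole-element removal for the presence/absence elements, so
their expected removal proportion equals the same `p`).

## What the tests do and do not show

The fixture round-trips demonstrate that the measurement chain —
validation, counting rules, denominators, rounding — reproduces every
published headline frequency exactly from printed marginals alone. They do
not validate the fixtures as realistic populations. The kill-site raw data
are likewise not redistributable, so the published utilization figures
(overall removal, yearly range, decade split) are covered by
simulation-recovery properties at matched sizes — 100 carcasses/year over
20 years, removal probabilities 0.15/0.20 across the decade split — rather
than by desk reproduction; the worked 80%-present → 20% index example is
reproduced exactly. Simulation sizes in the suite (up to 2000 skulls,
10,000 null-table replicates for the type-I-error check) were chosen so
that every stochastic assertion sits several standard errors inside its
tolerance while the whole suite runs in well under a minute.

## Known limitations

* The canine-excluded summary column cannot be reproduced exactly from
  published marginals because per-sample observed-canine counts are
  unpublished; it is reported but not asserted.
* Regional composition of the historic North American sample is available
  only as totals; per-region frequencies are out of scope.
* No severity grading of fractures, no inter-observer reliability
  modelling, no scavenger attribution at kill sites, and no Fisher exact
  or regression-based inference — the pipeline mirrors the chi-square /
  stratification design it implements.
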