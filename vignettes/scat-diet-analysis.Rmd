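---
title: "Scat-based diet composition and prey selection: models and conventions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scat-based diet composition and prey selection: models and conventions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scatdiet)
```

## The problem

Scat analysis identifies prey remains (hair, bone, feathers) in
carnivore feces. Three statistics with very different meanings are in
common use, and `scatdiet` computes all three so results remain
comparable across studies:

* **Frequency of occurrence (Occ)** — the percentage of scats
  containing a prey item. Robust but coarse; sums can exceed 100%
  because scats may contain up to three items.
* **Percent volume (Vol)** — each scat contributes a composition
  (fractions summing to 1), and Vol averages these per-scat fractions
  over all scats. Per-item volume fractions are the required input
  format (long CSV, one prey item per row).
* **Percent biomass (Bio)** — the least biased estimate of what was
  actually ingested, obtained by weighting scat content with a
  correction factor for differential digestibility.

## The biomass correction model

Feeding trials across felids from domestic cats to lions show that the
biomass consumed per collectable scat rises with the ratio of prey mass
*w* to predator mass *W*:

$$\mathrm{CF}(W, w) = W\left(0.033 - 0.025\,e^{-4.284\,w/W}\right)
\quad \text{kg per collectable scat.}$$

The model is linear in *W* at fixed ratio (the scale property
`CF(cW, cw) = c CF(W, w)`), strictly increasing in *w*, and bounded in
`(0.008 W, 0.033 W)`. It is applied here across its full published use
range — from 0.5 kg rodents to 212 kg sambar — with positivity as the
only guard; no extrapolation penalty is imposed. Numerically, the
strict upper bound is only representable for mass ratios up to about 8;
property tests therefore probe ratios in `[0.003, 6]`.

Percent biomass with the default **volume weighting** is

$$\mathrm{Bio}_i = 100\,\frac{V_i\,\mathrm{CF}_i}{\sum_j V_j\,\mathrm{CF}_j},$$

where $V_i$ is taxon *i*'s volume fraction summed across scats. How
multi-item scats should enter this computation is genuinely open in the
literature; volume weighting was chosen because it reproduces the
example study's printed Bio columns from its printed Vol columns to
about ±0.2 points. An occurrence-weighted alternative ($V_i$ replaced
by the count of scats containing *i*) is exposed via
`percent_biomass(..., weighting = "occurrence")` but documented as not
matching volume-resolved published tables. A useful identity follows
from the formula: volume-weighted Bio depends on the data only through
the per-taxon totals $V_i$, so it is invariant to how a taxon's volume
is distributed among scats — the property tests exploit this.

**Niche breadth.** Levins' measure $B = 1/\sum p_i^2$ is computed over
*species-level* biomass proportions, never over category aggregates;
this convention reproduces both published B values (4.27 and 3.89) in
the example analysis.

## Prey selection

Availability of each ungulate taxon is its surveyed density multiplied
by an adult-female body mass; shares below the 5% inclusion rule (a
standard guard against unstable electivity for rare species) are
excluded and the remainder renormalized, as are taxa without a mass on
record (gaur, in the example data). Jacobs' index

$$D = \frac{r - p}{r + p - 2rp} \in [-1, 1]$$

compares the used proportion *r* with availability *p*; classification
uses strict thresholds (preferred above 0.30, avoided below −0.30).

The used proportion has no canonical definition when the diet includes
taxa outside the availability set. Two conventions are implemented:

* **renormalized** (default): biomass percentages of the
  availability-included taxa rescaled to sum to 1, so *r* and *p*
  describe the same prey base. This reproduces the example study's
  printed tiger wild-pig value (−0.28).
* **raw**: $r_i = \mathrm{Bio}_i/100$ over the whole diet.

The conventions agree on the qualitative result that matters in the
example (serow preferred by both predators) but not on magnitudes, and
for taxa near neutrality not even the sign is stable (tiger muntjac:
+0.02 renormalized vs −0.09 raw around a printed 0.01). No single
convention reproduces every printed electivity value — the published
serow values (0.69/0.61) fall between the two conventions' outputs
(0.76/0.67 renormalized, 0.47/0.60 raw), most plausibly because the
original computation used unrounded per-scat volumes. The package
reports both conventions and does not force agreement; availability
standard errors are carried through for reporting but not propagated
into *D* (point values only, as is standard).

## Accumulation curves

`accumulation_curve()` answers "were enough scats collected to see the
prey spectrum?" by shuffling scat order (10,000 seeded Fisher–Yates
permutations by default) and averaging cumulative distinct-taxon
counts. The confidence band is `mean ± 1.96 SD` clipped to `[1, S]`
(the conventional output of sample-based rarefaction software) or,
optionally, empirical 2.5/97.5 permutation percentiles — the choice is
exposed because band construction is rarely stated in applied papers.
`exact_accumulation()` enumerates all orderings (up to 8 scats) as a
deterministic oracle; tests require the permutation means to sit within
3 Monte-Carlo standard errors of the exact means, and cross-check
against `vegan::specaccum` and the closed-form hypergeometric mean.

## The packaged example data

Published diet tables print marginals, not raw records.
`reconstruct_fixture()` rebuilds per-scat records from (i) occurrence
counts, derived as `round(Occ% × n / 100)`; (ii) an explicit
co-occurrence plan stating which taxa shared multi-item scats; and
(iii) the printed Vol column as volume targets. Single-item scats get
fraction 1; multi-item fractions are solved by iterative proportional
fitting (rows constrained to sum to 1 per scat, columns to the
remaining per-taxon volume; converged column deviation below 1e−6,
achieved volume within 0.15 points of target or an error is raised).

The source study never states which taxa co-occurred. The packaged plan
(`nepl_cooccurrence_plan()`) is one explicit assignment satisfying
every printed marginal, including the reported single-item scat counts
(8/14 and 14/21) and the per-category occurrence rows, which force
specific co-occurrences (e.g. the tiger's seven carnivore occurrences
fall in seven distinct scats; hog badger and civet share a clouded
leopard scat). All published statistics are provably plan-invariant, so
this choice carries no analytic weight; a property test verifies
invariance over random feasible plans.

Collection dates and scat diameters in the fixture are synthesized
(dry-season weighted 11/14 and 17/21; diameters within the printed
mean ± SD ranges) and flagged non-authoritative in the file header.

**Known deviations from the printed table.** Recomputing Bio from the
printed Vol columns reproduces every species-level cell to ±0.11 except
the two civet cells (computed 3.97 vs printed 4.2; 2.22 vs 2.4), almost
certainly because the original computation used unrounded per-scat
volumes. The printed clouded-leopard category rows are additionally
inconsistent with their own printed members (carnivore 32.7 vs
28.4 + 4.2 = 32.6; ungulate 46.1 vs 33.3 + 13.3 = 46.6). The package
computes categories as exact member sums and documents, rather than
absorbs, these sub-half-point printing artifacts. They propagate into
the clouded leopard's pipeline-computed niche breadth (4.25 vs printed
4.27, which is recovered exactly from the printed Bio column).

## The synthetic generator

`generate_scats()` emulates the data-generating process the field data
imply: per scat, an item count from `{1, 2, 3}` (defaults 0.63 / 0.31 /
0.06, from the 22/35 single-item scats and the one three-item scat per
predator in the reconstruction), a set of distinct prey taxa, and a
symmetric Dirichlet split of the scat's volume (concentration 1 =
uniform simplex; the source data give no within-scat distribution).
Season labels default to 0.8 dry / 0.2 rainy, matching the 28/35
dry-season collections.

Because estimation weights volume by CF, taxa are drawn with inclusion
probability proportional to `true_bio_i / CF_i` via systematic
probability-proportional-to-size sampling. Naive sequential weighted
draws do *not* deliver the intended unbiasedness — they depress the
dominant taxon's expected share by several points at realistic
compositions — so the selection weights are calibrated by a fixed-point
iteration until the expected volume share of every taxon equals the
target (exact wherever `k·q_i ≤ 1`; the certainty cap in three-item
scats is redistributed by the same calibration). With the example tiger
composition as truth, a single replicate of 5000 scats recovers every
taxon's biomass percentage to about ±1 point; the estimator is unbiased
(mean error below 0.001 over 20 seeds) with single-replicate breadth
noise of SD ≈ 0.06, which is why `recovery_experiment()` reports
replicate means.

At the field sample sizes (14–21 scats), the same machinery quantifies
the small-sample caveat: electivity estimates carry standard deviations
of roughly 0.06–0.10, so preference classes for taxa near a ±0.30
threshold are unstable at n ≈ 20 even when composition estimates look
reasonable. What the passing recovery tests show is that the estimators
are consistent under the model's own assumptions; they do not validate
assumptions real scats may violate (non-independent deposition,
detection bias toward trail-marking individuals, seasonal diet shifts).

## Problem sizes and numerical choices

Test and validation runs use: 10,000 permutations for accumulation
checks against exact enumeration on ≤ 8-scat sets; recovery at 5000
scats (single replicate for composition bias, five replicates for
breadth and electivity classes); consistency probes at 50/500/5000
scats. Tolerances: volume sums validated to 1e−9 (2% renormalization
window on file input, matching data-entry rounding); IPF convergence
1e−12 with a 1e−6 acceptance gate; strict inequality thresholds
everywhere the conventions above say strict. Ties in systematic PPS are
avoided by randomizing unit order each draw; all randomness flows from
a single user-supplied seed, restored on exit so package calls do not
disturb the caller's RNG state.

## Limitations

The package treats scats as independent samples of one predator
population; it does not model individual heterogeneity, spatial
structure, or DNA/microscopy identification error. Electivity inference
is point-valued by design (no bootstrap), availability is a single
density × mass product per taxon, and the biomass model is borrowed
from cross-species feeding trials rather than refit — all three match
standard practice in the field, and all three are the right first
places to look when results surprise.
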