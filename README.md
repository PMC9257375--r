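# scatdiet

Quantitative diet analysis for carnivores from field-collected scats.

Scats (feces) are often the only dietary evidence obtainable for rare,
elusive carnivores: undigested hair and bone identify what was eaten,
but raw scat contents misrepresent the diet because small prey produce
disproportionately many collectable scats per kilogram consumed.
`scatdiet` implements the standard correction-based workflow used in
felid food-habits studies, end to end:

- **Diet composition** as frequency of occurrence (Occ), percent volume
  (Vol) and percent of ingested biomass (Bio), where Bio corrects Vol
  with the generalized felid biomass model: one collectable scat
  represents

  CF = W (0.033 − 0.025 e^(−4.284 w / W)) kilograms of prey,

  for predator mass *W* and killed-prey mass *w* (kg).
- **Levins' dietary niche breadth** B = 1 / Σ pᵢ² over the biomass
  proportions (1 = specialist, S = uniform generalist over S prey).
- **Prey selection** with Jacobs' electivity index
  D = (r − p) / (r + p − 2rp), comparing the used biomass proportion
  *r* against availability *p* (prey density × adult-female mass), with
  a >5% availability inclusion rule and ±0.30 preference/avoidance
  thresholds.
- **Prey-species accumulation curves** by seeded permutation
  (mean ± SD and 95% band over random scat orderings), with an exact
  enumeration oracle for small data sets.
- **A synthetic scat generator** with known ground-truth composition
  (probability-proportional-to-size taxon sampling, calibrated so the
  expected biomass shares equal the truth), plus a parameter-recovery
  report quantifying what 14–21 scats can and cannot estimate.

The packaged example data set reconstructs a published study of clouded
leopards (*Neofelis nebulosa*) and tigers (*Panthera tigris*) in Nam
Et-Phou Louey NPA, northern Laos (14 and 21 DNA-confirmed scats), from
its printed marginal summaries.

## Worked example

```r
library(scatdiet)
res <- run_pipeline("tiger", out_dir = "out", n_permutations = 10000,
                    seed = 1)
print(res$composition)
```

```
Diet composition of tiger (n = 21 scats, volume weighting)
      taxon  category occ_pct vol_pct bio_pct
 black_bear carnivore    14.3     8.7     9.6
 hog_badger carnivore    14.3     9.5     5.6
      civet carnivore     4.8     4.8     2.2
    macaque     other     4.8     2.4     1.4
   wild_pig  ungulate    52.4    44.0    43.8
      serow  ungulate    19.0    13.1    18.0
     sambar  ungulate    14.3     8.7    12.2
    muntjac  ungulate    14.3     8.7     7.2
...
Niche breadth B = 3.89
```

Wild pig dominates the tiger's ingested biomass (43.8%), and the
biomass correction matters: serow is 13.1% of scat volume but 18.0% of
biomass because a 135 kg kill yields far fewer scats per kilogram than
small prey. Selection against availability:

```r
res$selection[c("taxon", "r", "p", "D", "preference_class")]
```

```
    taxon      r      p       D preference_class
  muntjac 0.0882 0.0846  0.0227          neutral
 wild_pig 0.5392 0.6748 -0.2788          neutral
   sambar 0.1508 0.1878 -0.1313          neutral
    serow 0.2218 0.0527  0.6731        preferred
```

Serow is the only positively selected ungulate (D = 0.67 > 0.30):
tigers ate it four times more than its share of available biomass.
Wild pig, despite being the top food, is eaten slightly below its
availability (D = −0.28). The accumulation curve reaches all 8 observed
prey species at 21 scats (`res$accumulation`), with the confidence band
quantifying how many scats a richness estimate of this kind needs.

`run_pipeline()` writes `composition.csv`, `selection.csv`,
`accumulation.csv`, a diet-table `report.md` and a `run_log.txt`
recording every reference constant, convention and seed.

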