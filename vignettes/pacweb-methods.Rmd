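---
title: "Methods: quantitative plant-herbivore webs and the potential for apparent competition"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantitative plant-herbivore webs and the potential for apparent competition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pacweb)
```

## The problem

Plants growing in a community share invertebrate herbivores. Two plants
that never interact directly can still harm each other indirectly when a
herbivore population sustained by one spills over onto the other
("apparent competition"). In invasion ecology this matters twice over:
exotic plants may escape herbivores (enemy release), suffer them
disproportionately (biotic resistance), or accumulate herbivores and
export them onto neighbours. `pacweb` turns replicated per-plant herbivore
survey counts into quantitative bipartite webs and computes the *potential*
for apparent competition between every plant pair, plus the supporting
species-level indices and a community-dominance test.

## From counts to link strengths

Surveys record, per occasion, the number of individuals of each herbivore
species observed feeding on each plant individual. Because weighing every
individual is impractical, counts are converted to **standardised dry
biomass**: for plant $i$ and herbivore $k$,

$$\alpha_{ik} = \frac{(\text{total count over surveys}) \times
  (\text{mean dry mass per individual, g})}{\text{number of surveys of
  plant } i}.$$

Dividing by the per-plant survey count corrects for plants that died
mid-experiment and were surveyed fewer times. The *mesocosm-level* total
biomass deliberately omits this division (mass × total abundance, summed
over species), because the per-plant and per-community quantities serve
different comparisons; `mesocosm_herbivore_biomass(normalize_per_survey =
TRUE)` exposes the alternative.

Dead plants are excluded from all plant-biomass analyses, but their survey
records still feed the webs and the meta-web: the herbivores were really
there.

## Pairwise PAC and its aggregation

Given the mesocosm's matrix $\alpha$ ($H$ plants × $P$ herbivores),

$$d_{ij} = \sum_{k=1}^{P} \left[ \frac{\alpha_{ik}}{\sum_l \alpha_{il}}
 \cdot \frac{\alpha_{jk}}{\sum_m \alpha_{mk}} \right],$$

the proportion of herbivore biomass attacking plant $i$ that is shared
with plant $j$. Numerical conventions:

* any $0/0$ term contributes 0 — a plant with no herbivores has an
  all-zero row, a herbivore absent from the mesocosm contributes nothing;
* consequently $\sum_j d_{ij} = 1$ exactly (diagonal included) for every
  plant with positive load — the implementation is vectorised
  (`r %*% t(cshare)`) and tested to $10^{-12}$ against a literal
  triple-loop evaluation;
* $d$ is invariant to rescaling all of $\alpha$ by a positive constant,
  so it measures *sharing structure*, not herbivore abundance.

Abundance re-enters through the weighted aggregates. Summing over
heterospecific partners only (each species occurs once per mesocosm here,
so excluding intraspecific PAC equals dropping the diagonal):

$$\text{PAC}_\text{exerted}(i) = B_i \sum_{j \ne i} d_{ji}, \qquad
  \text{PAC}_\text{received}(i) = B_{-i} \sum_{j \ne i} d_{ij},$$

with $B_i = \sum_l \alpha_{il}$ and $B_{-i} = \sum_{j \ne i} B_j$.

**Direction convention (an open design point).** $d_{ij}$ as defined above
is the potential effect *of donor $j$ on receiver $i$*. The aggregation
prose this package follows ("summing PAC values for the focal species on
all other community members") does not pin down whether the focal species
is the row or the column index. We adopt the reading consistent with the
definition of $d_{ij}$ — exerted sums the focal plant's *column*
($d_{ji}$), received its *row* ($d_{ij}$) — and expose
`aggregate_pac(direction = "transposed")` for the other reading. The two
differ only in labelling, not in the set of numbers produced, and the
exerted/received pair simply swaps.

**Weighting scale.** Weights use the standardised (per-survey) biomass
scale, the same scale as $\alpha$; since $d$ is scale invariant, weighting
on the un-normalised scale would only multiply both aggregates by the
common survey count.

**Summaries.** Group summaries log-transform PAC, which is right-skewed
with exact zeros; we use $\log(x + \tfrac{1}{2}\min\{x : x>0\})$ when
zeros are present (offset recorded in the output attributes), no offset
when none are, and report raw-scale means alongside.

## Meta-web and informative zeroes

The **meta-web** is the binary union of realised interactions across all
mesocosms; an absence of herbivore $k$ on plant species $s$ is treated as
an informative zero only if $(s, k)$ appears somewhere in the meta-web
(the herbivore demonstrably can feed on that species), otherwise it is
discarded (`zero_fill_presence()`). **Normalised degree** divides a
plant's realised herbivore richness by the number of herbivore species
active in its own mesocosm, making richness comparable across mesocosms
that received different colonists.

**Damage index.** Field damage scores are ordinal (0 = none, 1 = 1–5 %,
2 = 6–25 %, 3 = 26–50 %, 4 = 51–75 %, 5 = > 75 % of leaf area). Only the
category-3 midpoint (38 %) is fixed by the source convention; the others
are range midpoints consistent with it: 0, 3, 15.5, 38, 63, and 88 (the
last reading "> 75 %" as 76–100 %). The index is the per-plant mean of the
mapped values over surveys.

## The dominance test

Per mesocosm, the realised exotic share of plant biomass is
$\sum_\text{exotic} b / \sum_\text{all} b$ over alive plants (total =
above + below ground; aboveground-only by flag). For each planted exotic
level in $\{0.25, 0.5, 0.75\}$ — levels 0 and 1 are excluded because the
realised share is then constrained to the boundary — crossed with the
herbivore treatment, the group mean and a two-sided 95 % Student-$t$
interval are computed (the CI method was not specified by the source
analysis; $t$ on the raw proportions matches its "mean ± 95 % CI, n = 16"
presentation, and a percentile bootstrap is available by flag). A group
"exceeds expected" when its lower CI bound lies above the planted
proportion; the ±Herbivore overlap flag reproduces the CI-overlap
reasoning used to ask whether herbivory alters dominance.

## What the generator simulates — and what it does not

The generator is a *stated world*, fixed up front, not a dial tuned to
test outcomes.

Structure (all defaults): a 39-species plant pool (19 native, 20 exotic;
7 woody in each), 20 communities of 8 species laid out on a balanced grid
of exotic levels $\{0, .25, .5, .75, 1\}$ × woody levels
$\{0, .125, .375, .625\}$ so the two planted gradients are exactly
orthogonal; a 20-species herbivore pool (7 native, 13 exotic; 13 added,
7 self-colonised) with fundamental host ranges of 6–16 plant species;
2 herbivore × 2 soil treatments × 2 replicates = 160 mesocosms; 8 surveys.

Stochastic model, per (plant, in-range herbivore, survey):

| parameter | default | units / scale | why |
|---|---|---|---|
| `presence_base_prob` | 0.12 | probability per visit | free parameter (no per-species detection rates are published); gives per-pair realisation rates over 8 surveys comparable to the observed web fill |
| `exotic_interaction_odds_multiplier` | 2.0 | odds ratio | herbivores were about twice as likely to interact with exotic plants |
| `exotic_biomass_multiplier` | 1.72 | ratio of conditional mean counts | 72 % higher herbivore biomass per realised interaction on exotics |
| `minus_H_presence_retention` | 0.21 | probability multiplier | exclusion cages reduced herbivore presence by 79 %; removal is modelled as thinning of *all* species (spillover of added species into −H cages was real), not as a hard zero |
| `exotic_herbivore_prop_exotic_slope` | 1.0 | logit units per unit planted proportion | exotic herbivore load rises with community exotic fraction; the published slope is on a different (log-biomass) scale, so this is a free positive parameter |
| `count_mean_native`, `count_size` | 2.5, 1 | individuals; NB dispersion | overdispersed counts; free parameters |
| `plant_growth` | meanlog log 3 (native), log 12 (exotic), sdlog 0.8 | g, log-normal | exotics are several-fold larger, matching the reported 3.8–5.7× biomass advantage |
| `herbivory_biomass_penalty_exotic` | 0.31 | proportional reduction | exotics produced 31 % less biomass with herbivores; applied on the log scale so the geometric +H:−H ratio is exactly 0.69 |
| `death_prob` | 0.03 | per plant | small, exercises the "< 8 surveys" branch |

Counts given presence are **zero-truncated negative binomial
parameterised by the conditional mean** (the untruncated $\mu$ is solved
by `uniroot`): this makes the exotic multiplier an exact conditional-mean
ratio, so parameter recovery tests the pipeline's estimators rather than
truncation algebra. Damage categories are drawn from provenance-specific
weights (exotics slightly higher, mean damage a few percent, matching the
low damage observed); in −H mesocosms the non-zero category mass is
thinned by the retention parameter. The soil treatment is a pure label
with no simulated effect (default 0), mirroring the null soil results —
so any soil "effect" found downstream on synthetic data is a false
positive by construction.

Seeding: one master seed; every mesocosm's surveys, schedule, damage and
biomass use substreams derived by stable hashing of the mesocosm id, so
subsetting a design to fewer communities leaves the remaining mesocosms'
data bit-identical (tested).

**Not simulated** — hence not established by green tests: predator and
parasitoid trophic levels (PAC here is *potential*, never realised
dynamics); soil-biota mechanisms; trait covariates (SLA, legume status);
within-season population dynamics (surveys are i.i.d. given the design);
spatial structure within mesocosms; observation error in damage scoring.
The penalty on exotic biomass is applied at treatment level, not coupled
to each plant's realised herbivore load, so the generator cannot be used
to test load–biomass regressions.

## Parameter recovery and calibration

Four estimators (`estimate_generator_effects()`) invert the generator's
model from pipeline-visible tables: a binomial GLM on zero-filled
survey-level presence recovers the presence odds ratio; a quasi-Poisson
log-link regression of per-record biomass on plant provenance and
herbivore species recovers the biomass multiplier (consistent for the
multiplicative mean whatever the count distribution); the −H:+H presence
rate ratio recovers retention; a log-scale regression of alive exotic
biomass on treatment recovers the penalty. Zero-filling for recovery uses
the generator's ground-truth host ranges (echoed in
`generator_truth.json`) rather than the realised meta-web, because
conditioning on realisation selects pairs on their own presence draws and
would bias the rates at reduced size. The acceptance suite checks that
the Monte-Carlo 95 % interval of each estimator's mean over 100 reduced
replicates covers the configured value, and that with a
provenance-neutral configuration the dominance test's one-sided CI
exceedance rate over 1000 simulated experiments is 2.5 % within binomial
error (the realised exotic share is exchangeable across plants under
neutrality, so its expectation equals the planted share exactly).

## Known limitations

* Matrices are indexed by plant individual; with one individual per
  species per mesocosm this coincides with species-level PAC, but the
  intraspecific-exclusion rule would need revisiting for designs with
  conspecific replicates within a community.
* The $t$-interval's coverage for bounded, mildly skewed proportions at
  n = 16 is approximate; the null-calibration test quantifies exactly how
  approximate under the stated world.
* `validate_inputs()` enforces the CSV schemas and referential integrity
  but does not attempt to clean or ingest third-party deposits; adapters
  for external datasets are out of scope.
* All computation is plain R; the largest default run (160 mesocosms,
  8 surveys) takes seconds, so no compiled code is warranted.
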