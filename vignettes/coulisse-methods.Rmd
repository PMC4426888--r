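---
title: "Simulating a multifunctional bocage landscape under opposing CAP futures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating a multifunctional bocage landscape under opposing CAP futures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Hedgerow-rich (*coulissen*/bocage) agricultural regions supply food, scenery,
habitat and tourism at once. Their future depends on thousands of individual
farm-household decisions — expand, contract, retire, sell, cut or plant
hedgerows — each shaped by age, management style, location and the policy
environment. `coulisse` is an agent-based simulator of such a region. It
generates a synthetic ~53,000 ha landscape of 1-ha parcels calibrated to a
2005 baseline (1,705 farm households, 45,765 ha agricultural land, 5,045 ha
semi-natural land, 31% diversified/multifunctional farmers, rural residents
38% of the rural population) and advances it year by year to 2030 under two
opposing EU agricultural-policy futures:

* **BTS** — *balanced, targeted and sustainable support*: a flat-rate payment
  with a cap, a small-farm subsidy, compulsory support for "green" public
  goods in protection zones, diversification aid in LEADER zones, and a
  tourism feedback on landscape quality.
* **AMIS** — *abolition of market and income support*: a price–cost squeeze
  that pushes low-productivity farms out, expansion concentrated on
  productive land, nature organisations buying ecologically significant
  parcels, and widespread hedgerow removal outside protected zones.

On top of either future, three stakeholder-derived interventions can be
switched on: zoning restrictions on intensive (expansionist) farms in
protected and pilot zones, a cooperation/tourism sub-model in which farmers
adopt multifunctional practices from their neighbours, and an urban
in-migration programme that raises the purchase probability of small rural
estates.

## The annual decision cycle

A simulated year executes a fixed phase order (the sources describing the
original model leave the within-year order unspecified; fixing it, with a
fresh RNG sub-stream per `(seed, replicate, year)`, makes every trajectory
reproducible bit for bit and auditable):

1. **Ageing** — every active farmer ages one year (capped at 100).
2. **Cessation and succession** — a farmer past their personal retirement age
   (drawn once per agent from N(65, 5) years) retires each year with hazard
   0.094. A retiring farmer hands the farm to a successor (who restarts at
   ~N(36, 6) years) with a type-specific succession probability; otherwise
   the farm ceases. Independently of retirement, a farm may cease for
   business reasons with a small annual (type × age-class) base rate,
   multiplied by scenario levers: the small-farm subsidy multiplier (farms
   < 10 Dutch Size Units, BTS 0.6), the low-productivity squeeze (AMIS ×4
   when mean holding productivity < 0.35), and LEADER-zone diversification
   aid (BTS ×0.75 for diversified farms).
3. **Offers** — ceasing farms offer *all* parcels the same year (the
   "aggressive land market"); continuing farms offer their farthest parcel
   with probability 0.02 (contraction).
4. **Expansion bids** — farmers enter the land market with a type- and
   scenario-dependent participation probability; each bid scores
   `propensity × productivity × proximity × zone multiplier`, with no bids
   below the scenario's productivity floor or beyond 15 km.
5. **Market allocation** — per parcel, in id order: highest farmer bid
   (capacity 6 parcels/yr per buyer); otherwise an estate purchase by a new
   rural resident with probability `p_estate` when the parcel is small and
   aesthetic; otherwise a nature-organisation purchase (`p_nature`, AMIS
   only, in habitat/protection zones); otherwise abandonment to semi-natural
   land. Abandonment converts immediately — the one-year lag alternative
   would only delay the identical area accounting.
6. **Landscape elements** — every managed parcel draws cut/keep/plant from a
   (manager class × zone × scenario) table; cutting removes 50% of the
   parcel's element length, planting adds 50 m/ha. Protection-zone
   multipliers lower cutting and raise planting under BTS; a small
   scenario-independent stewardship bonus adds planting in habitat zones.
7. **Cooperation adoption** (intervention) — see below; adopters switch type
   simultaneously at year end.
8. **Tourism demand** — the index multiplies by `1 + g·Δ` where `Δ` is the
   weighted relative change in element length, semi-natural area and
   attraction count (BTS `g = 0.5`; AMIS `g = 0`).

Total area is conserved exactly in every phase, ownership stays a partition,
and the farmer population can only shrink (succession preserves, never adds;
estate buyers become residents, not farmers).

## The synthetic region

No deposited region data exist, so `generate_region()` builds one: a
rectangular grid of 1-ha cells sized so the configured areas tile it exactly
(the stated areas force ~53,000 ha, not the nominal 20 × 30 km of the study
area — every non-semi-natural parcel must have an owner, so the extent must
close). Policy zones (landscape protection 15%, habitat directive 10% nested
inside it, agricultural development 25% disjoint from protection, LEADER
20%, one contiguous pilot sub-area of 8% standing in for the policy pilot
municipality) are painted by seeded stochastic region-growing, so they are
contiguous blobs rather than scattered noise. Productivity and aesthetics
are smooth random fields (rank-transformed bilinear interpolation of a
coarse Gaussian lattice) with a productivity bonus in development zones and
a malus in habitat zones. Farms receive 60% of their parcels contiguously
around the farmstead and 40% scattered within 16.5 km, which reproduces the
baseline mean farmstead-to-farthest-parcel distance of ~15 km. Baseline
element length per parcel is gamma-distributed, twice as dense in protection
zones, normalised to 5,000 km region-wide (only the *percentage change* of
this total is an outcome of interest, so the absolute level is a free
default).

What the generator does **not** emulate: real cadastral geometry, road and
water networks, soil maps, the actual spatial autocorrelation of Dutch farm
censuses, or farm economics as cash flows. A green test therefore
establishes that the *decision dynamics* reproduce the reported indicator
trajectories on a landscape with the right composition and structure — not
that the model predicts the real region parcel by parcel.

## Calibration

The original model's parameter values lived in an unavailable supplement, so
every probability here is a shipped calibration default, tuned once so that
the two scenario presets reproduce the case region's reported 2005 → 2030
indicator trajectories
(farmer counts, agricultural and semi-natural area, multifunctional share,
element change) and the reported intervention effects. Two structural
choices were forced by that table and deserve note:

* **Succession probabilities.** The reported trajectories require ~28%
  total farmer attrition over 25 years while the multifunctional share falls
  from 31% to 16% and expansionists barely decline. With a realistic age
  structure (mean 55) and retirement around 65, this pins succession high
  for expansionists (0.933), intermediate for conventional farms (0.72) and
  low for diversified farms (0.10) — diversified businesses rarely find
  successors, which is exactly the mechanism the policy debate worries
  about. A naive ordering with diversified succession above conventional
  cannot produce the reported share decline.
* **Retirement hazard.** The zoning intervention (succession banned in
  restricted zones) reduces pilot-zone expansionists by the probability that
  a farm faces retirement at all within the horizon; the reported ~60%
  declines pin that probability near 0.65, hence the annual hazard of 0.094
  past the personal retirement age.

## The cooperation/tourism sub-model

Each active non-multifunctional farmer censuses its `k = 10` nearest active
farmers (Euclidean farmstead distance, ties by id — verified in the tests
against a brute-force all-pairs computation). If at least `threshold = 4`
are diversified/multifunctional *and* a tourist asset lies within the search
radius of the farmstead, the farmer adopts with probability
`rate × (1 + tourism_increase) × tourism_demand` (defaults 0.10, 0.10). The
census uses start-of-year types only; adopters switch simultaneously at
year end, so no within-year cascade is possible.

A tourist asset is any of: a dominant patch of semi-natural land (≥ 90% of a
250-m asset cell — a scattered abandoned 1-ha field is not a tourist draw),
an attraction-tagged parcel, or hedgerow density above the baseline 99th
percentile of 250-m cells. The density threshold is frozen at baseline, so
landscape restoration (BTS) moves cells above it and landscape
rationalisation (AMIS) moves cells below it over the run — this is the
mechanism by which the same intervention is roughly twice as effective under
BTS as under AMIS. The search radius is deliberately the immediate farm
surroundings (250 m, not kilometres): at a 2-km radius assets are
near-ubiquitous in a bocage landscape and the adoption flow overshoots the
reported effect by an order of magnitude.

## Numerical and design choices

* All scenario effects are multipliers/overrides on neutral base tables;
  `effective_probability()` is `min(1, base × Π multipliers)`, so modifier
  order is irrelevant and compositions clamp rather than overflow.
* Cessation outcomes are drawn with a single uniform per farmer, indexed by
  farmer row, with "cease" occupying the lower interval — raising any
  cessation multiplier can only enlarge that interval, which makes
  common-random-number comparisons monotone by construction.
* Element action triples must sum to 1 within 1e-9 at load time; zone
  modifiers are applied to cut and plant, `keep` absorbing the remainder
  (rescaled if cut + plant would exceed 1); element length is floored at 0.
* Market allocation resolves parcels in id order and ranks equal-scored bids
  by bidder id; a parcel offered twice is a hard error.
* Grid maps are written as ESRI ASCII (this environment has no GeoTIFF
  writer; the format contract allows either) with `%.17g` formatting so
  round-trips are bit-exact; parcels export as GeoJSON squares.
* Replicate `r` of a run with master seed `s` reseeds each year from a
  32-bit integer mix of `(s, r, year)`; summaries are therefore invariant to
  replicate execution order, and a rerun reproduces every number.

## Known limitations

* The farm-size indicator (agricultural area / farmer count, ~27 ha at
  baseline) does not match the case study's reported farm-size row, whose
  denominator is undefined in the sources; it is reported but not targeted.
* The zoning intervention's mechanism is scenario-independent, so the
  reported 63% vs 56% split between the two futures can only be matched to
  within the shared band (~65% here) — no documented lever separates them.
* Hobby farms are supported throughout but the default baseline mix gives
  them zero share; resident land-management heterogeneity is reduced to one
  "resident" element-action class.
* Prices, incomes and the monetary side of the land market are out of scope;
  the "price–cost squeeze" exists only as probability modifiers.
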