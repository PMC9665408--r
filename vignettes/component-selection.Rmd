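---
title: "Selecting RBA components: model, defaults, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Selecting RBA components: model, defaults, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rbaselect)
library(dplyr)
```

## The selection model

A food risk–benefit assessment (RBA) compares health impact across two
dietary scenarios — here always a two-food substitution — and must first
decide which nutritional, microbiological, and toxicological components
the impact model will contain. `rbaselect` formalizes that decision as
three nested lists.

**Long list.** All candidates per domain. For nutrients the package
applies two screening questions: is the evidence linking the component
to a health outcome *convincing* (components graded *limited* or
*contradictory* are excluded), and do the two foods actually differ?
The difference question uses the relative concentration difference

$$d = \frac{|c_A - c_B|}{(c_A + c_B)/2}$$

with inclusion when $d$ strictly exceeds 20% (10% allowance for
analytical error plus a minimum meaningful 10% difference). A nutrient
quantified in only one food is always included, since a substitution
changes its intake by construction. Hazards skip the difference
question entirely: a hazard reported for either food is a potential
contamination and enters the long list for each food where found.

**Short list.** Every evidence-gated component receives a
prioritization index, the product of an occurrence criterion and a
severity criterion, each built from 3-point sub-criteria:

| domain | occurrence sub-criteria | severity sub-criteria | index range |
|---|---|---|---|
| nutrition | presence in raw material; processing effect | policy relevance (FBDG/fortification); intake contribution; bioavailability | 1–243 |
| microbiology | prevalence × process effect, re-banded to 1–3 | DALY/1,000 cases bin | 1–9 |
| toxicology | presence vs reference doses + exposure share, combined to 1–3 | four-statement grading | 1–9 |

Nutrition deliberately carries three severity sub-criteria against two
occurrence sub-criteria (a 3/5 vs 2/5 proportional weight): nutrients
are naturally present and obtainable from many foods, so their
public-health relevance matters more than their mere occurrence,
whereas hazards weigh the two criteria equally. The index thresholds
are inclusive — a component scoring exactly the limit is kept — with
defaults 108 (nutrition, attainable as $2 \cdot 2 \cdot 3 \cdot 3
\cdot 3$) and 2 (both hazard domains, same limit for both foods).

**Final list.** Nutrients short-listed for exactly one food are
symmetrically added as candidates for the other (`symmetry_added`),
because the substitution changes their exposure on both sides; hazards
are never mirrored, as each food's contamination stands on its own.
Every candidate then needs all applicable data-availability items:
dose–response, outcome incidence, source attribution (microbiology
only), intake data, composition/contamination data, and a DALY value
per case. Anything failing here is excluded with the missing items
named in the ledger — these exclusions are themselves a result, to be
reported as data gaps.

## Tunable parameters

Everything the framework leaves numerically open is a `rba_config()`
key, overridable per call or from YAML:

* `longlist$concentration_diff_threshold` (0.20) and
  `longlist$diff_denominator` (`"mean"`): the mean denominator makes
  the 20% rule symmetric in the two foods and scale-invariant, which
  fits a substitution with no privileged reference food; `"max"` and
  `"reference"` are available for assessors who prefer a conservative
  or baseline-anchored reading.
* `nutrition$presence_low_fraction` (0.10): detection in fewer than 10%
  of samples scores 1; only detection in *all* samples scores 3, and
  everything between is the middle band (the two extremes are the only
  ones the grading defines; the middle is the remainder).
* `nutrition$intake_cuts` (1/3, 2/3): the contribution of the food to
  population intake of the nutrient has no published cut points, so the
  default bins are tertiles of the [0, 1] share; layer 2 (a
  composition-difference class) is consulted only when no contribution
  estimate exists.
* `nutrition$processing_levels` and `nutrition$bioavailability_levels`:
  the level directions are fixed so that a higher level always means
  greater public-health relevance of this food as a source — a nutrient
  eliminated by processing scores 1, one preserved or concentrated
  scores 3; a significant matrix-driven bioavailability reduction
  scores 1, mild-or-none scores 3. Both maps are overridable.
* `microbiology$occurrence_band_map` (1–2 → 1, 3–4 → 2, 6–9 → 3): the
  grading both multiplies the two occurrence sub-scores (raw range up
  to 9) and keeps the final hazard index within 1–9, which is only
  consistent if the raw product is re-banded to 1–3 before meeting
  severity. The default bands split the six attainable raw products
  into three pairs; the map is a config key and recorded in run
  output.
* `microbiology$severity_bins` (10, 100 DALYs per 1,000 cases),
  closed-left: exactly 10 opens the 10–99 band, exactly 100 the
  100–1,000 band. Values above 1,000 clamp to level 3 with a warning.
  Severity may be supplied as DALY/case in input files; it is
  multiplied by 1,000 on load.
* `toxicology$exposure_bins` (0.10, 0.50): both printed edges belong to
  the middle band (a 10% or 50% share scores 2).
* `toxicology$occurrence_combiner` (`"ceiling_mean"`): the two
  occurrence sub-scores must collapse to 1–3 to keep the index in 1–9;
  the ceiling of the mean is the default (the same tension as the
  microbiology band map, resolved in the same spirit), with `"min"`
  and `"max"` as alternatives.
* `toxicology$severity_map` (≤1 true statement → 1, exactly 2 → 2,
  ≥3 → 3): the statement-count-to-level map has no published
  thresholds; the default is the symmetric choice. Statements (c)
  lifelong disability and (d) high disability (DW > 0.4) are counted
  independently even where they overlap for chronic conditions.
* `selection$thresholds`: inclusive, per domain.

Tie-breaking in `rank_components()` is deterministic and invented:
descending index, then descending severity criterion score (severity is
the emphasized criterion in the nutrition weighting), then component id.

## Degenerate inputs and edge conventions

Two zero concentrations make the relative difference undefined; such a
pair is excluded from the long list with that reason rather than
erroring the run. A nutrient pair with a missing concentration on
either side is kept on qualitative presence — the numeric rule applies
only when both numbers exist. Concentration units must match within a
component across foods (no conversion is attempted; the loader rejects
mismatched rows). All sub-criterion levels are integers in {1, 2, 3};
no fractional levels exist anywhere, so every index is an integer and
`index == occurrence_score * severity_score` is asserted on
construction. Checklist flags must be explicit `TRUE`/`FALSE` at the
final gate; an `NA` is an error, not a default.

## The packaged case study

`load_novrba()` returns the beef-vs-cricket substitution fixture: the
published long list per domain and food, a checklist, outcome links,
and the expected short/final memberships. The published account prints
*memberships*, not the underlying sub-criterion scores, so all fixture
attribute values are synthesized to be consistent with those
memberships under the default configuration and flagged
`synthesized = TRUE`; regression tests assert membership, never the
synthesized scores. Two published inconsistencies are preserved rather
than resolved: the summary counts of the long and short lists do not
reconcile with the enumerable table rows (grouped entries), and the
chemical-hazard columns of the short-list table omit inorganic arsenic
for beef even though the final list and the narrative counts require
it — the fixture short-lists it for beef and marks that row
`printed = FALSE` in the expected-membership table.

## The synthetic generator and its oracle

`synthetic_spec()` + `generate_profiles()` draw a seeded two-food
scenario: per-domain component counts (defaults 40/14/12, the
magnitudes of the case study), per-sub-criterion level probabilities
(default uniform), an evidence mix (85% convincing, 10% limited, 5%
contradictory), 15% single-food nutrients, 20% below-threshold
concentration pairs, and a 15% chance that any applicable checklist
item is missing. Attributes are drawn *within* the band implied by the
sampled level (e.g. a level-2 detection fraction lands in [0.1, 1)),
so the generator and the scorer can disagree only if one of them is
wrong. Ground truth comes from `oracle_truth()`, a straight-line
re-derivation of every level, index, and stage decision with
hard-coded rules and plain loops that shares no code or configuration
with the engine. `index_distribution()` additionally enumerates the
exact index probability mass implied by the level distributions, which
the test suite compares with the empirical short-list inclusion rate.

What the generator does *not* emulate: correlated sub-criteria (in real
data, a hazard's prevalence and its process resistance are not
independent), more than two foods, qualitative-only nutrient presence,
conflicting multi-source detection fractions, or unit heterogeneity.
Passing tests therefore demonstrate that the engine implements the
selection rules exactly, not that the rules themselves capture any
particular real food pair.

## Problem sizes and runtimes

The test suite enumerates all $3^5 = 243$ nutrition and $3^3 = 27$
hazard level combinations exhaustively; oracle-equivalence runs cover
three seeds at 250/60/60 components per domain (about 1,900
component-by-food rows in total); the inclusion-rate check uses 5,000
scored nutrition rows, where the binomial standard error (~0.4
percentage points) sits far inside the ±3-point acceptance band. The
whole suite runs in well under a minute on a single CPU.

## Known limitations

* The engine selects components; it does not model dose–response,
  exposure, or DALYs — HBGV/MoE exceedance and severity statements
  arrive as curated flags.
* Exactly two foods per scenario; multi-food baskets would need a
  generalized symmetry rule.
* No unit conversion: concentration units must already agree.
* Evidence levels are input annotations; no literature retrieval or
  weight-of-evidence computation is attempted.
* The middle prevalence class in microbiology (what separates
  *occasional* from *rare* or *common*) is a labelled enumeration whose
  quantitative meaning is left to the assessor, as the grading scheme
  itself does not fix it.
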