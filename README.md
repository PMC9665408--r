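# rbaselect

Harmonized, auditable selection of the components of a food risk–benefit
assessment (RBA).

## The problem

An RBA weighs the beneficial and adverse health effects of a dietary
change — say, replacing minced beef with house-cricket (*Acheta
domesticus*) powder — across nutrition, microbiology, and toxicology at
once. Before any burden modelling can start, the assessor must decide
*which* nutrients, microbial hazards, and chemical hazards enter the
model. Historically that choice rested on unstandardized expert
judgment, and it can change the conclusions of the whole assessment.

`rbaselect` implements a three-tier, fully logged selection pipeline for
a two-food substitution scenario:

1. **Long list** — every candidate component per domain. Nutrients
   quantified in only one food are always kept (it is a substitution);
   nutrients present in both foods are kept only when their relative
   concentration difference `|a − b| / mean(a, b)` exceeds 20% (10%
   analytical-error allowance plus a 10% minimum meaningful difference);
   all reported microbiological and toxicological hazards are kept.
   Components whose link to a health outcome is not backed by
   *convincing* evidence are then dropped at an evidence gate.
2. **Short list** — each surviving component is graded on 3-point
   sub-criteria and receives a prioritization index

   `INDEX = score(criterion 1: occurrence) × score(criterion 2: severity)`

   In nutrition, occurrence multiplies two sub-criteria (presence in the
   raw material, processing effect) and severity three (dietary-policy
   relevance, contribution of the food to nutrient intake,
   matrix-driven bioavailability reduction), so the index spans 1–243
   and severity carries 3/5 of the sub-criteria. For hazards the two
   criteria weigh equally and the index spans 1–9: microbiology combines
   prevalence × process effect (re-banded to 1–3) with a DALY-per-1,000-cases
   severity bin (<10, 10–99, 100–1,000); toxicology combines presence
   relative to reference doses (LOD/LOQ, HBGV exceedance, MoE < 10,000
   for genotoxic carcinogens) and share of total dietary exposure
   (<10%, 10–50%, >50%) with a four-statement severity grading.
   Inclusive thresholds (defaults: 108 for nutrition, 2 for hazards)
   cut the short list.
3. **Final list** — a nutrient short-listed for one food is
   symmetrically assessed for the other; every candidate then passes a
   data-availability checklist (dose–response, incidence, source
   attribution for microbes, intake, composition/contamination,
   DALY-per-case). Exclusions here are data gaps that must be reported
   alongside the RBA results.

Every inclusion and exclusion at every stage lands in a selection
ledger with its reason, and each component's sub-score levels carry a
rationale string, so the selection is transparent end to end.

## Worked example

The beef-vs-cricket case study ships as a fixture (`load_novrba()`);
its attribute values are synthesized to be consistent with the
published list memberships and flagged as such.

```r
library(rbaselect)
library(dplyr)

novrba <- load_novrba()
run <- rba_run(novrba$profiles, novrba$checklist,
               outcomes = novrba$outcomes, scenario_id = "novrba")
run
#> <rba_run> novrba -- foods: ad vs beef
#>   long list: 127 | evidence-gated: 127 | short list: 35 | final list: 23
#>   ledger entries: 427
```

127 component-by-food profiles enter; 35 rows clear the index
thresholds; after the nutrient symmetry expansion and the checklist
gate, 23 component-by-food pairs make the final list. The tidied run
shows, per component and food, the index and how it travelled:

```r
tidy(run) |>
  filter(domain == "nutrition", in_finallist, food_id == "ad") |>
  arrange(desc(index)) |>
  select(component_id, index, in_shortlist, symmetry_added)
#> # A tibble: 7 × 4
#>   component_id    index in_shortlist symmetry_added
#> 1 calcium           162 TRUE         FALSE
#> 2 fiber_insoluble   162 TRUE         FALSE
#> ...
#> 7 vitamin_b12        36 FALSE        TRUE
```

Vitamin B12 scored 36 (< 108) for cricket powder and was short-listed
for beef only; the symmetry rule carries it onto the cricket side so
the substitution's B12 change can be assessed for both foods — exactly
the seven shared final nutrients of the case study (calcium, insoluble
fiber, iron, magnesium, sodium, vitamin B12, zinc). The outcome tree
links each final component to its health outcomes with the effect
direction:

```r
cat(format_outcome_tree(run$outcome_tree), sep = "\n")
#> nutrition:
#>   sodium
#>     -> cardiovascular_disease [adverse]
#>     -> gastric_cancer [adverse]
#> ...
```

`autoplot(run)` plots every index against its domain threshold, and
`write_run_report(run, "report.json")` serializes the lists, scores,
ledger, and configuration snapshot (byte-identical for identical
inputs). A thin CLI wraps the same functions:

```sh
inst/scripts/rba-select report --profiles profiles.csv \
    --checklist checklist.csv --out report.json
inst/scripts/rba-select simulate --seed 7 --out sim/
```

Everything the framework leaves open — bin edges, class→level maps,
occurrence combiners, thresholds, the 20%-rule denominator — lives in
`rba_config()` and can be overridden per run or via a YAML file.

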