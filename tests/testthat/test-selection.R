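test_that("ranking is descending by index with severity-then-id tie-breaks", {
  scores <- score_components(dplyr::bind_rows(
    micro_profile("A", daly_per_1000_cases = 500),  # index 9
    micro_profile("B", prevalence_class = "rare", processing_effect = "reduces",
                  daly_per_1000_cases = 500),       # index 3
    micro_profile("C", daly_per_1000_cases = 500)   # index 9, tie with A
  ))
  ranked <- rank_components(scores)
  expect_equal(ranked$component_id, c("A", "C", "B"))
  expect_equal(ranked$rank, 1:3)

  empty <- rank_components(score_components(empty_profiles()))
  expect_equal(nrow(empty), 0)
  one <- rank_components(score_components(micro_profile("only")))
  expect_equal(one$component_id, "only")
})

test_that("ties prefer the higher severity criterion before the id", {
  scores <- score_components(dplyr::bind_rows(
    # occurrence 3 x severity 2 = 6
    micro_profile("zeta", daly_per_1000_cases = 50),
    # occurrence 2 x severity 3 = 6
    micro_profile("alpha", prevalence_class = "occasional",
                  daly_per_1000_cases = 500)
  ))
  expect_equal(rank_components(scores)$component_id, c("alpha", "zeta"))
})

test_that("short-list thresholds are inclusive and per domain", {
  nut <- score_components(dplyr::bind_rows(
    nutrition_profile("at_threshold", sample_detection_fraction = 0.5,
                      processing_effect = "reduces",
                      intake_contribution = 0.9,
                      bioavailability_reduction = "mild_or_none"),
    nutrition_profile("below", intake_contribution = 0.2,
                      bioavailability_reduction = "moderate")
  ))
  # verify the constructed indices before asserting the rule
  expect_equal(nut$index[nut$component_id == "at_threshold"], 108L) # 2*2*3*3*3
  expect_equal(nut$index[nut$component_id == "below"], 54L)
  sl <- apply_shortlist_threshold(nut)
  expect_equal(sl$members$component_id, "at_threshold")

  haz <- score_components(dplyr::bind_rows(
    micro_profile("keep", prevalence_class = "rare",
                  processing_effect = "neutral", daly_per_1000_cases = 50),
    micro_profile("drop", prevalence_class = "rare",
                  processing_effect = "reduces", daly_per_1000_cases = 5)
  ))
  expect_equal(sort(haz$index), c(1L, 2L))
  sl <- apply_shortlist_threshold(haz)
  expect_equal(sl$members$component_id, "keep")
  excl <- sl$ledger[sl$ledger$decision == "excluded", ]
  expect_match(excl$reason, "index 1 < threshold 2")
})

test_that("raising an index never removes a component from the short list", {
  set.seed(9)
  sim <- generate_profiles(synthetic_spec(seed = 9, n_nutrition = 30,
                                          n_microbiology = 10,
                                          n_toxicology = 10,
                                          evidence_probs = c(1, 0, 0)))
  scores <- score_components(evidence_gate(
    build_long_list(sim$profiles)$members)$members)
  before <- apply_shortlist_threshold(scores)$members
  bumped <- scores
  bump <- bumped$index < c(nutrition = 243, microbiology = 9,
                           toxicology = 9)[bumped$domain]
  bumped$index[bump] <- bumped$index[bump] + 1L
  after <- apply_shortlist_threshold(bumped)$members
  expect_true(all(run_key(before) %in% run_key(after)))
})

test_that("nutrient symmetry adds the mirror food and leaves pairs alone", {
  shortlist <- tibble::tibble(
    component_id = c("b12", "iron", "iron"),
    food_id = c("beef", "beef", "cricket"),
    domain = "nutrition")
  out <- apply_nutrient_symmetry(shortlist, c("beef", "cricket"))
  b12 <- out[out$component_id == "b12", ]
  expect_setequal(b12$food_id, c("beef", "cricket"))
  expect_equal(b12$symmetry_added[b12$food_id == "cricket"], TRUE)
  expect_false(any(out$symmetry_added[out$component_id == "iron"]))
  expect_equal(nrow(out), 4)
  expect_error(
    apply_nutrient_symmetry(
      tibble::tibble(component_id = "pcb", food_id = "beef",
                     domain = "toxicology"), c("beef", "cricket")),
    "nutrients only")
})

test_that("the checklist gate requires every applicable data item", {
  cand <- tibble::tibble(
    component_id = c("iron", "copper", "salmonella", "cadmium"),
    food_id = "beef",
    domain = c("nutrition", "nutrition", "microbiology", "toxicology"))
  checklist <- tibble::tibble(
    component_id = cand$component_id, food_id = "beef",
    has_dose_response = c(TRUE, FALSE, TRUE, TRUE),
    has_incidence = TRUE,
    # missing source attribution blocks the microbe but not the metal
    has_source_attribution = c(TRUE, TRUE, FALSE, FALSE),
    has_intake_data = TRUE, has_composition_or_contamination = TRUE,
    has_daly_per_case = TRUE)
  out <- apply_checklist_gate(cand, checklist)
  expect_setequal(out$members$component_id, c("iron", "cadmium"))
  excl <- out$ledger[out$ledger$decision == "excluded", ]
  expect_match(excl$reason[excl$component_id == "copper"], "dose_response")
  expect_match(excl$reason[excl$component_id == "salmonella"],
               "source_attribution")

  expect_error(
    apply_checklist_gate(cand, checklist[-1, ]), "no checklist status")
  na_checklist <- checklist
  na_checklist$has_incidence[1] <- NA
  expect_error(apply_checklist_gate(cand, na_checklist), "explicit")
})
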