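test_that("relative difference matches hand arithmetic under the mean denominator", {
  expect_equal(relative_difference(100, 100), 0)
  expect_equal(relative_difference(100, 150), 0.4)
  expect_equal(relative_difference(0, 50), 2) # passes any threshold <= 200%
  expect_error(relative_difference(0, 0), "undefined")
  expect_error(relative_difference(NA, 1), "present")
})

test_that("relative difference is symmetric and scale-invariant", {
  set.seed(11)
  a <- runif(200, 0, 500)
  b <- runif(200, 0.01, 500)
  expect_equal(relative_difference(a, b), relative_difference(b, a))
  for (c in c(0.001, 3, 1e6)) {
    expect_equal(relative_difference(a * c, b * c), relative_difference(a, b))
  }
})

test_that("alternative denominators are available but not the default", {
  expect_equal(relative_difference(100, 150, "max"), 1 / 3)
  expect_equal(relative_difference(100, 150, "reference"), 0.5)
  expect_error(relative_difference(0, 50, "reference"), "zero")
})

test_that("nutrients in one food are always long-listed; both-food nutrients need >20% difference", {
  p <- dplyr::bind_rows(
    nutrition_profile("vitamin_d", "food_a", concentration = 5),
    nutrition_profile("iron", "food_a", concentration = 100),
    nutrition_profile("iron", "food_b", concentration = 115),
    nutrition_profile("zinc", "food_a", concentration = 100),
    nutrition_profile("zinc", "food_b", concentration = 150)
  )
  ll <- build_long_list(p)
  expect_setequal(unique(ll$members$component_id), c("vitamin_d", "zinc"))
  # the computed difference is logged with the exclusion
  iron <- ll$ledger[ll$ledger$component_id == "iron", ]
  expect_true(all(iron$decision == "excluded"))
  expect_match(iron$reason, "0.1395")
})

test_that("all reported hazards are long-listed for each food where found", {
  p <- dplyr::bind_rows(
    micro_profile("salmonella", "food_a"),
    micro_profile("listeria", "food_b"),
    tox_profile("cadmium", "food_a")
  )
  ll <- build_long_list(p)
  expect_equal(nrow(ll$members), 3)
  expect_true(all(ll$ledger$decision == "included"))
})

test_that("the numeric rule applies only when both concentrations exist", {
  p <- dplyr::bind_rows(
    nutrition_profile("fiber", "food_a", concentration = NA),
    nutrition_profile("fiber", "food_b", concentration = 80)
  )
  ll <- build_long_list(p)
  expect_equal(nrow(ll$members), 2)
  expect_match(ll$ledger$reason, "qualitative", all = TRUE)
})

test_that("long-list assembly rejects duplicates and logs every submitted row", {
  p <- dplyr::bind_rows(nutrition_profile("iron", "food_a"),
                        nutrition_profile("iron", "food_a"))
  expect_error(build_long_list(p), "duplicate")

  set.seed(4)
  sim <- generate_profiles(synthetic_spec(seed = 4, n_nutrition = 12,
                                          n_microbiology = 5,
                                          n_toxicology = 5))
  ll <- build_long_list(sim$profiles)
  expect_equal(nrow(ll$ledger), nrow(sim$profiles))
  # output is exactly input minus the ledger-logged exclusions
  excl <- ll$ledger[ll$ledger$decision == "excluded", ]
  expect_setequal(run_key(ll$members),
                  setdiff(run_key(sim$profiles), run_key(excl)))
})

test_that("the evidence gate keeps convincing components only", {
  p <- dplyr::bind_rows(
    nutrition_profile("iron", "food_a", evidence_level = "convincing"),
    nutrition_profile("zinc", "food_a", evidence_level = "limited"),
    micro_profile("salmonella", "food_a", evidence_level = "contradictory")
  )
  eg <- evidence_gate(p)
  expect_equal(eg$members$component_id, "iron")
  excl <- eg$ledger[eg$ledger$decision == "excluded", ]
  expect_setequal(excl$reason,
                  c("evidence level: limited", "evidence level: contradictory"))
  expect_error(evidence_gate(nutrition_profile(evidence_level = NA)),
               "evidence_level")
})
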