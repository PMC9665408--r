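test_that("presence grading follows the <10% / all-samples bands", {
  expect_equal(presence_level(c(0.05, 0.5, 1)), c(1L, 2L, 3L))
  expect_equal(presence_level(0), 1L)
  expect_equal(presence_level(0.10), 2L) # 10% is no longer "not frequent"
  expect_equal(presence_level(0.999), 2L) # all samples means all
  expect_error(presence_level(NA), "required")
  expect_error(presence_level(1.2), "\\[0, 1\\]")
})

test_that("national-repository values override single-sample results", {
  expect_equal(resolve_detection_fraction(
    c(0.05, 0.9), c("national_repository", "single_sample")), 0.05)
  expect_equal(resolve_detection_fraction(
    c(0.05, 0.9), c("single_sample", "single_sample")), 0.9)
  expect_error(resolve_detection_fraction(NA_real_), "no detection")
})

test_that("processing and bioavailability maps point the agreed direction", {
  # more of the nutrient surviving processing means higher occurrence
  expect_equal(processing_level(c("eliminates", "reduces", "neutral",
                                  "introduces_or_increases")),
               c(1L, 2L, 3L, 3L))
  expect_error(processing_level("boiled"), "unknown processing")
  # a stronger bioavailability reduction lowers the severity weight
  expect_equal(bioavailability_level(c("significant", "moderate",
                                       "mild_or_none")), c(1L, 2L, 3L))
  expect_error(bioavailability_level("unknown"), "unknown bioavailability")
})

test_that("policy relevance grades FBDG and fortification scope", {
  expect_equal(policy_level("none", "none"), 1L)
  expect_equal(policy_level("all_countries", "none"), 3L)
  expect_equal(policy_level("some_countries", "all_countries"), 3L)
  expect_equal(policy_level("some_countries", "none"), 2L)
  expect_error(policy_level("everywhere", "none"), "fbdg_scope")
})

test_that("intake contribution uses layer 1 when present, layer 2 otherwise", {
  expect_equal(intake_level(0, NA), 1L)
  expect_equal(intake_level(0.6, NA), 2L)  # 0.6 <= 2/3 sits in the middle bin
  expect_equal(intake_level(0.7, NA), 3L)
  expect_equal(intake_level(NA, "large_difference"), 3L)
  expect_equal(intake_level(c(0.2, NA), c("small_difference", "moderate_difference")),
               c(1L, 2L))
  expect_error(intake_level(NA, NA), "neither")
})

test_that("the nutrition index is the product of five sub-criterion levels", {
  expect_equal(nutrition_index(c(3, 3), c(3, 3, 3))$index, 243L)
  expect_equal(nutrition_index(c(1, 1), c(1, 1, 1))$index, 1L)
  expect_equal(nutrition_index(c(2, 2), c(3, 3, 3))$index, 108L)
  expect_error(nutrition_index(c(2, 2, 2), c(3, 3, 3)), "occurrence")
  expect_error(nutrition_index(c(2, 4), c(3, 3, 3)), "levels")
})

test_that("exhaustive enumeration matches the closed-form product and is monotone", {
  grid <- expand.grid(a = 1:3, b = 1:3, c = 1:3, d = 1:3, e = 1:3)
  res <- nutrition_index(cbind(grid$a, grid$b), cbind(grid$c, grid$d, grid$e))
  expect_equal(res$index, grid$a * grid$b * grid$c * grid$d * grid$e)
  expect_true(all(res$index >= 1 & res$index <= 243))
  expect_equal(res$occurrence_score * res$severity_score, res$index)
  # strictly increasing in every sub-score holding the others fixed
  for (col in names(grid)) {
    lower <- grid[grid[[col]] < 3, ]
    raised <- lower
    raised[[col]] <- raised[[col]] + 1
    il <- nutrition_index(cbind(lower$a, lower$b),
                          cbind(lower$c, lower$d, lower$e))$index
    ir <- nutrition_index(cbind(raised$a, raised$b),
                          cbind(raised$c, raised$d, raised$e))$index
    expect_true(all(ir > il))
  }
})

test_that("occurrence carries 2 of 5 sub-criteria and severity 3 of 5", {
  s <- score_components(nutrition_profile())
  counts <- table(s$sub_scores[[1]]$criterion)
  expect_equal(unname(counts[["occurrence"]]), 2)
  expect_equal(unname(counts[["severity"]]), 3)
})
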