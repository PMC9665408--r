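test_that("the generator is deterministic under a fixed seed", {
  s <- synthetic_spec(seed = 123, n_nutrition = 10, n_microbiology = 5,
                      n_toxicology = 5)
  a <- generate_profiles(s)
  b <- generate_profiles(s)
  expect_identical(a$profiles, b$profiles)
  expect_identical(a$checklist, b$checklist)
  expect_identical(a$truth, b$truth)
  c <- generate_profiles(synthetic_spec(seed = 124, n_nutrition = 10,
                                        n_microbiology = 5, n_toxicology = 5))
  expect_false(identical(a$profiles, c$profiles))
})

test_that("degenerate level distributions force the index extremes", {
  top <- list(presence = c(0, 0, 1), processing = c(0, 0, 1),
              policy = c(0, 0, 1), intake = c(0, 0, 1),
              bioavailability = c(0, 0, 1))
  haz_top <- list(prevalence = c(0, 0, 1), process = c(0, 0, 1),
                  severity = c(0, 0, 1))
  tox_top <- list(presence = c(0, 0, 1), exposure = c(0, 0, 1),
                  severity = c(0, 0, 1))
  sim <- generate_profiles(synthetic_spec(
    seed = 5, n_nutrition = 8, n_microbiology = 6, n_toxicology = 6,
    nutrition_probs = top, micro_probs = haz_top, tox_probs = tox_top,
    evidence_probs = c(1, 0, 0), p_below_threshold = 0))
  scores <- score_components(evidence_gate(
    build_long_list(sim$profiles)$members)$members)
  expect_true(all(scores$index[scores$domain == "nutrition"] == 243))
  expect_true(all(scores$index[scores$domain != "nutrition"] == 9))

  bottom <- lapply(top, rev)
  sim <- generate_profiles(synthetic_spec(
    seed = 5, n_nutrition = 8, n_microbiology = 6, n_toxicology = 6,
    nutrition_probs = bottom, micro_probs = lapply(haz_top, rev),
    tox_probs = lapply(tox_top, rev),
    evidence_probs = c(1, 0, 0), p_below_threshold = 0))
  scores <- score_components(evidence_gate(
    build_long_list(sim$profiles)$members)$members)
  expect_true(all(scores$index == 1))
  expect_equal(nrow(apply_shortlist_threshold(scores)$members), 0)
})

test_that("invalid specs are rejected", {
  expect_error(synthetic_spec(nutrition_probs = list(presence = c(0.5, 0.5))),
               "sum to 1")
  expect_error(synthetic_spec(evidence_probs = c(0.9, 0.2, 0.1)), "sum to 1")
  expect_error(synthetic_spec(p_single_food = 1.4), "\\[0, 1\\]")
})

test_that("engine indices and stage decisions match the independent oracle", {
  for (seed in c(21, 22)) {
    sim <- generate_profiles(synthetic_spec(seed = seed, n_nutrition = 60,
                                            n_microbiology = 20,
                                            n_toxicology = 20))
    run <- rba_run(sim$profiles, sim$checklist)
    t <- sim$truth$rows
    expect_setequal(run_key(run$long_list), run_key(t[t$in_longlist, ]))
    expect_setequal(run_key(run$evidence_gated), run_key(t[t$in_evidence, ]))
    s <- dplyr::arrange(run$scores, component_id, food_id)
    tt <- dplyr::arrange(t[t$in_evidence, ], component_id, food_id)
    expect_equal(s$occurrence_score, tt$occurrence_score)
    expect_equal(s$severity_score, tt$severity_score)
    expect_equal(s$index, tt$index)
    expect_setequal(run_key(run$short_list), run_key(t[t$in_shortlist, ]))
    expect_setequal(run_key(run$final_list), run_key(sim$truth$final))
  }
})

test_that("the closed-form index distribution is a true probability mass", {
  probs <- list(presence = c(0.2, 0.5, 0.3), processing = c(0.1, 0.4, 0.5),
                policy = c(0.3, 0.3, 0.4), intake = c(0.25, 0.5, 0.25),
                bioavailability = c(0.2, 0.2, 0.6))
  d <- index_distribution("nutrition", probs)
  expect_equal(sum(d$prob), 1)
  expect_true(all(d$index %in% unique(
    apply(expand.grid(1:3, 1:3, 1:3, 1:3, 1:3), 1, prod))))
  dm <- index_distribution("microbiology",
                           list(prevalence = rep(1 / 3, 3),
                                process = rep(1 / 3, 3),
                                severity = rep(1 / 3, 3)))
  expect_equal(sum(dm$prob), 1)
  expect_true(all(dm$index >= 1 & dm$index <= 9))
})
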