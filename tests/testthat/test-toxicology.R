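test_that("presence scoring follows the LOD/LOQ and reference-dose rules", {
  expect_equal(tox_presence_level(FALSE), 1L)
  expect_equal(tox_presence_level(TRUE, FALSE, exceeds_hbgv = TRUE), 3L)
  expect_equal(tox_presence_level(TRUE, FALSE, exceeds_hbgv = FALSE), 2L)
  expect_equal(tox_presence_level(TRUE, TRUE, moe_below_10000 = TRUE), 3L)
  expect_equal(tox_presence_level(TRUE, TRUE, moe_below_10000 = FALSE), 2L)
  expect_error(tox_presence_level(TRUE, TRUE, moe_below_10000 = NA),
               "moe_below_10000")
  expect_error(tox_presence_level(TRUE, FALSE, exceeds_hbgv = NA),
               "exceeds_hbgv")
})

test_that("strengthening an exceedance condition never lowers the presence score", {
  expect_lte(tox_presence_level(FALSE),
             tox_presence_level(TRUE, TRUE, moe_below_10000 = FALSE))
  expect_lte(tox_presence_level(TRUE, TRUE, moe_below_10000 = FALSE),
             tox_presence_level(TRUE, TRUE, moe_below_10000 = TRUE))
  expect_lte(tox_presence_level(TRUE, FALSE, exceeds_hbgv = FALSE),
             tox_presence_level(TRUE, FALSE, exceeds_hbgv = TRUE))
})

test_that("exposure share bins at 10% and 50% with both edges in the middle band", {
  expect_equal(tox_exposure_level(c(0.05, 0.30, 0.60)), c(1L, 2L, 3L))
  expect_equal(tox_exposure_level(0.10), 2L)
  expect_equal(tox_exposure_level(0.50), 2L)
  expect_error(tox_exposure_level(1.2), "\\[0, 1\\]")
})

test_that("the occurrence combiner defaults to ceiling-of-mean", {
  expect_equal(tox_occurrence(3, 3), 3L)
  expect_equal(tox_occurrence(1, 1), 1L)
  expect_equal(tox_occurrence(3, 2), 3L) # ceil(2.5)
  expect_equal(tox_occurrence(3, 1), 2L)
  expect_equal(tox_occurrence(3, 1, combiner = "min"), 1L)
  expect_equal(tox_occurrence(2, 1, combiner = "max"), 2L)
})

test_that("severity maps the count of true statements to 1-3", {
  expect_equal(tox_severity(FALSE, FALSE, FALSE, FALSE), 1L)
  expect_equal(tox_severity(TRUE, FALSE, FALSE, FALSE), 1L)
  expect_equal(tox_severity(TRUE, TRUE, FALSE, FALSE), 2L)
  expect_equal(tox_severity(TRUE, TRUE, TRUE, FALSE), 3L)
  expect_equal(tox_severity(TRUE, TRUE, TRUE, TRUE), 3L)
  expect_error(tox_severity(TRUE, NA, TRUE, TRUE), "severity statements")
})

test_that("the chemical index stays in 1-9 over all admissible flag combinations", {
  presence_cases <- list(
    list(above = FALSE, geno = NA, hbgv = NA, moe = NA),
    list(above = TRUE, geno = FALSE, hbgv = FALSE, moe = NA),
    list(above = TRUE, geno = FALSE, hbgv = TRUE, moe = NA),
    list(above = TRUE, geno = TRUE, hbgv = NA, moe = FALSE),
    list(above = TRUE, geno = TRUE, hbgv = NA, moe = TRUE)
  )
  shares <- c(0.05, 0.10, 0.30, 0.50, 0.80)
  statement_grid <- expand.grid(a = c(TRUE, FALSE), b = c(TRUE, FALSE),
                                c = c(TRUE, FALSE), d = c(TRUE, FALSE))
  for (pc in presence_cases) {
    p <- tox_presence_level(pc$above, pc$geno, pc$hbgv, pc$moe)
    for (x in shares) {
      occ <- tox_occurrence(p, tox_exposure_level(x))
      sev <- tox_severity(statement_grid$a, statement_grid$b,
                          statement_grid$c, statement_grid$d)
      idx <- tox_index(rep(occ, nrow(statement_grid)), sev)
      expect_true(all(idx$index >= 1 & idx$index <= 9))
      expect_equal(idx$index, idx$occurrence_score * idx$severity_score)
    }
  }
  expect_equal(tox_index(3, 3)$index, 9L)
  expect_equal(tox_index(2, 2)$index, 4L)
  expect_equal(tox_index(1, 3)$index, 3L)
})
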