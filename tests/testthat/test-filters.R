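test_that("the 6-row fixture tallies as computed by hand", {
  catalog <- test_catalog()
  design <- test_design()
  resp <- make_fixture6(catalog, design)
  out <- apply_inclusion(resp, catalog, design, invited = 10L)

  expect_identical(nrow(out$benefit_cohort), 3L)  # part_harms, ok1, ok2
  expect_identical(nrow(out$harm_cohort), 3L)     # part_benefits, ok1, ok2
  expect_setequal(out$benefit_cohort$respondent_id,
                  c("part_harms", "ok1", "ok2"))
  expect_setequal(out$harm_cohort$respondent_id,
                  c("part_benefits", "ok1", "ok2"))

  fl <- out$flow
  expect_identical(fl$invited, 10L)
  expect_identical(fl$responded, 6L)
  expect_identical(fl$excluded_non_tmj, 1L)
  expect_identical(fl$excluded_missing_demographics, 1L)
  expect_identical(fl$analyzable_base, 4L)
  expect_identical(fl$excluded_incomplete_benefits, 1L)
  expect_identical(fl$benefit_analysis_n, 3L)
  expect_identical(fl$excluded_incomplete_harms, 1L)
  expect_identical(fl$harm_analysis_n, 3L)
  expect_identical(fl$included_final, 4L)  # union of the two cohorts
})

test_that("cohort members satisfy every inclusion criterion", {
  catalog <- test_catalog()
  design <- test_design()
  model <- preference_model(
    flat_utilities(),
    missingness = list(p_missing_demographics = 0.1,
                       p_incomplete_benefits = 0.2,
                       p_incomplete_harms = 0.2, p_non_tmj = 0.05))
  resp <- simulate_survey(model, catalog, design, 500L, seed = 8)
  out <- apply_inclusion(resp, catalog, design)
  for (cohort in list(out$benefit_cohort, out$harm_cohort)) {
    expect_true(all(cohort$has_tmj_condition))
    expect_false(anyNA(cohort$birth_year))
    expect_false(anyNA(cohort$gender))
    expect_false(anyNA(cohort$ppi))
  }
  expect_true(all(benefits_complete(out$benefit_cohort, catalog)))
  expect_true(all(harms_complete(out$harm_cohort, design)))
})

test_that("flow arithmetic holds on simulated tables and edge cases", {
  catalog <- test_catalog()
  design <- test_design()
  model <- preference_model(
    flat_utilities(),
    missingness = list(p_missing_demographics = 0.05,
                       p_incomplete_benefits = 0.14,
                       p_incomplete_harms = 0.16, p_non_tmj = 0))
  resp <- simulate_survey(model, catalog, design, 746L, seed = 3)
  fl <- apply_inclusion(resp, catalog, design, invited = 4130L)$flow
  expect_identical(fl$analyzable_base,
                   fl$responded - fl$excluded_non_tmj -
                     fl$excluded_missing_demographics)
  expect_identical(fl$benefit_analysis_n,
                   fl$analyzable_base - fl$excluded_incomplete_benefits)
  expect_identical(fl$harm_analysis_n,
                   fl$analyzable_base - fl$excluded_incomplete_harms)
  expect_lte(fl$included_final, fl$analyzable_base)
  expect_gte(fl$included_final,
             max(fl$benefit_analysis_n, fl$harm_analysis_n))

  # all-complete: no exclusions at all
  complete <- simulate_survey(
    preference_model(flat_utilities(), missingness = zero_missing()),
    catalog, design, 100L, seed = 2)
  fl2 <- apply_inclusion(complete, catalog, design)$flow
  expect_identical(fl2$benefit_analysis_n, 100L)
  expect_identical(fl2$harm_analysis_n, 100L)
  expect_identical(fl2$included_final, 100L)

  # empty table: all counts zero
  empty <- complete[0, , drop = FALSE]
  fl3 <- apply_inclusion(empty, catalog, design, invited = 0L)$flow
  expect_true(all(unlist(fl3) == 0L))

  expect_error(apply_inclusion(complete, catalog, design, invited = 5L),
               "less than responded")
})

test_that("cohorts are invariant to input row order", {
  catalog <- test_catalog()
  design <- test_design()
  resp <- make_fixture6(catalog, design)
  shuffled <- resp[c(4, 1, 6, 2, 5, 3), , drop = FALSE]
  a <- apply_inclusion(resp, catalog, design, invited = 6L)
  b <- apply_inclusion(shuffled, catalog, design, invited = 6L)
  expect_identical(unclass(a$flow), unclass(b$flow))
  expect_setequal(a$benefit_cohort$respondent_id,
                  b$benefit_cohort$respondent_id)
  expect_setequal(a$harm_cohort$respondent_id,
                  b$harm_cohort$respondent_id)
})
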