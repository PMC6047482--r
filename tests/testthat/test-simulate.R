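test_that("sample_ranking is a bijection and handles edge cases", {
  expect_identical(sample_ranking(c(solo = 1.5)), c(solo = 1L))
  expect_error(sample_ranking(numeric(0)), "at least one")
  expect_error(sample_ranking(c(a = Inf, b = 0)), "finite")
  set.seed(1)
  r <- sample_ranking(c(a = 0, b = 1, c = -1, d = 2))
  expect_setequal(r, 1:4)
  expect_named(r, c("a", "b", "c", "d"))
})

test_that("equal utilities give uniform rankings over permutations", {
  set.seed(20)
  n <- 60000L
  ranks <- bwsrank:::pl_rank_matrix(c(a = 0, b = 0, c = 0), n)
  key <- paste(ranks[, 1], ranks[, 2], ranks[, 3])
  counts <- table(key)
  expect_length(counts, 6L)
  chisq <- sum((counts - n / 6)^2 / (n / 6))
  # 5 df; 20.5 is the 0.999 quantile
  expect_lt(chisq, 20.5)
})

test_that("a dominant utility is ranked first almost surely", {
  # P(first) = e^10 / (e^10 + 2) > 0.99990 analytically
  set.seed(21)
  ranks <- bwsrank:::pl_rank_matrix(c(big = 10, s1 = 0, s2 = 0), 20000L)
  expect_gte(mean(ranks[, "big"] == 1L), 0.999)
})

test_that("simulate_survey produces valid, seeded tables", {
  catalog <- test_catalog()
  design <- test_design()
  model <- preference_model(flat_utilities(), missingness = zero_missing())

  expect_identical(nrow(simulate_survey(model, catalog, design, 0L, 1)), 0L)

  resp <- simulate_survey(model, catalog, design, 200L, seed = 5)
  expect_s3_class(resp, "response_table")
  expect_identical(nrow(resp), 200L)
  # zero missingness: every record complete on both tasks
  expect_true(all(benefits_complete(resp, catalog)))
  expect_true(all(harms_complete(resp, design)))
  expect_true(all(resp$harm_set_id == assign_set(resp$birth_month, 12L)))

  resp2 <- simulate_survey(model, catalog, design, 200L, seed = 5)
  expect_identical(resp, resp2)
  resp3 <- simulate_survey(model, catalog, design, 200L, seed = 6)
  expect_false(identical(resp, resp3))
})

test_that("missingness channels censor at their nominal rates", {
  catalog <- test_catalog()
  design <- test_design()
  n <- 4000L
  model <- preference_model(
    flat_utilities(),
    missingness = list(p_missing_demographics = 0.05,
                       p_incomplete_benefits = 0.10,
                       p_incomplete_harms = 0.15, p_non_tmj = 0.02))
  resp <- simulate_survey(model, catalog, design, n, seed = 11)
  frac_harm_incomplete <- mean(!harms_complete(resp, design))
  # binomial 99.9% band around 0.15
  se <- sqrt(0.15 * 0.85 / n)
  expect_lt(abs(frac_harm_incomplete - 0.15), 3.3 * se)
  frac_ben_incomplete <- mean(!benefits_complete(resp, catalog))
  expect_lt(abs(frac_ben_incomplete - 0.10), 3.3 * sqrt(0.1 * 0.9 / n))
  expect_lt(abs(mean(!resp$has_tmj_condition) - 0.02),
            3.3 * sqrt(0.02 * 0.98 / n))
})

test_that("simulate_survey rejects inconsistent inputs", {
  catalog <- test_catalog()
  bogus <- as_block_design(list(c("not_a_harm", LETTERS[1:6])))
  model <- preference_model(flat_utilities())
  expect_error(simulate_survey(model, catalog, bogus, 5L, 1),
               "absent from the catalog")
  small <- preference_model(c(pain_relief = 0))
  expect_error(simulate_survey(small, catalog, test_design(), 5L, 1),
               "lacks utilities")
  expect_error(simulate_survey(model, catalog, test_design(), -1L, 1),
               "nonnegative")
})

test_that("raising an item's utility raises its rank-1 frequency", {
  items <- c(a = 0, b = 0, c = 0, d = 0, e = 0)
  freqs <- vapply(c(0, 0.5, 1.5, 3), function(bonus) {
    u <- items; u["c"] <- bonus
    set.seed(33)
    ranks <- bwsrank:::pl_rank_matrix(u, 5000L)
    mean(ranks[, "c"] == 1L)
  }, numeric(1))
  expect_true(all(diff(freqs) >= 0))
})

test_that("model configs read from YAML and validate", {
  p <- system.file("extdata", "model_example.yaml", package = "bwsrank")
  model <- read_model_config(p)
  expect_s3_class(model, "preference_model")
  expect_identical(unname(model$utilities["pain_relief"]), 3.7)
  expect_identical(model$missingness$p_non_tmj, 0)
  expect_error(preference_model(c(a = 1), missingness = list(p_non_tmj = 2)),
               "\\[0, 1\\]")
  expect_error(preference_model(c(1, 2)), "named")
  expect_error(
    preference_model(c(a = 1), demographics = list(
      tradeoff_probs = c(benefits = .5, harms = .2, equal = .1))),
    "summing to 1")
})
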