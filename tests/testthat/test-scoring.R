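benefit_cohort_from_ranks <- function(rank_rows, catalog, design) {
  rows <- do.call(rbind, lapply(seq_len(nrow(rank_rows)), function(i) {
    response_row(paste0("r", i), catalog, design, 1L, harm_ranks = 1:7,
                 benefit_ranks = rank_rows[i, ])
  }))
  validate_responses(rows, catalog)
}

test_that("summarize_benefits medians and IQRs are exact on fixtures", {
  catalog <- test_catalog()
  design <- test_design()
  items <- benefit_task_items(catalog)

  # degenerate: everyone ranks identically
  cohort <- benefit_cohort_from_ranks(
    matrix(rep(1:7, 4), nrow = 4, byrow = TRUE), catalog, design)
  s <- summarize_benefits(cohort, catalog)
  expect_identical(s$item_id, items)  # order 1..7 = catalog order here
  expect_equal(s$median_rank, 1:7)
  expect_equal(s$iqr, rep(0, 7))
  expect_equal(s$n, rep(4L, 7))

  # hand case: first item ranked 1, 1, 3 (others shifted accordingly)
  cohort2 <- benefit_cohort_from_ranks(rbind(
    c(1, 2, 3, 4, 5, 6, 7),
    c(1, 2, 3, 4, 5, 6, 7),
    c(3, 1, 2, 4, 5, 6, 7)), catalog, design)
  s2 <- summarize_benefits(cohort2, catalog)
  first <- s2[s2$item_id == items[1], ]
  expect_equal(first$median_rank, 1)
  # type-7 quartiles of (1,1,3): Q1 = 1, Q3 = 2
  expect_equal(first$iqr, 1)

  expect_error(summarize_benefits(cohort[0, ], catalog), "empty")
  expect_error(summarize_benefits(
    rbind(cohort, response_row("bad", catalog, design, 1L, 1:7,
                               benefit_ranks = c(1:6, NA))),
    catalog), "incomplete")
})

test_that("bws_set_scores matches hand tallies and the unanimity case", {
  catalog <- test_catalog()
  items <- LETTERS[1:7]
  mk <- function(rank_rows) {
    df <- as.data.frame(rank_rows)
    names(df) <- paste0("rank_", items)
    df
  }
  # unanimity: everyone ranks A best, G worst
  s <- bws_set_scores(mk(matrix(rep(1:7, 5), nrow = 5, byrow = TRUE)),
                      items, set_id = 1L)
  expect_equal(s$score[s$item_id == "A"], 1)
  expect_equal(s$score[s$item_id == "G"], -1)
  expect_equal(s$score[!s$item_id %in% c("A", "G")], rep(0, 5))

  # two respondents: (best A, worst G) and (best A, worst B)
  s2 <- bws_set_scores(mk(rbind(c(1, 2, 3, 4, 5, 6, 7),
                                c(1, 7, 2, 3, 4, 5, 6))),
                       items, set_id = 1L)
  expect_equal(s2$score[s2$item_id == "A"], 1)
  expect_equal(s2$score[s2$item_id == "B"], -0.5)
  expect_equal(s2$score[s2$item_id == "G"], -0.5)
  expect_equal(s2$score[s2$item_id %in% c("C", "D", "E", "F")], rep(0, 4))
  expect_equal(sum(s2$score), 0)

  expect_error(bws_set_scores(mk(matrix(1:7, 1))[0, ], items, 3L), "set 3")
})

test_that("bws_set_scores agrees with the brute-force oracle", {
  items <- LETTERS[1:7]
  set.seed(14)
  for (i in 1:10) {
    n <- sample(2:40, 1)
    rank_rows <- t(replicate(n, sample.int(7L)))
    df <- as.data.frame(rank_rows)
    names(df) <- paste0("rank_", items)
    got <- bws_set_scores(df, items)
    expect_equal(got$score, oracle_bws(rank_rows))
    expect_equal(sum(got$score), 0)          # zero-sum
    expect_true(all(abs(got$score) <= 1))    # range
  }
})

test_that("uniform rankings give scores near zero at large n", {
  items <- LETTERS[1:7]
  set.seed(15)
  n <- 20000L
  ranks <- bwsrank:::pl_rank_matrix(stats::setNames(rep(0, 7), items), n)
  df <- as.data.frame(ranks)
  names(df) <- paste0("rank_", items)
  got <- bws_set_scores(df, items)
  se <- sqrt((2 / 7) / n)  # var(best - worst indicator) = 2/7 under uniform
  expect_true(all(abs(got$score) < 3 * se))
})

test_that("bws_average averages per item and ranks deterministically", {
  design <- as_block_design(list(c("A", "B"), c("A", "C"), c("B", "C"),
                                 c("A", "B"), c("A", "C"), c("B", "C")))
  # A appears in 4 blocks; hand scores
  sc <- data.frame(
    set_id = c(1, 2, 4, 5, 1, 3, 4, 6, 2, 3, 5, 6),
    item_id = c("A", "A", "A", "A", "B", "B", "B", "B", "C", "C", "C", "C"),
    score = c(0.2, 0.4, 0.0, 0.2, -0.2, 0.1, 0.0, 0.1, -0.4, -0.1, -0.2, -0.1),
    n = 10)
  out <- bws_average(sc, design)
  expect_equal(out$averaged_score[out$item_id == "A"], 0.2)
  expect_identical(out$final_rank[out$item_id == "A"], 1L)
  expect_identical(out$item_id, c("A", "B", "C"))

  # all-zero scores: ranks by item id
  sc0 <- sc; sc0$score <- 0
  out0 <- bws_average(sc0, design)
  expect_identical(out0$item_id, c("A", "B", "C"))
  expect_identical(out0$final_rank, 1:3)

  expect_error(bws_average(sc[-1, ], design), "expected 4")
})

test_that("relabeling items permutes scoring outputs identically", {
  catalog <- test_catalog()
  design <- test_design()
  model <- preference_model(flat_utilities() +
                              stats::setNames(runif(28, 0, 2),
                                              names(flat_utilities())),
                            missingness = zero_missing())
  resp <- simulate_survey(model, catalog, design, 300L, seed = 77)
  out <- apply_inclusion(resp, catalog, design)
  bws <- bws_average(bws_all_sets(out$harm_cohort, design), design)

  # relabel: prefix every harm id consistently in catalog, design, responses
  relab <- function(x) ifelse(x %in% catalog_items(catalog, "harm"),
                              paste0("z_", x), x)
  cat2 <- catalog; cat2$item_id <- relab(cat2$item_id)
  class(cat2) <- class(catalog)
  des2 <- as_block_design(lapply(design$blocks, relab))
  resp2 <- resp
  names(resp2) <- ifelse(startsWith(names(resp), "rank_"),
                         paste0("rank_", relab(sub("^rank_", "", names(resp)))),
                         names(resp))
  out2 <- apply_inclusion(resp2, cat2, des2)
  bws2 <- bws_average(bws_all_sets(out2$harm_cohort, des2), des2)
  expect_identical(paste0("z_", bws$item_id), bws2$item_id)
  expect_equal(bws$averaged_score, bws2$averaged_score)
})

test_that("tally_tradeoff reproduces exact proportions", {
  catalog <- test_catalog()
  design <- test_design()
  mk <- function(answers) {
    rows <- do.call(rbind, lapply(seq_along(answers), function(i) {
      response_row(paste0("r", i), catalog, design, 1L, harm_ranks = 1:7,
                   tradeoff = answers[i])
    }))
    validate_responses(rows, catalog)
  }
  t1 <- tally_tradeoff(mk(rep("benefits", 5)))
  expect_equal(t1$proportion, c(1, 0, 0))

  t2 <- tally_tradeoff(mk(c(rep("benefits", 6), rep("harms", 3),
                            rep("equal", 1), NA)))
  expect_identical(t2$denominator, rep(10L, 3))
  expect_equal(t2$proportion, c(0.6, 0.3, 0.1))
  expect_equal(sum(t2$proportion), 1)

  expect_error(tally_tradeoff(mk(NA_character_)), "no answered")
})

test_that("group_balance summarizes each set and the cross-set range", {
  catalog <- test_catalog()
  design <- test_design()

  # one respondent per set
  rows <- do.call(rbind, lapply(1:12, function(b) {
    response_row(paste0("r", b), catalog, design, b, harm_ranks = 1:7)
  }))
  gb <- group_balance(validate_responses(rows, catalog), design)
  expect_identical(nrow(gb), 13L)
  expect_true(all(gb$n[1:12] == 1L))
  expect_identical(gb$set_id[13], "range")

  # empty cohort: 12 empty rows
  gb0 <- group_balance(rows[0, , drop = FALSE], design)
  expect_true(all(gb0$n[1:12] == 0L))
  expect_true(all(is.na(gb0$pct_female[1:12])))

  # homogeneous population: per-set % female within 5 points of global
  model <- preference_model(flat_utilities(), missingness = zero_missing())
  resp <- simulate_survey(model, catalog, design, 3600L, seed = 10)
  gb2 <- group_balance(resp, design)
  global <- 100 * mean(resp$gender == "female")
  expect_true(all(abs(gb2$pct_female[1:12] - global) < 5))
})
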