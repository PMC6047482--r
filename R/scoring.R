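#' Summarize the benefits ranking task
#'
#' Per-item median and interquartile range of the ranks assigned by a
#' cohort of respondents with complete 7-item rankings (the 6 benefits plus
#' the side-effects aggregate). Items are ordered by ascending median, ties
#' broken by ascending IQR then item id. Quartiles use linear interpolation
#' by default (`stats::quantile` type 7); the rule is configurable.
#'
#' @param cohort A `response_table` in which every row has a complete
#'   benefits ranking.
#' @param catalog An `outcome_catalog`.
#' @param qtype Quantile algorithm type passed to [stats::quantile()].
#' @return Data frame with columns `item_id`, `median_rank`, `iqr`, `n`,
#'   ordered best first.
#' @export
summarize_benefits <- function(cohort, catalog, qtype = 7) {
  items <- benefit_task_items(catalog)
  if (nrow(cohort) == 0L) {
    stop("cannot summarize an empty benefit cohort", call. = FALSE)
  }
  if (!all(benefits_complete(cohort, catalog))) {
    stop("benefit cohort contains incomplete rankings", call. = FALSE)
  }
  out <- do.call(rbind, lapply(items, function(it) {
    r <- cohort[[paste0("rank_", it)]]
    q <- stats::quantile(r, c(.25, .5, .75), type = qtype, names = FALSE)
    data.frame(item_id = it, median_rank = q[2L], iqr = q[3L] - q[1L],
               n = length(r), stringsAsFactors = FALSE)
  }))
  out <- out[order(out$median_rank, out$iqr, out$item_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Best-worst scores for one ranking set
#'
#' For each item of a 7-item set, the proportion of respondents who ranked
#' it 1 ("most affects your decision") minus the proportion who ranked it 7
#' ("least affects your decision"). Scores lie in `[-1, 1]` and sum to 0
#' over the set, since every complete ranking contributes exactly one best
#' and one worst.
#'
#' @param cohort_set A `response_table` whose rows all rank exactly this
#'   set, completely.
#' @param items Character vector: the set's item ids.
#' @param set_id Identifier used in error messages and the output.
#' @return Data frame with columns `set_id`, `item_id`, `score`, `n`.
#' @export
bws_set_scores <- function(cohort_set, items, set_id = NA_integer_) {
  n <- nrow(cohort_set)
  if (n == 0L) {
    stop("no complete rankings for set ", set_id, call. = FALSE)
  }
  k <- length(items)
  m <- as.matrix(cohort_set[, rank_cols(items), drop = FALSE])
  if (anyNA(m)) {
    stop("incomplete ranking passed to bws_set_scores (set ", set_id, ")",
         call. = FALSE)
  }
  best <- colSums(m == 1L)
  worst <- colSums(m == k)
  data.frame(set_id = set_id, item_id = items,
             score = (best - worst) / n, n = n,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Best-worst scores for every set of a design
#'
#' Splits a harm cohort by assigned set and applies [bws_set_scores()] to
#' each.
#'
#' @param cohort A `response_table` of complete harm rankings.
#' @param design A `block_design`.
#' @return Data frame with columns `set_id`, `item_id`, `score`, `n`
#'   (one row per item-in-set).
#' @export
bws_all_sets <- function(cohort, design) {
  do.call(rbind, lapply(seq_along(design$blocks), function(b) {
    sub <- cohort[!is.na(cohort$harm_set_id) & cohort$harm_set_id == b, ,
                  drop = FALSE]
    bws_set_scores(sub, design$blocks[[b]], set_id = b)
  }))
}

#' Average best-worst scores across sets and rank the items
#'
#' Each item's averaged score is the unweighted mean of its per-set scores
#' (one per block containing it, i.e. `replication` of them); the final
#' rank orders items by descending averaged score, ties broken by item id.
#' A mean weighted by per-set sample size is available but off by default.
#'
#' @param set_scores Data frame from [bws_all_sets()] (or rbound
#'   [bws_set_scores()] results).
#' @param design A `block_design`.
#' @param weighted If `TRUE`, weight each set's score by its `n`.
#' @return Data frame of class `bws_result`: `item_id`, `averaged_score`,
#'   `n_sets`, `final_rank`, ordered by `final_rank`.
#' @export
bws_average <- function(set_scores, design, weighted = FALSE) {
  items <- design$item_ids
  rows <- lapply(items, function(it) {
    sc <- set_scores[set_scores$item_id == it, , drop = FALSE]
    if (nrow(sc) != design$replication) {
      stop("item ", it, " has ", nrow(sc), " set scores; expected ",
           design$replication, call. = FALSE)
    }
    avg <- if (weighted) stats::weighted.mean(sc$score, sc$n)
           else mean(sc$score)
    data.frame(item_id = it, averaged_score = avg, n_sets = nrow(sc),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$averaged_score, out$item_id), , drop = FALSE]
  out$final_rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  class(out) <- c("bws_result", "data.frame")
  out
}

#' Tally the benefits-versus-harms trade-off question
#'
#' @param responses A `response_table` (rows with a missing answer are
#'   dropped from the denominator).
#' @return Data frame with one row per answer (`benefits`, `harms`,
#'   `equal`): `count`, `denominator`, `proportion`.
#' @export
tally_tradeoff <- function(responses) {
  ans <- responses$tradeoff[!is.na(responses$tradeoff)]
  if (length(ans) == 0L) {
    stop("no answered trade-off questions", call. = FALSE)
  }
  counts <- vapply(TRADEOFF_LEVELS, function(l) sum(ans == l), integer(1L))
  data.frame(answer = TRADEOFF_LEVELS, count = counts,
             denominator = length(ans),
             proportion = counts / length(ans),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Compare respondent characteristics across the ranking sets
#'
#' Descriptive check that the groups created by the birth-month split are
#' exchangeable: per set, the sample size, percent female, and median (IQR)
#' of age and present pain intensity; plus a row giving the range of each
#' statistic across sets. No hypothesis test is performed.
#'
#' @param cohort A `response_table` with demographics (typically the harm
#'   cohort).
#' @param design A `block_design`.
#' @param survey_year Year used to convert birth year to age.
#' @param qtype Quantile algorithm type.
#' @return Data frame, one row per set plus a final `range` row.
#' @export
group_balance <- function(cohort, design, survey_year = 2015, qtype = 7) {
  n_blocks <- length(design$blocks)
  rows <- lapply(seq_len(n_blocks), function(b) {
    sub <- cohort[!is.na(cohort$harm_set_id) & cohort$harm_set_id == b, ,
                  drop = FALSE]
    if (nrow(sub) == 0L) {
      return(data.frame(set_id = as.character(b), n = 0L,
                        pct_female = NA_real_, age_median = NA_real_,
                        age_iqr = NA_real_, ppi_median = NA_real_,
                        ppi_iqr = NA_real_, stringsAsFactors = FALSE))
    }
    age <- survey_year - sub$birth_year
    qa <- stats::quantile(age, c(.25, .5, .75), type = qtype,
                          na.rm = TRUE, names = FALSE)
    qp <- stats::quantile(sub$ppi, c(.25, .5, .75), type = qtype,
                          na.rm = TRUE, names = FALSE)
    data.frame(set_id = as.character(b), n = nrow(sub),
               pct_female = 100 * mean(sub$gender == "female", na.rm = TRUE),
               age_median = qa[2L], age_iqr = qa[3L] - qa[1L],
               ppi_median = qp[2L], ppi_iqr = qp[3L] - qp[1L],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  stat_cols <- setdiff(names(out), "set_id")
  rng <- out[0 < out$n, stat_cols, drop = FALSE]
  range_row <- data.frame(set_id = "range", stringsAsFactors = FALSE)
  for (cl in stat_cols) {
    range_row[[cl]] <- if (nrow(rng) == 0L) NA_real_
                       else diff(range(rng[[cl]], na.rm = TRUE))
  }
  rbind(out, range_row)
}
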