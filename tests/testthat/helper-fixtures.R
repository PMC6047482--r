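# Shared fixtures, built in code. Expensive objects (the full-scale design)
# are generated once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

test_catalog <- function() default_catalog()

# full-scale harm design, light search budget (balance quality is tested
# separately at the full budget in the acceptance suite)
test_design <- function() {
  cached("design2112", generate_design(
    21, 12, 7, seed = 1, item_ids = catalog_items(test_catalog(), "harm"),
    restarts = 1L, perturbations = 5L))
}

# tiny single-set design over items A..G, used for scoring unit tests
tiny_design <- function(items = LETTERS[1:7]) {
  as_block_design(list(items))
}

zero_missing <- function() {
  list(p_missing_demographics = 0, p_incomplete_benefits = 0,
       p_incomplete_harms = 0, p_non_tmj = 0)
}

flat_utilities <- function(catalog = test_catalog(), value = 0) {
  items <- c(benefit_task_items(catalog), catalog_items(catalog, "harm"))
  stats::setNames(rep(value, length(items)), items)
}

# one respondent row ranking the given harm set; ranks given in item order
response_row <- function(id, catalog, design, set_id, harm_ranks,
                         benefit_ranks = 1:7, birth_year = 1970L,
                         gender = "female", ppi = 4L, tmj = TRUE,
                         tradeoff = "benefits") {
  ben <- benefit_task_items(catalog)
  row <- data.frame(respondent_id = id, birth_year = birth_year,
                    birth_month = set_id, gender = gender,
                    has_tmj_condition = tmj, ppi = ppi,
                    comorbid_pain_count = 2L, current_med_count = 1L,
                    past_med_count = 3L, harm_set_id = set_id,
                    tradeoff = tradeoff, stringsAsFactors = FALSE)
  for (j in seq_along(ben)) {
    row[[paste0("rank_", ben[j])]] <- as.integer(benefit_ranks[j])
  }
  for (it in catalog_items(catalog, "harm")) {
    row[[paste0("rank_", it)]] <- NA_integer_
  }
  items <- design$blocks[[set_id]]
  for (j in seq_along(items)) {
    row[[paste0("rank_", items[j])]] <- as.integer(harm_ranks[j])
  }
  row
}

# independent brute-force BWS tally used as an oracle against bws_set_scores
oracle_bws <- function(rank_matrix) {
  n <- nrow(rank_matrix); k <- ncol(rank_matrix)
  sapply(seq_len(k), function(j) {
    best <- 0; worst <- 0
    for (i in seq_len(n)) {
      if (rank_matrix[i, j] == 1) best <- best + 1
      if (rank_matrix[i, j] == k) worst <- worst + 1
    }
    (best - worst) / n
  })
}

# six-row hand fixture: one non-TMJ, one missing PPI, one incomplete
# benefits, one incomplete harms, two fully complete
make_fixture6 <- function(catalog, design) {
  rows <- rbind(
    response_row("non_tmj", catalog, design, 1L, harm_ranks = 1:7,
                 tmj = FALSE),
    response_row("no_ppi", catalog, design, 2L, harm_ranks = 1:7,
                 ppi = NA_integer_),
    response_row("part_benefits", catalog, design, 3L, harm_ranks = 1:7,
                 benefit_ranks = c(1:6, NA)),
    response_row("part_harms", catalog, design, 4L,
                 harm_ranks = c(NA, 2:7)),
    response_row("ok1", catalog, design, 5L, harm_ranks = 7:1),
    response_row("ok2", catalog, design, 6L, harm_ranks = 1:7))
  validate_responses(rows, catalog)
}

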