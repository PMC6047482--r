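#' Define a latent-preference respondent model
#'
#' The generator draws each respondent's complete rankings from a
#' Plackett-Luce model: the item ranked 1 is chosen with probability
#' proportional to `exp(utility)` among the items on offer, the item ranked
#' 2 likewise among the remainder, and so on. Demographics are simulation
#' dressing (they never feed back into utilities); item nonresponse censors
#' complete records through four independent channels, mirroring the
#' exclusion categories a survey flow diagram tracks.
#'
#' @param utilities Named numeric vector of latent utilities (log-worths),
#'   one entry per catalog item used in either ranking task.
#' @param demographics List of generator settings. Recognised entries and
#'   defaults: `proportion_female` (0.92), `age_median` (52),
#'   `age_iqr` (8), `survey_year` (2015), `ppi_scale_max` (10),
#'   `ppi_median` (4), `ppi_iqr` (3), `comorbid_mean` (3),
#'   `current_med_mean` (3), `past_med_mean` (6),
#'   `tradeoff_probs` (c(benefits = .60, harms = .28, equal = .12)),
#'   `p_missing_tradeoff` (0.013).
#' @param missingness List of censoring probabilities, all in `[0, 1]`:
#'   `p_missing_demographics` (0.051), `p_incomplete_benefits` (0.143),
#'   `p_incomplete_harms` (0.155), `p_non_tmj` (0).
#' @return A `preference_model` object.
#' @export
preference_model <- function(utilities, demographics = list(),
                             missingness = list()) {
  if (is.null(names(utilities)) || any(names(utilities) == "")) {
    stop("utilities must be a fully named numeric vector", call. = FALSE)
  }
  if (!all(is.finite(utilities))) {
    stop("utilities must be finite", call. = FALSE)
  }
  dem <- utils::modifyList(default_demographics(), demographics)
  mis <- utils::modifyList(default_missingness(), missingness)
  probs <- unlist(mis)
  if (any(probs < 0 | probs > 1)) {
    stop("missingness probabilities must lie in [0, 1]", call. = FALSE)
  }
  tp <- dem$tradeoff_probs
  if (length(tp) != 3L || abs(sum(tp) - 1) > 1e-8) {
    stop("tradeoff_probs must be 3 probabilities summing to 1",
         call. = FALSE)
  }
  structure(list(utilities = utilities, demographics = dem,
                 missingness = mis),
            class = "preference_model")
}

default_demographics <- function() {
  list(
    proportion_female = 0.92,
    age_median = 52, age_iqr = 8, survey_year = 2015,
    ppi_scale_max = 10, ppi_median = 4, ppi_iqr = 3,
    comorbid_mean = 3, current_med_mean = 3, past_med_mean = 6,
    tradeoff_probs = c(benefits = 0.60, harms = 0.28, equal = 0.12),
    p_missing_tradeoff = 0.013
  )
}

default_missingness <- function() {
  # marginal rates chosen to emulate a ~746-response flow:
  # 38/746 missing demographics, 101/708 incomplete benefits,
  # 110/708 incomplete harms
  list(p_missing_demographics = 0.051,
       p_incomplete_benefits = 0.143,
       p_incomplete_harms = 0.155,
       p_non_tmj = 0)
}

#' A default preference model for the packaged catalog
#'
#' Graded utilities placing pain relief clearly first among the benefits
#' (at least 2.5 above every other item, enough to make its median rank 1)
#' and death, fainting and headache at the top of the harms, with the
#' remaining harms descending in catalog order.
#'
#' @param catalog An `outcome_catalog` (default: the packaged one).
#' @return A `preference_model`.
#' @export
default_model <- function(catalog = default_catalog()) {
  ben <- benefit_task_items(catalog)
  harms <- catalog_items(catalog, "harm")
  u_ben <- stats::setNames(numeric(length(ben)), ben)
  u_ben["pain_relief"] <- 3.7
  if ("normal_activities" %in% ben) u_ben["normal_activities"] <- 1.2
  if ("quality_of_life" %in% ben) u_ben["quality_of_life"] <- 1.0
  if ("sleep" %in% ben) u_ben["sleep"] <- 0.6
  if ("side_effects" %in% ben) u_ben["side_effects"] <- 0.5
  if ("mood" %in% ben) u_ben["mood"] <- 0.3
  u_harm <- stats::setNames(seq(3, 0, length.out = length(harms)), harms)
  preference_model(c(u_ben, u_harm))
}

#' Read a preference model from a YAML config
#'
#' Expects top-level blocks `utilities:`, `demographics:`, `missingness:`.
#'
#' @param path Path to a YAML file.
#' @return A `preference_model`.
#' @export
read_model_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$utilities)) {
    stop("model config must contain a utilities block", call. = FALSE)
  }
  preference_model(unlist(cfg$utilities),
                   demographics = if (is.null(cfg$demographics)) list() else cfg$demographics,
                   missingness = if (is.null(cfg$missingness)) list() else cfg$missingness)
}

#' Draw one complete ranking under the Plackett-Luce model
#'
#' Sequential choice: rank 1 goes to an item drawn with probability
#' proportional to `exp(utility)`, rank 2 likewise among the remaining
#' items, and so on. Implemented by the equivalent Gumbel-perturbation
#' representation: rank items by `utility + Gumbel(0, 1)` noise,
#' descending.
#'
#' @param utilities Named numeric vector over the items on offer.
#' @return Named integer vector of ranks (1 = most important), a bijection
#'   onto `1..length(utilities)`.
#' @export
sample_ranking <- function(utilities) {
  if (length(utilities) < 1L) {
    stop("sample_ranking needs at least one item", call. = FALSE)
  }
  if (!all(is.finite(utilities))) {
    stop("utilities must be finite", call. = FALSE)
  }
  drop(pl_rank_matrix(utilities, 1L))
}

# n complete PL rankings at once; rows = respondents, columns = items,
# entries = rank assigned (1 = chosen first). Gumbel-max: adding iid
# standard Gumbel noise to utilities and sorting descending draws from the
# Plackett-Luce distribution with worths exp(utility).
pl_rank_matrix <- function(utilities, n) {
  k <- length(utilities)
  g <- -log(-log(stats::runif(n * k)))
  scores <- matrix(rep(utilities, each = n) + g, nrow = n)
  ranks <- t(apply(scores, 1L, function(s) rank(-s, ties.method = "first")))
  if (k == 1L) ranks <- matrix(1L, nrow = n, ncol = 1L)
  colnames(ranks) <- names(utilities)
  ranks
}

# Integer draws with a target median/IQR: a rounded, clipped normal whose
# location is the median and whose sd is IQR/1.349.
draw_scale <- function(n, med, iqr, lo, hi) {
  x <- round(stats::rnorm(n, mean = med, sd = max(iqr, .5) / 1.349))
  as.integer(pmin(pmax(x, lo), hi))
}

#' Simulate a survey response table
#'
#' Each respondent receives a uniform birth month (hence a harm set via
#' [assign_set()]), demographics drawn from the model's settings, complete
#' benefit and harm rankings drawn from the Plackett-Luce model, and a
#' benefit-versus-harm trade-off answer. Censoring is then applied through
#' four independent channels: with `p_non_tmj` the respondent reports a
#' non-TMJ pain condition; with `p_missing_demographics` one of age, sex or
#' pain intensity is blanked; with `p_incomplete_benefits` (resp.
#' `p_incomplete_harms`) a nonempty random subset of that task's ranks is
#' blanked.
#'
#' @param model A `preference_model` covering every item in `catalog` that
#'   appears in a ranking task.
#' @param catalog An `outcome_catalog`.
#' @param design A `block_design` over the catalog's harm items.
#' @param n Number of respondents.
#' @param seed Integer seed; equal seeds give identical tables.
#' @return A `response_table` with `n` rows.
#' @export
simulate_survey <- function(model, catalog, design, n, seed) {
  stopifnot(inherits(model, "preference_model"),
            inherits(design, "block_design"))
  if (n < 0) stop("n must be nonnegative", call. = FALSE)
  harm_items <- catalog_items(catalog, "harm")
  if (!all(unlist(design$blocks) %in% harm_items)) {
    stop("design contains items absent from the catalog's harms",
         call. = FALSE)
  }
  ben_items <- benefit_task_items(catalog)
  need <- c(ben_items, unique(unlist(design$blocks)))
  missing_u <- setdiff(need, names(model$utilities))
  if (length(missing_u) > 0L) {
    stop("model lacks utilities for: ", paste(missing_u, collapse = ", "),
         call. = FALSE)
  }

  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(restore_seed(old_seed))
  set.seed(as.integer(seed))

  dem <- model$demographics
  mis <- model$missingness
  n_blocks <- length(design$blocks)

  df <- data.frame(
    respondent_id = sprintf("r%05d", seq_len(max(n, 0L))),
    stringsAsFactors = FALSE
  )[seq_len(n), , drop = FALSE]

  if (n == 0L) {
    df <- empty_response_table(catalog)
    return(validate_responses(df, catalog))
  }

  age <- draw_scale(n, dem$age_median, dem$age_iqr, 18L, 95L)
  df$birth_year <- as.integer(dem$survey_year - age)
  df$birth_month <- sample.int(12L, n, replace = TRUE)
  df$gender <- ifelse(stats::runif(n) < dem$proportion_female,
                      "female", "male")
  df$has_tmj_condition <- stats::runif(n) >= mis$p_non_tmj
  df$ppi <- draw_scale(n, dem$ppi_median, dem$ppi_iqr, 0L, dem$ppi_scale_max)
  df$comorbid_pain_count <- stats::rpois(n, dem$comorbid_mean)
  df$current_med_count <- stats::rpois(n, dem$current_med_mean)
  df$past_med_count <- stats::rpois(n, dem$past_med_mean)
  df$harm_set_id <- assign_set(df$birth_month, n_blocks)
  df$tradeoff <- sample(TRADEOFF_LEVELS, n, replace = TRUE,
                        prob = dem$tradeoff_probs)
  df$tradeoff[stats::runif(n) < dem$p_missing_tradeoff] <- NA

  # complete benefit rankings
  ben_ranks <- pl_rank_matrix(model$utilities[ben_items], n)
  for (j in seq_along(ben_items)) {
    df[[paste0("rank_", ben_items[j])]] <- as.integer(ben_ranks[, j])
  }
  # harm rankings, drawn per set
  for (it in harm_items) df[[paste0("rank_", it)]] <- NA_integer_
  for (b in seq_len(n_blocks)) {
    idx <- which(df$harm_set_id == b)
    if (length(idx) == 0L) next
    items_b <- design$blocks[[b]]
    hr <- pl_rank_matrix(model$utilities[items_b], length(idx))
    for (j in seq_along(items_b)) {
      df[idx, paste0("rank_", items_b[j])] <- as.integer(hr[, j])
    }
  }

  # censoring channels, independent per respondent
  blank_demog <- stats::runif(n) < mis$p_missing_demographics
  if (any(blank_demog)) {
    which_field <- sample(c("birth_year", "gender", "ppi"),
                          sum(blank_demog), replace = TRUE)
    for (f in c("birth_year", "gender", "ppi")) {
      rows <- which(blank_demog)[which_field == f]
      df[rows, f] <- NA
    }
  }
  df <- censor_ranks(df, which(stats::runif(n) < mis$p_incomplete_benefits),
                     function(i) ben_items)
  df <- censor_ranks(df, which(stats::runif(n) < mis$p_incomplete_harms),
                     function(i) design$blocks[[df$harm_set_id[i]]])

  validate_responses(df, catalog)
}

# Blank a random nonempty subset of the given rows' ranks for the items
# returned by items_for(row).
censor_ranks <- function(df, rows, items_for) {
  for (i in rows) {
    items <- items_for(i)
    k <- sample.int(length(items), 1L)
    drop_items <- items[sample.int(length(items), k)]
    df[i, paste0("rank_", drop_items)] <- NA_integer_
  }
  df
}

empty_response_table <- function(catalog) {
  cols <- c(DEMOGRAPHIC_COLS,
            rank_cols(c(benefit_task_items(catalog),
                        catalog_items(catalog, "harm"))))
  df <- as.data.frame(stats::setNames(
    rep(list(integer(0L)), length(cols)), cols))
  df$respondent_id <- character(0L)
  df$gender <- character(0L)
  df$tradeoff <- character(0L)
  df
}
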