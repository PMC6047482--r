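#' Apply the eligibility-filter cascade
#'
#' Filters are applied in a fixed order: (1) the respondent's pain
#' conditions include the target (TMJ) condition; (2) age, sex and present
#' pain intensity are all reported; (3) task-specific ranking completeness.
#' Criterion 3 is a disjunction: a respondent complete on only the benefits
#' task enters only the benefit cohort, and vice versa; the final included
#' count is the union of the two cohorts.
#'
#' @param responses A `response_table`.
#' @param catalog An `outcome_catalog`.
#' @param design A `block_design` (needed to judge harm-ranking
#'   completeness against each respondent's assigned set).
#' @param invited Number of people invited (flow denominator); must be at
#'   least `nrow(responses)`.
#' @return A list with `benefit_cohort`, `harm_cohort` (both
#'   `response_table`s) and `flow` (a `flow_counts` object).
#' @export
apply_inclusion <- function(responses, catalog, design,
                            invited = nrow(responses)) {
  n <- nrow(responses)
  if (invited < n) {
    stop("invited (", invited, ") is less than responded (", n, ")",
         call. = FALSE)
  }
  tmj_ok <- !is.na(responses$has_tmj_condition) & responses$has_tmj_condition
  demog_ok <- !is.na(responses$birth_year) & !is.na(responses$gender) &
    !is.na(responses$ppi)
  base_ok <- tmj_ok & demog_ok
  ben_ok <- benefits_complete(responses, catalog)
  harm_ok <- harms_complete(responses, design)

  benefit_cohort <- responses[base_ok & ben_ok, , drop = FALSE]
  harm_cohort <- responses[base_ok & harm_ok, , drop = FALSE]

  flow <- flow_counts(
    invited = as.integer(invited),
    responded = n,
    excluded_non_tmj = sum(!tmj_ok),
    excluded_missing_demographics = sum(tmj_ok & !demog_ok),
    analyzable_base = sum(base_ok),
    excluded_incomplete_benefits = sum(base_ok & !ben_ok),
    benefit_analysis_n = sum(base_ok & ben_ok),
    excluded_incomplete_harms = sum(base_ok & !harm_ok),
    harm_analysis_n = sum(base_ok & harm_ok),
    included_final = sum(base_ok & (ben_ok | harm_ok))
  )
  list(benefit_cohort = benefit_cohort, harm_cohort = harm_cohort,
       flow = flow)
}

#' Participant-flow counts
#'
#' Constructor validating the arithmetic identities of the filter cascade:
#' the analyzable base is what remains after the condition and demographics
#' exclusions, each cohort is the base minus its task-specific exclusion,
#' and the final included count (the cohort union) is at most the base and
#' at least each cohort.
#'
#' @param invited,responded,excluded_non_tmj,excluded_missing_demographics
#'   Stage counts.
#' @param analyzable_base,excluded_incomplete_benefits,benefit_analysis_n
#'   Stage counts.
#' @param excluded_incomplete_harms,harm_analysis_n,included_final
#'   Stage counts.
#' @return A `flow_counts` object (named integer list).
#' @export
flow_counts <- function(invited, responded, excluded_non_tmj,
                        excluded_missing_demographics, analyzable_base,
                        excluded_incomplete_benefits, benefit_analysis_n,
                        excluded_incomplete_harms, harm_analysis_n,
                        included_final) {
  x <- lapply(list(
    invited = invited, responded = responded,
    excluded_non_tmj = excluded_non_tmj,
    excluded_missing_demographics = excluded_missing_demographics,
    analyzable_base = analyzable_base,
    excluded_incomplete_benefits = excluded_incomplete_benefits,
    benefit_analysis_n = benefit_analysis_n,
    excluded_incomplete_harms = excluded_incomplete_harms,
    harm_analysis_n = harm_analysis_n,
    included_final = included_final), as.integer)
  stopifnot(
    x$responded <= x$invited,
    x$analyzable_base ==
      x$responded - x$excluded_non_tmj - x$excluded_missing_demographics,
    x$benefit_analysis_n ==
      x$analyzable_base - x$excluded_incomplete_benefits,
    x$harm_analysis_n ==
      x$analyzable_base - x$excluded_incomplete_harms,
    x$included_final <= x$analyzable_base,
    x$included_final >= max(x$benefit_analysis_n, x$harm_analysis_n)
  )
  structure(x, class = "flow_counts")
}

#' @export
print.flow_counts <- function(x, ...) {
  cat("participant flow:\n")
  for (nm in names(x)) cat(sprintf("  %-32s %d\n", nm, x[[nm]]))
  invisible(x)
}

#' Flow counts as a two-column table
#'
#' @param flow A `flow_counts` object.
#' @return Data frame with columns `stage`, `count`, suitable for
#'   [write_table()].
#' @export
flow_table <- function(flow) {
  data.frame(stage = names(flow), count = unlist(flow, use.names = FALSE),
             stringsAsFactors = FALSE)
}
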