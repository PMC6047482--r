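#' Kendall rank correlation between two item orderings
#'
#' `1 - 2 * D / choose(m, 2)` where `D` counts discordant pairs between two
#' tie-free orderings of the same `m` items.
#'
#' @param order_a,order_b Character vectors: the items, best first. Must be
#'   permutations of the same item set.
#' @return A value in `[-1, 1]`; 1 means identical orderings.
#' @export
kendall_tau <- function(order_a, order_b) {
  if (!setequal(order_a, order_b) ||
      anyDuplicated(order_a) || anyDuplicated(order_b) ||
      length(order_a) != length(order_b)) {
    stop("order_a and order_b must be permutations of the same item set",
         call. = FALSE)
  }
  m <- length(order_a)
  if (m < 2L) return(1)
  pos_b <- match(order_a, order_b)
  disc <- 0L
  for (i in seq_len(m - 1L)) {
    disc <- disc + sum(pos_b[(i + 1L):m] < pos_b[i])
  }
  1 - 2 * disc / choose(m, 2L)
}

#' True preference ordering of a model over a design's items
#'
#' Descending latent utility, ties broken by item id -- the same tie-break
#' the scorer uses, so perfect recovery corresponds to tau = 1.
#'
#' @param model A `preference_model`.
#' @param design A `block_design`.
#' @return Character vector of item ids, best first.
#' @export
true_ordering <- function(model, design) {
  u <- model$utilities[design$item_ids]
  design$item_ids[order(-u, design$item_ids)]
}

#' Parameter-recovery experiment for the best-worst scaling pipeline
#'
#' For each sample size and replicate: simulate a survey, apply the
#' inclusion cascade, score harms by best-worst scaling, and compare the
#' recovered ordering of the design's items with the model's true utility
#' ordering by Kendall tau. Fully seeded: replicate j at sample size n uses
#' a sub-seed derived deterministically from `seed`.
#'
#' @param model A `preference_model` covering all design items.
#' @param catalog An `outcome_catalog`.
#' @param design A `block_design`.
#' @param ns Integer vector of respondent counts.
#' @param reps Replicates per sample size.
#' @param seed Integer master seed.
#' @return A list of class `recovery_report`: `runs` (data frame with `n`,
#'   `replicate`, `kendall_tau`, `top_item_correct`) and `summary` (per-`n`
#'   mean tau and fraction of replicates with tau exactly 1).
#' @export
recovery_experiment <- function(model, catalog, design, ns, reps, seed) {
  truth <- true_ordering(model, design)
  runs <- vector("list", length(ns) * reps)
  k <- 0L
  for (ni in seq_along(ns)) {
    n <- ns[ni]
    for (j in seq_len(reps)) {
      k <- k + 1L
      sub_seed <- (as.integer(seed) + 7919L * ni + 104729L * j) %% 2147483647L
      recovered <- tryCatch({
        resp <- simulate_survey(model, catalog, design, n, seed = sub_seed)
        filt <- apply_inclusion(resp, catalog, design)
        scores <- bws_all_sets(filt$harm_cohort, design)
        bws_average(scores, design)$item_id
      }, error = function(e) {
        stop("recovery replicate failed (n = ", n, ", replicate = ", j,
             "): ", conditionMessage(e), call. = FALSE)
      })
      runs[[k]] <- data.frame(n = n, replicate = j,
                              kendall_tau = kendall_tau(recovered, truth),
                              top_item_correct = recovered[1L] == truth[1L])
    }
  }
  runs <- do.call(rbind, runs)
  summary <- do.call(rbind, lapply(unique(runs$n), function(n) {
    sub <- runs[runs$n == n, , drop = FALSE]
    data.frame(n = n, mean_tau = mean(sub$kendall_tau),
               frac_perfect = mean(sub$kendall_tau == 1),
               reps = nrow(sub))
  }))
  structure(list(runs = runs, summary = summary, seed = as.integer(seed)),
            class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat("recovery experiment (seed", x$seed, "):\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}
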