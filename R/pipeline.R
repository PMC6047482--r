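#' Assemble a pipeline configuration
#'
#' @param out_dir Output directory (created if absent).
#' @param seed Integer seed recorded in every output's provenance header.
#' @param mode `"simulate"` (generate responses from the model) or
#'   `"ingest"` (read them from `responses`).
#' @param catalog Path to a catalog CSV, or `NULL` for the packaged one.
#' @param design Path to a design CSV, or `NULL` to generate one.
#' @param responses Path to a response CSV (ingest mode).
#' @param n_items,n_blocks,block_size Design parameters used when
#'   generating.
#' @param n Respondent count in simulate mode.
#' @param invited Invitation count (flow denominator); defaults to the
#'   number of responses.
#' @param qtype Quantile rule for medians/IQRs.
#' @param model A `preference_model`, a path to a YAML model config, or
#'   `NULL` for [default_model()].
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(out_dir, seed = 1L, mode = c("simulate", "ingest"),
                            catalog = NULL, design = NULL, responses = NULL,
                            n_items = 21L, n_blocks = 12L, block_size = 7L,
                            n = 746L, invited = NULL, qtype = 7,
                            model = NULL) {
  mode <- match.arg(mode)
  if (mode == "ingest" && is.null(responses)) {
    stop("ingest mode needs a responses path", call. = FALSE)
  }
  structure(list(out_dir = out_dir, seed = as.integer(seed), mode = mode,
                 catalog = catalog, design = design, responses = responses,
                 n_items = n_items, n_blocks = n_blocks,
                 block_size = block_size, n = n, invited = invited,
                 qtype = qtype, model = model),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys mirror the arguments of [pipeline_config()]; an optional
#' `model:` block holds `utilities`, `demographics` and `missingness`.
#' Because a bare `n` is a YAML 1.1 boolean, the respondent count is
#' spelled `n_respondents:` (a quoted `"n"` also works).
#'
#' @param path YAML file path.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  model <- NULL
  if (!is.null(cfg$model)) {
    model <- preference_model(
      unlist(cfg$model$utilities),
      demographics = if (is.null(cfg$model$demographics)) list()
                     else cfg$model$demographics,
      missingness = if (is.null(cfg$model$missingness)) list()
                    else cfg$model$missingness)
  }
  if (!is.null(cfg$n_respondents)) cfg$n <- cfg$n_respondents
  if ("FALSE" %in% names(cfg)) {  # a bare `n:` key parses as boolean FALSE
    cfg$n <- cfg[["FALSE"]]
  }
  args <- cfg[intersect(names(cfg), names(formals(pipeline_config)))]
  args$model <- model
  do.call(pipeline_config, args)
}

#' Run the full survey-analysis pipeline
#'
#' Stages: obtain catalog and design, simulate or ingest responses, apply
#' the inclusion cascade, score benefits and harms, tally the trade-off
#' question, summarize group balance, and render a Markdown report. Every
#' CSV artifact carries a `#` provenance header with package version and
#' seed; the run is byte-for-byte reproducible under a fixed config.
#'
#' @param config A `pipeline_config`.
#' @return Invisibly, a list with the in-memory results (`catalog`,
#'   `design`, `responses`, `flow`, `benefit_summary`, `bws`, `tradeoff`,
#'   `balance`) and the paths written.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  prov <- c(paste0("bwsrank ", as.character(utils::packageVersion("bwsrank"))),
            paste0("seed ", config$seed))
  log_msg <- function(...) message("[bwsrank] ", ...)

  catalog <- stage("catalog", {
    if (is.null(config$catalog)) default_catalog()
    else load_catalog(config$catalog)
  })
  harms <- catalog_items(catalog, "harm")

  design <- stage("design", {
    if (!is.null(config$design)) read_design(config$design)
    else generate_design(length(harms), config$n_blocks, config$block_size,
                         seed = config$seed, item_ids = harms)
  })
  write_design(design, file.path(config$out_dir, "design.csv"), prov)

  model <- stage("model", {
    if (is.null(config$model)) default_model(catalog)
    else if (inherits(config$model, "preference_model")) config$model
    else read_model_config(config$model)
  })

  responses <- stage(config$mode, {
    if (config$mode == "simulate") {
      simulate_survey(model, catalog, design, config$n, seed = config$seed)
    } else {
      read_responses(config$responses, catalog)
    }
  })
  log_msg("responses: ", nrow(responses))
  write_table(responses, file.path(config$out_dir, "responses.csv"), prov)

  invited <- if (is.null(config$invited)) nrow(responses) else config$invited
  filt <- stage("filter", apply_inclusion(responses, catalog, design,
                                          invited = invited))
  log_msg("benefit cohort: ", nrow(filt$benefit_cohort),
          "; harm cohort: ", nrow(filt$harm_cohort))
  write_table(flow_table(filt$flow), file.path(config$out_dir, "flow.csv"),
              prov)

  benefit_summary <- stage("score benefits",
    summarize_benefits(filt$benefit_cohort, catalog, qtype = config$qtype))
  write_table(benefit_summary,
              file.path(config$out_dir, "benefits_summary.csv"), prov)

  set_scores <- stage("score harms", bws_all_sets(filt$harm_cohort, design))
  bws <- stage("score harms", bws_average(set_scores, design))
  write_table(set_scores, file.path(config$out_dir, "bws_by_set.csv"), prov)
  write_table(bws, file.path(config$out_dir, "bws.csv"), prov)

  tradeoff <- stage("score tradeoff", tally_tradeoff(responses))
  write_table(tradeoff, file.path(config$out_dir, "tradeoff.csv"), prov)

  balance <- stage("score balance", group_balance(filt$harm_cohort, design))
  write_table(balance, file.path(config$out_dir, "balance.csv"), prov)

  report <- render_report(filt$flow, benefit_summary, bws, tradeoff, config)
  writeLines(report, file.path(config$out_dir, "report.md"))

  invisible(list(catalog = catalog, design = design, responses = responses,
                 flow = filt$flow, benefit_cohort = filt$benefit_cohort,
                 harm_cohort = filt$harm_cohort,
                 benefit_summary = benefit_summary, set_scores = set_scores,
                 bws = bws, tradeoff = tradeoff, balance = balance,
                 out_dir = config$out_dir))
}

render_report <- function(flow, benefit_summary, bws, tradeoff, config) {
  fmt_num <- function(x) formatC(x, format = "fg", digits = 4)
  c(
    "# Outcome-prioritization survey report",
    "",
    paste0("Seed: ", config$seed, "; mode: ", config$mode, "."),
    "",
    "## Participant flow",
    "",
    sprintf("- %s: %d", names(flow), unlist(flow)),
    "",
    "## Benefit ranking (median rank, IQR; 1 = most important)",
    "",
    sprintf("%2d. %s (median %s, IQR %s, n = %d)",
            seq_len(nrow(benefit_summary)), benefit_summary$item_id,
            fmt_num(benefit_summary$median_rank),
            fmt_num(benefit_summary$iqr), benefit_summary$n),
    "",
    "## Harm ordering by averaged best-worst score",
    "",
    sprintf("%2d. %s (score %s)", bws$final_rank, bws$item_id,
            fmt_num(bws$averaged_score)),
    "",
    "## Benefits versus side effects",
    "",
    sprintf("- %s: %d/%d (%.0f%%)", tradeoff$answer, tradeoff$count,
            tradeoff$denominator, 100 * tradeoff$proportion)
  )
}

#' Command-line entry point
#'
#' Subcommands: `design`, `simulate`, `filter`, `score`, `diagnose`,
#' `run`. Invoked by the `exec/bwsrank` script; callable directly with a
#' character vector of arguments for testing.
#'
#' @param args Character vector of command-line arguments.
#' @return Exit status (0 on success), invisibly.
#' @export
bws_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  status <- tryCatch({
    if (length(args) == 0L) stop(cli_usage(), call. = FALSE)
    cmd <- args[1L]
    opts <- parse_kv(args[-1L])
    switch(cmd,
      design = cli_design(opts),
      simulate = cli_simulate(opts),
      filter = cli_filter(opts),
      score = cli_score(opts),
      diagnose = cli_diagnose(opts),
      report = cli_report(opts),
      run = cli_run(opts),
      stop("unknown subcommand '", cmd, "'\n", cli_usage(), call. = FALSE))
    0L
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  invisible(status)
}

cli_usage <- function() {
  paste("usage: bwsrank <design|simulate|filter|score|diagnose|run> [--key value ...]",
        "  design:   --items N --blocks B --block-size K --seed S --out design.csv",
        "  simulate: [--config model.yaml] --design design.csv --n N --seed S --out responses.csv",
        "  filter:   --in responses.csv [--design design.csv] [--invited N] --out-flow f.csv --out-benefit b.csv --out-harm h.csv",
        "  score:    --task benefits|harms|tradeoff|balance --in cohort.csv [--design design.csv] --out out.csv",
        "  diagnose: [--config model.yaml] --design design.csv --ns 480,1200 --reps R --seed S --out recovery.csv",
        "  report:   --in responses.csv --design design.csv [--invited N] --out report.md",
        "  run:      --config pipeline.yaml | [--out-dir D --seed S --n N]",
        sep = "\n")
}

parse_kv <- function(args) {
  opts <- list()
  i <- 1L
  while (i <= length(args)) {
    key <- sub("^--", "", args[i])
    if (!startsWith(args[i], "--") || i == length(args)) {
      stop("malformed option near '", args[i], "'", call. = FALSE)
    }
    opts[[key]] <- args[i + 1L]
    i <- i + 2L
  }
  opts
}

opt_or <- function(opts, key, default = NULL) {
  if (!is.null(opts[[key]])) opts[[key]] else default
}

req_opt <- function(opts, key) {
  v <- opts[[key]]
  if (is.null(v)) stop("missing required option --", key, call. = FALSE)
  v
}

cli_catalog <- function(opts) {
  p <- opt_or(opts, "catalog")
  if (is.null(p)) default_catalog() else load_catalog(p)
}

cli_design <- function(opts) {
  d <- generate_design(as.integer(opt_or(opts, "items", "21")),
                       as.integer(opt_or(opts, "blocks", "12")),
                       as.integer(opt_or(opts, "block-size", "7")),
                       seed = as.integer(req_opt(opts, "seed")))
  write_design(d, req_opt(opts, "out"))
}

cli_simulate <- function(opts) {
  catalog <- cli_catalog(opts)
  design <- read_design(req_opt(opts, "design"))
  model <- if (is.null(opts$config)) default_model(catalog)
           else read_model_config(opts$config)
  resp <- simulate_survey(model, catalog, design,
                          n = as.integer(req_opt(opts, "n")),
                          seed = as.integer(req_opt(opts, "seed")))
  write_table(resp, req_opt(opts, "out"))
}

cli_filter <- function(opts) {
  catalog <- cli_catalog(opts)
  resp <- read_responses(req_opt(opts, "in"), catalog)
  design <- if (is.null(opts$design)) {
    harms <- catalog_items(catalog, "harm")
    stop("filter needs --design to judge harm-ranking completeness",
         call. = FALSE)
  } else read_design(opts$design)
  filt <- apply_inclusion(resp, catalog, design,
                          invited = as.integer(opt_or(opts, "invited",
                                                      nrow(resp))))
  write_table(flow_table(filt$flow), req_opt(opts, "out-flow"))
  write_table(filt$benefit_cohort, req_opt(opts, "out-benefit"))
  write_table(filt$harm_cohort, req_opt(opts, "out-harm"))
}

cli_score <- function(opts) {
  catalog <- cli_catalog(opts)
  task <- req_opt(opts, "task")
  resp <- read_responses(req_opt(opts, "in"), catalog)
  out <- switch(task,
    benefits = summarize_benefits(resp, catalog),
    harms = {
      design <- read_design(req_opt(opts, "design"))
      sets <- bws_all_sets(resp, design)
      if (!is.null(opts[["out-by-set"]])) {
        write_table(sets, opts[["out-by-set"]])
      }
      bws_average(sets, design)
    },
    tradeoff = tally_tradeoff(resp),
    balance = group_balance(resp, read_design(req_opt(opts, "design"))),
    stop("unknown score task '", task, "'", call. = FALSE))
  write_table(out, req_opt(opts, "out"))
}

cli_diagnose <- function(opts) {
  catalog <- cli_catalog(opts)
  design <- read_design(req_opt(opts, "design"))
  model <- if (is.null(opts$config)) default_model(catalog)
           else read_model_config(opts$config)
  ns <- as.integer(strsplit(req_opt(opts, "ns"), ",")[[1L]])
  rep_ <- recovery_experiment(model, catalog, design, ns = ns,
                              reps = as.integer(opt_or(opts, "reps", "20")),
                              seed = as.integer(req_opt(opts, "seed")))
  write_table(rep_$runs, req_opt(opts, "out"))
}

cli_report <- function(opts) {
  catalog <- cli_catalog(opts)
  design <- read_design(req_opt(opts, "design"))
  resp <- read_responses(req_opt(opts, "in"), catalog)
  filt <- apply_inclusion(resp, catalog, design,
                          invited = as.integer(opt_or(opts, "invited",
                                                      nrow(resp))))
  report <- render_report(
    filt$flow,
    summarize_benefits(filt$benefit_cohort, catalog),
    bws_average(bws_all_sets(filt$harm_cohort, design), design),
    tally_tradeoff(resp),
    list(seed = NA, mode = "ingest"))
  writeLines(report, req_opt(opts, "out"))
}

cli_run <- function(opts) {
  config <- if (!is.null(opts$config)) read_pipeline_config(opts$config)
            else pipeline_config(out_dir = req_opt(opts, "out-dir"),
                                 seed = as.integer(opt_or(opts, "seed", "1")),
                                 n = as.integer(opt_or(opts, "n", "746")))
  run_pipeline(config)
}
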