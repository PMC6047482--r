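VALID_KINDS <- c("benefit", "harm", "side_effects_aggregate")

#' Load an outcome catalog
#'
#' Reads a CSV catalog of outcome domains. Each row is one item with a short
#' stable identifier, a human-readable label, and a kind: `benefit`, `harm`,
#' or `side_effects_aggregate` (the single item standing in for all harms in
#' the benefits ranking task).
#'
#' @param path Path to a CSV file with header `item_id,label,kind`.
#'   Lines starting with `#` are treated as comments.
#' @return A data frame of class `outcome_catalog` with columns `item_id`,
#'   `label`, `kind`.
#' @examples
#' cat_path <- system.file("extdata", "outcome_catalog.csv", package = "bwsrank")
#' catalog <- load_catalog(cat_path)
#' table(catalog$kind)
#' @export
load_catalog <- function(path) {
  if (!file.exists(path)) {
    stop("catalog file does not exist: ", path, call. = FALSE)
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#",
                        colClasses = "character")
  required <- c("item_id", "label", "kind")
  if (!all(required %in% names(df))) {
    stop("catalog must have columns item_id,label,kind; found: ",
         paste(names(df), collapse = ","), call. = FALSE)
  }
  df <- df[, required, drop = FALSE]
  validate_catalog(df)
  class(df) <- c("outcome_catalog", "data.frame")
  df
}

validate_catalog <- function(df) {
  if (nrow(df) == 0L) return(invisible(df))
  dup <- df$item_id[duplicated(df$item_id)]
  if (length(dup) > 0L) {
    stop("duplicate item_id in catalog: ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  }
  bad <- setdiff(unique(df$kind), VALID_KINDS)
  if (length(bad) > 0L) {
    stop("unknown kind token(s) in catalog: ", paste(bad, collapse = ", "),
         "; expected one of ", paste(VALID_KINDS, collapse = ", "),
         call. = FALSE)
  }
  invisible(df)
}

#' The packaged default outcome catalog
#'
#' Six specific benefits of pain treatment, one aggregate "side effects" item
#' ranked alongside them, and 21 grouped harm domains.
#'
#' @return An `outcome_catalog` data frame (28 rows).
#' @export
default_catalog <- function() {
  load_catalog(system.file("extdata", "outcome_catalog.csv",
                           package = "bwsrank", mustWork = TRUE))
}

#' Subset catalog items by kind
#'
#' @param catalog An `outcome_catalog`.
#' @param kind One of `"benefit"`, `"harm"`, `"side_effects_aggregate"`.
#' @return Character vector of item ids, in catalog order.
#' @export
catalog_items <- function(catalog, kind) {
  kind <- match.arg(kind, VALID_KINDS)
  catalog$item_id[catalog$kind == kind]
}

#' Items of the benefits ranking task
#'
#' The benefits task ranks the 6 benefit items plus the single side-effects
#' aggregate item, 7 items in all.
#'
#' @param catalog An `outcome_catalog`.
#' @return Character vector of the 7 item ids, in catalog order.
#' @export
benefit_task_items <- function(catalog) {
  catalog$item_id[catalog$kind %in% c("benefit", "side_effects_aggregate")]
}

DEMOGRAPHIC_COLS <- c("respondent_id", "birth_year", "birth_month", "gender",
                      "has_tmj_condition", "ppi", "comorbid_pain_count",
                      "current_med_count", "past_med_count", "harm_set_id",
                      "tradeoff")

TRADEOFF_LEVELS <- c("benefits", "harms", "equal")

rank_cols <- function(items) paste0("rank_", items)

#' Read a survey response table
#'
#' One row per respondent. Demographic columns follow the response-record
#' schema; ranking columns are named `rank_<item_id>`. Ranks must be integers
#' in 1..7; missing answers are empty cells. Partial rankings are retained
#' and only annotated: completeness is judged downstream by the inclusion
#' filters.
#'
#' @param path Path to a CSV response table (comment lines start with `#`).
#' @param catalog An `outcome_catalog`; ranking columns are matched against
#'   its item ids.
#' @return A data frame of class `response_table`.
#' @export
read_responses <- function(path, catalog) {
  if (!file.exists(path)) {
    stop("response file does not exist: ", path, call. = FALSE)
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  validate_responses(df, catalog)
}

#' Validate an in-memory response table
#'
#' @param df A data frame in the response-table layout.
#' @param catalog An `outcome_catalog`.
#' @return `df`, with class `response_table`, after validation.
#' @export
validate_responses <- function(df, catalog) {
  all_items <- catalog$item_id
  rcols <- intersect(rank_cols(all_items), names(df))
  if (!"respondent_id" %in% names(df)) {
    stop("response table must have a respondent_id column", call. = FALSE)
  }
  for (col in rcols) {
    v <- df[[col]]
    if (is.character(v)) v <- suppressWarnings(as.numeric(ifelse(v == "", NA, v)))
    bad <- which(!is.na(v) & (v != round(v) | v < 1 | v > 7))
    if (length(bad) > 0L) {
      stop("rank outside 1-7 (or non-integer) in column ", col,
           ", row(s) ", paste(utils::head(bad, 5L), collapse = ", "),
           call. = FALSE)
    }
    df[[col]] <- as.integer(v)
  }
  # duplicate ranks within one respondent's ranking (vectorized: a rank
  # value may be used at most once per task per row)
  check_dup <- function(cols, task) {
    if (length(cols) == 0L || nrow(df) == 0L) return(invisible())
    m <- as.matrix(df[, cols, drop = FALSE])
    for (v in 1:7) {
      bad <- which(rowSums(m == v, na.rm = TRUE) > 1L)
      if (length(bad) > 0L) {
        stop("duplicate rank ", v, " within ", task, " ranking, row(s) ",
             paste(utils::head(bad, 5L), collapse = ", "), call. = FALSE)
      }
    }
  }
  check_dup(intersect(rank_cols(benefit_task_items(catalog)), names(df)),
            "benefit")
  check_dup(intersect(rank_cols(catalog_items(catalog, "harm")), names(df)),
            "harm")
  if ("tradeoff" %in% names(df)) {
    tv <- df$tradeoff
    tv[tv %in% ""] <- NA
    bad <- unique(tv[!is.na(tv) & !tv %in% TRADEOFF_LEVELS])
    if (length(bad) > 0L) {
      stop("unknown tradeoff value(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
    df$tradeoff <- tv
  }
  class(df) <- c("response_table", "data.frame")
  df
}

#' Does each row carry a complete 7-item benefits ranking?
#'
#' Complete means the ranks over the 6 benefits plus the side-effects item
#' form a bijection onto 1..7.
#'
#' @param responses A `response_table`.
#' @param catalog An `outcome_catalog`.
#' @return Logical vector, one element per row.
#' @export
benefits_complete <- function(responses, catalog) {
  items <- benefit_task_items(catalog)
  cols <- rank_cols(items)
  missing_cols <- setdiff(cols, names(responses))
  if (length(missing_cols) > 0L) return(rep(FALSE, nrow(responses)))
  complete_bijection(as.matrix(responses[, cols, drop = FALSE]))
}

# rows whose entries are a bijection onto 1..ncol (vectorized)
complete_bijection <- function(m) {
  k <- ncol(m)
  ok <- rep(TRUE, nrow(m))
  for (v in seq_len(k)) ok <- ok & (rowSums(m == v, na.rm = TRUE) == 1L)
  ok & rowSums(is.na(m)) == 0L
}

#' Does each row carry a complete 7-item harms ranking?
#'
#' Complete means the respondent has an assigned set and the ranks over
#' exactly that set's items form a bijection onto 1..7.
#'
#' @param responses A `response_table`.
#' @param design A `block_design` giving each set's membership.
#' @return Logical vector, one element per row.
#' @export
harms_complete <- function(responses, design) {
  n <- nrow(responses)
  out <- rep(FALSE, n)
  if (n == 0L) return(out)
  sid <- responses$harm_set_id
  for (b in seq_along(design$blocks)) {
    idx <- which(!is.na(sid) & sid == b)
    if (length(idx) == 0L) next
    cols <- rank_cols(design$blocks[[b]])
    if (!all(cols %in% names(responses))) next
    out[idx] <- complete_bijection(
      as.matrix(responses[idx, cols, drop = FALSE]))
  }
  out
}

#' Write a result table to CSV
#'
#' Deterministic column order (as given), UTF-8, LF line endings, empty cells
#' for missing values. Optional provenance lines are written as `#` comments
#' before the header so the file round-trips through the package readers.
#'
#' @param rows A data frame (may have zero rows).
#' @param path Output path.
#' @param comments Optional character vector of provenance lines.
#' @return Invisibly, `path`.
#' @export
write_table <- function(rows, path, comments = NULL) {
  if (is.null(rows)) stop("rows must be non-null", call. = FALSE)
  con <- tryCatch(file(path, open = "wb"), error = function(e)
    stop("cannot open for writing: ", path, call. = FALSE))
  on.exit(close(con))
  if (length(comments) > 0L) {
    writeLines(paste0("# ", comments), con, sep = "\n")
  }
  utils::write.csv(rows, con, row.names = FALSE, quote = TRUE, na = "",
                   eol = "\n", fileEncoding = "UTF-8")
  invisible(path)
}
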