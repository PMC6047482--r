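#' Replication forced by block-design parameters
#'
#' If every one of `n_items` items is to appear equally often across
#' `n_blocks` blocks of `block_size` distinct items, each item must appear in
#' exactly `n_blocks * block_size / n_items` blocks. Errors if that quotient
#' is not an integer.
#'
#' @param n_items,n_blocks,block_size Positive integer counts.
#' @return The integer replication count.
#' @examples
#' required_replication(21, 12, 7)  # 4
#' @export
required_replication <- function(n_items, n_blocks, block_size) {
  for (v in list(n_items = n_items, n_blocks = n_blocks,
                 block_size = block_size)) {
    if (length(v) != 1L || is.na(v) || v <= 0 || v != round(v)) {
      stop("n_items, n_blocks and block_size must be positive integers",
           call. = FALSE)
    }
  }
  if (block_size > n_items) {
    stop("block_size (", block_size, ") exceeds n_items (", n_items, ")",
         call. = FALSE)
  }
  total <- n_blocks * block_size
  if (total %% n_items != 0L) {
    stop("infeasible design: replication would be ", total, "/", n_items,
         " = ", format(total / n_items, digits = 6),
         ", which is not an integer", call. = FALSE)
  }
  as.integer(total / n_items)
}

#' Construct a near-balanced incomplete block design
#'
#' Assigns `n_items` items to `n_blocks` blocks of `block_size` distinct
#' items so that every item appears in exactly `required_replication()`
#' blocks. Among such designs the construction minimizes the variance of
#' pairwise co-occurrence counts: a seeded randomized greedy fill followed by
#' pairwise-swap hill-climbing on the sum of squared co-occurrences, inside
#' an iterated-local-search loop (random-swap kicks, re-climb) with
#' restarts. A perfect BIBD is returned whenever the search reaches the
#' theoretical optimum; otherwise the best near-balanced design found. Note
#' that for some parameter sets -- including (21, 12, 7) -- spreading every
#' pairwise count over at most two adjacent values is provably impossible
#' (a rank bound on the co-occurrence matrix forbids it), so a small number
#' of never-co-occurring or thrice-co-occurring pairs can be unavoidable.
#'
#' @param n_items,n_blocks,block_size Design parameters.
#' @param seed Integer seed; equal seeds give identical designs.
#' @param item_ids Optional character vector of `n_items` ids (default
#'   `item01`...).
#' @param restarts Number of greedy restarts (each followed by a climb).
#' @param perturbations Iterated-local-search kicks per restart.
#' @param max_sweeps Maximum hill-climbing sweeps per climb.
#' @param max_cooccurrence Optional integer; if set, error unless the final
#'   design's off-diagonal co-occurrence counts are all `<=` this bound.
#' @return A `block_design`: list with `item_ids`, `blocks` (list of
#'   character vectors), `block_size`, `replication`.
#' @examples
#' d <- generate_design(21, 12, 7, seed = 1)
#' table(unlist(d$blocks))  # every item 4 times
#' @export
generate_design <- function(n_items, n_blocks, block_size, seed,
                            item_ids = NULL, restarts = 2L,
                            perturbations = 40L, max_sweeps = 50L,
                            max_cooccurrence = NULL) {
  r <- required_replication(n_items, n_blocks, block_size)
  if (is.null(item_ids)) {
    item_ids <- sprintf("item%02d", seq_len(n_items))
  }
  if (length(item_ids) != n_items || anyDuplicated(item_ids)) {
    stop("item_ids must be ", n_items, " distinct ids", call. = FALSE)
  }
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(restore_seed(old_seed))
  set.seed(as.integer(seed))

  # Minimum achievable sum of squared off-diagonal co-occurrences: the total
  # co-occurrence mass n_blocks*C(k,2) is fixed, so the optimum spreads it as
  # evenly as integers allow over C(n_items,2) pairs.
  total_pairs <- choose(n_items, 2L)
  mass <- n_blocks * choose(block_size, 2L)
  q <- mass %/% total_pairs; rem <- mass %% total_pairs
  ss_lower <- (total_pairs - rem) * q^2 + rem * (q + 1L)^2

  best <- NULL
  best_ss <- Inf
  for (rs in seq_len(max(1L, restarts))) {
    inc <- NULL
    for (try in 1:100) {
      inc <- greedy_fill(n_items, n_blocks, block_size, r)
      if (!is.null(inc)) break
    }
    if (is.null(inc)) next
    inc <- climb_swaps(inc, max_sweeps)
    ss <- cooc_ss(inc)
    # iterated local search: kick the local optimum with a few random swaps
    # and re-climb, keeping the best incidence seen
    for (p in seq_len(perturbations)) {
      if (ss <= ss_lower) break
      cand <- climb_swaps(random_swaps(inc, 3L), max_sweeps)
      cand_ss <- cooc_ss(cand)
      if (cand_ss <= ss) { inc <- cand; ss <- cand_ss }
    }
    if (ss < best_ss) {
      best_ss <- ss
      best <- inc
      if (best_ss <= ss_lower) break
    }
  }
  if (is.null(best)) {
    stop("design search failed to produce a feasible incidence for (",
         n_items, ",", n_blocks, ",", block_size, ")", call. = FALSE)
  }
  co <- crossprod(best)
  offd <- co[upper.tri(co)]
  if (!is.null(max_cooccurrence) && max(offd) > max_cooccurrence) {
    stop("design search did not reach co-occurrence bound ",
         max_cooccurrence, "; best achieved max ", max(offd),
         " (sum of squares ", best_ss, ")", call. = FALSE)
  }
  blocks <- lapply(seq_len(n_blocks), function(b)
    item_ids[which(best[b, ] == 1L)])
  structure(list(item_ids = item_ids, blocks = blocks,
                 block_size = as.integer(block_size),
                 replication = r),
            class = "block_design")
}

restore_seed <- function(old_seed) {
  if (is.null(old_seed)) {
    if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old_seed, envir = globalenv())
  }
}

# Randomized feasible fill: deal r copies of each item into blocks, always
# into the emptiest admissible block; returns n_blocks x n_items 0/1 matrix
# or NULL if the dealing dead-ends.
greedy_fill <- function(n_items, n_blocks, block_size, r) {
  inc <- matrix(0L, nrow = n_blocks, ncol = n_items)
  items <- sample(rep(seq_len(n_items), each = r))
  for (it in items) {
    load <- rowSums(inc)
    ok <- which(load < block_size & inc[, it] == 0L)
    if (length(ok) == 0L) return(NULL)
    ok <- ok[load[ok] == min(load[ok])]
    b <- if (length(ok) == 1L) ok else sample(ok, 1L)
    inc[b, it] <- 1L
  }
  if (any(rowSums(inc) != block_size)) return(NULL)
  inc
}

cooc_ss <- function(inc) {
  co <- crossprod(inc)
  sum(co[upper.tri(co)]^2)
}

is_perfectly_balanced <- function(inc) {
  co <- crossprod(inc)
  offd <- co[upper.tri(co)]
  max(offd) - min(offd) <= 0L
}

# Perturbation move for iterated local search: k random margin-preserving
# item swaps between random block pairs.
random_swaps <- function(inc, k) {
  n_blocks <- nrow(inc)
  if (n_blocks < 2L) return(inc)
  for (i in seq_len(k)) {
    ab <- sample.int(n_blocks, 2L)
    a <- ab[1L]; b <- ab[2L]
    only_a <- which(inc[a, ] == 1L & inc[b, ] == 0L)
    only_b <- which(inc[b, ] == 1L & inc[a, ] == 0L)
    if (!length(only_a) || !length(only_b)) next
    x <- only_a[sample.int(length(only_a), 1L)]
    y <- only_b[sample.int(length(only_b), 1L)]
    inc[a, x] <- 0L; inc[b, x] <- 1L
    inc[a, y] <- 1L; inc[b, y] <- 0L
  }
  inc
}

# First-improvement hill climbing on item swaps between block pairs,
# objective = sum of squared pairwise co-occurrences (minimizing it at fixed
# margins minimizes co-occurrence variance).
climb_swaps <- function(inc, max_sweeps) {
  n_blocks <- nrow(inc)
  if (n_blocks < 2L) return(inc)
  co <- crossprod(inc)
  for (sweep in seq_len(max_sweeps)) {
    improved <- FALSE
    pairs <- utils::combn(n_blocks, 2L)
    pairs <- pairs[, sample(ncol(pairs)), drop = FALSE]
    for (p in seq_len(ncol(pairs))) {
      a <- pairs[1L, p]; b <- pairs[2L, p]
      repeat {
        only_a <- which(inc[a, ] == 1L & inc[b, ] == 0L)
        only_b <- which(inc[b, ] == 1L & inc[a, ] == 0L)
        if (!length(only_a) || !length(only_b)) break
        set_a <- which(inc[a, ] == 1L)
        set_b <- which(inc[b, ] == 1L)
        best_delta <- 0L; best_x <- NA_integer_; best_y <- NA_integer_
        for (x in only_a) {
          for (y in only_b) {
            delta <- swap_delta(co, x, y, set_a, set_b)
            if (delta < best_delta) {
              best_delta <- delta; best_x <- x; best_y <- y
            }
          }
        }
        if (is.na(best_x)) break
        x <- best_x; y <- best_y
        oa <- setdiff(set_a, c(set_b, x, y))
        ob <- setdiff(set_b, c(set_a, x, y))
        co[x, oa] <- co[x, oa] - 1L; co[oa, x] <- co[oa, x] - 1L
        co[x, ob] <- co[x, ob] + 1L; co[ob, x] <- co[ob, x] + 1L
        co[y, ob] <- co[y, ob] - 1L; co[ob, y] <- co[ob, y] - 1L
        co[y, oa] <- co[y, oa] + 1L; co[oa, y] <- co[oa, y] + 1L
        inc[a, x] <- 0L; inc[b, x] <- 1L
        inc[a, y] <- 1L; inc[b, y] <- 0L
        improved <- TRUE
      }
    }
    if (!improved) break
  }
  inc
}

# Change in sum of squared off-diagonal co-occurrences if x (in block a) and
# y (in block b) trade places. set_a/set_b are the current memberships.
# Items in both blocks see no net change and must be excluded; the (x, y)
# pair itself is also unchanged by the trade.
swap_delta <- function(co, x, y, set_a, set_b) {
  oa <- setdiff(set_a, c(set_b, x, y))   # partners x leaves / y gains
  ob <- setdiff(set_b, c(set_a, x, y))   # partners x gains / y leaves
  d <- 0L
  # x: loses one co-occurrence with each of oa, gains one with each of ob
  d <- d + sum((co[x, oa] - 1L)^2 - co[x, oa]^2)
  d <- d + sum((co[x, ob] + 1L)^2 - co[x, ob]^2)
  # y: mirrored
  d <- d + sum((co[y, ob] - 1L)^2 - co[y, ob]^2)
  d <- d + sum((co[y, oa] + 1L)^2 - co[y, oa]^2)
  d
}

#' Pairwise co-occurrence matrix of a design
#'
#' Entry (i, j), i != j, counts the blocks containing both items; the
#' diagonal is each item's replication.
#'
#' @param design A `block_design`.
#' @return Symmetric integer matrix with item ids as dimnames.
#' @export
cooccurrence_matrix <- function(design) {
  stopifnot(inherits(design, "block_design"))
  ids <- design$item_ids
  inc <- vapply(design$blocks, function(b) as.integer(ids %in% b),
                integer(length(ids)))
  co <- tcrossprod(inc)
  dimnames(co) <- list(ids, ids)
  co
}

#' Map a birth month to a ranking set
#'
#' Deterministic natural-order mapping: month m goes to set
#' `((m - 1) mod n_blocks) + 1`, so with 12 sets January is set 1 and
#' December set 12.
#'
#' @param birth_month Integer vector, values in 1..12 (NA passes through).
#' @param n_blocks Number of sets.
#' @return Integer set indices.
#' @export
assign_set <- function(birth_month, n_blocks) {
  m <- birth_month
  bad <- !is.na(m) & (m < 1 | m > 12 | m != round(m))
  if (any(bad)) {
    stop("birth_month out of range 1-12: ",
         paste(utils::head(m[bad], 5L), collapse = ", "), call. = FALSE)
  }
  as.integer(((m - 1L) %% n_blocks) + 1L)
}

#' @export
print.block_design <- function(x, ...) {
  cat("block_design:", length(x$item_ids), "items in", length(x$blocks),
      "blocks of", x$block_size, "(replication", paste0(x$replication, ")\n"))
  co <- cooccurrence_matrix(x)
  offd <- co[upper.tri(co)]
  cat("  pairwise co-occurrence counts:",
      paste(names(table(offd)), table(offd), sep = "x", collapse = ", "),
      "\n")
  invisible(x)
}

#' Write a design to CSV
#'
#' Long format, one row per item-in-set: `set_id,item_id`.
#'
#' @param design A `block_design`.
#' @param path Output path.
#' @param comments Optional provenance comment lines.
#' @return Invisibly, `path`.
#' @export
write_design <- function(design, path, comments = NULL) {
  rows <- data.frame(
    set_id = rep(seq_along(design$blocks),
                 vapply(design$blocks, length, integer(1L))),
    item_id = unlist(design$blocks),
    stringsAsFactors = FALSE
  )
  write_table(rows, path, comments = comments)
}

#' Read a design written by [write_design()]
#'
#' @param path Path to a `set_id,item_id` CSV.
#' @return A `block_design`. Block size and replication are validated to be
#'   uniform across sets and items.
#' @export
read_design <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  if (!all(c("set_id", "item_id") %in% names(df))) {
    stop("design file must have columns set_id,item_id", call. = FALSE)
  }
  sets <- sort(unique(df$set_id))
  if (!identical(sets, seq_along(sets))) {
    stop("set_id values must be 1..n_blocks with no gaps", call. = FALSE)
  }
  blocks <- lapply(sets, function(s) df$item_id[df$set_id == s])
  sizes <- vapply(blocks, function(b) length(unique(b)), integer(1L))
  if (any(vapply(blocks, anyDuplicated, integer(1L)) > 0L)) {
    stop("a set lists the same item twice", call. = FALSE)
  }
  if (length(unique(sizes)) != 1L) {
    stop("sets have unequal sizes: ", paste(sizes, collapse = ","),
         call. = FALSE)
  }
  reps <- table(df$item_id)
  if (length(unique(as.integer(reps))) != 1L) {
    stop("items have unequal replication across sets", call. = FALSE)
  }
  structure(list(item_ids = sort(unique(df$item_id)), blocks = blocks,
                 block_size = sizes[1L],
                 replication = as.integer(reps[1L])),
            class = "block_design")
}

#' Build a block_design from explicit blocks
#'
#' @param blocks List of character vectors of item ids.
#' @return A validated `block_design`.
#' @export
as_block_design <- function(blocks) {
  sizes <- vapply(blocks, length, integer(1L))
  if (length(unique(sizes)) != 1L) {
    stop("blocks have unequal sizes", call. = FALSE)
  }
  reps <- table(unlist(blocks))
  if (length(unique(as.integer(reps))) != 1L) {
    stop("items have unequal replication across blocks", call. = FALSE)
  }
  structure(list(item_ids = sort(names(reps)), blocks = blocks,
                 block_size = sizes[1L], replication = as.integer(reps[1L])),
            class = "block_design")
}
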