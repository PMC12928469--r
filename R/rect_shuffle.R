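#' Rectangle-swap proposal
#'
#' A proposal names two rows and two columns of a genotype matrix.  It is
#' valid when the four corner entries form a crossed pattern --
#' `m[a,i] == m[b,j]`, `m[a,j] == m[b,i]` and `m[a,i] != m[a,j]` -- so that
#' exchanging the values within each row preserves every row sum and every
#' column sum.
#'
#' @param row_a,row_b distinct row indices.
#' @param col_i,col_j distinct column indices.
#' @return an object of class `swap_proposal`.
#' @export
swap_proposal <- function(row_a, row_b, col_i, col_j) {
  if (row_a == row_b || col_i == col_j)
    stop("rows and columns of a swap proposal must be distinct", call. = FALSE)
  structure(list(row_a = row_a, row_b = row_b, col_i = col_i, col_j = col_j),
            class = "swap_proposal")
}

#' @rdname swap_proposal
#' @param m integer matrix.
#' @param s a [swap_proposal()].
#' @export
is_valid_swap <- function(m, s) {
  m[s$row_a, s$col_i] == m[s$row_b, s$col_j] &&
    m[s$row_a, s$col_j] == m[s$row_b, s$col_i] &&
    m[s$row_a, s$col_i] != m[s$row_a, s$col_j]
}

#' Apply a single rectangle swap
#'
#' Applies a valid proposal; an invalid proposal is rejected with a warning
#' and the matrix is returned unchanged.  The swap is an involution:
#' applying it twice restores the input.
#'
#' @inheritParams is_valid_swap
#' @return the matrix, with attribute `swap_accepted` (logical).
#' @export
apply_swap <- function(m, s) {
  if (!is_valid_swap(m, s)) {
    warning("invalid swap proposal rejected (no-op)", call. = FALSE)
    attr(m, "swap_accepted") <- FALSE
    return(m)
  }
  ai <- m[s$row_a, s$col_i]; aj <- m[s$row_a, s$col_j]
  m[s$row_a, s$col_i] <- aj; m[s$row_a, s$col_j] <- ai
  m[s$row_b, s$col_i] <- ai; m[s$row_b, s$col_j] <- aj
  attr(m, "swap_accepted") <- TRUE
  m
}

#' One rectangle-shuffle epoch
#'
#' Applies `ceiling(N * M * log(N * M))` accepted rectangle swaps (natural
#' log) drawn uniformly at random; this swap count is the mixing budget
#' under which the shuffled matrix deviates sufficiently from its origin.
#' Invalid proposals are resampled without counting.  All row and column
#' sums are preserved exactly.
#'
#' @param m integer (genotype) matrix, at least 2 x 2 and non-constant.
#' @param n_swaps number of accepted swaps; default `(N*M)*log(N*M)`.
#' @param seed optional integer seed.
#' @param max_consecutive_fail abort threshold for degenerate matrices.
#' @return the shuffled matrix.
#' @export
shuffle_epoch <- function(m, n_swaps = NULL, seed = NULL,
                          max_consecutive_fail = 1e7) {
  if (!is.null(seed)) set.seed(seed)
  nm <- as.numeric(nrow(m)) * ncol(m)
  if (is.null(n_swaps)) n_swaps <- ceiling(nm * log(nm))
  storage.mode(m) <- "integer"
  out <- cpp_rect_shuffle(m, n_swaps, max_consecutive_fail)
  dimnames(out) <- dimnames(m)
  out
}

# independently permute the values within each row (preserves row sums,
# lets column sums drift) -- the post-80% fallback move
permute_rows <- function(m) {
  for (r in seq_len(nrow(m))) m[r, ] <- m[r, sample.int(ncol(m))]
  m
}

#' Expand a core population under a disease model
#'
#' Manufactures `target_n` genotype rows of a required status from a core
#' matrix.  The working copy of the core is rectangle-shuffled for one
#' epoch at a time; after each epoch every row classified as
#' `target_status` under `model` is moved into the output pool (rows of
#' the wrong status are rejected) and the remaining rows are shuffled
#' again.  When the working matrix runs dry, or rectangle shuffling stops
#' yielding acceptable rows before the pool is near complete, it is
#' replenished with a fresh copy of the core, starting a new sweep.
#' Because each individual is absorbed at most once per sweep, the pool
#' reproduces the core's load distribution (expanded Case sets keep a mean
#' load within a fraction of an allele of the core's) instead of
#' over-representing high-load rows.  Once the pool has reached
#' `fallback_fraction` of `target_n` *and* the rectangle acceptance rate
#' has deteriorated below `rate_floor` -- minting the last rows of the
#' required status becomes increasingly difficult -- the expansion falls
#' back to independently permuting values within rows (preserving each
#' individual's load, letting column sums drift) with the same
#' accept/reject rule.  At default parameterisations Control expansions
#' complete by rectangle shuffling alone and never fall back.
#'
#' @param core genotype matrix seeding the expansion (conventionally the
#'   group's core set; its rows need not all classify as `target_status`).
#' @param model a disease model (the Case/Control oracle).
#' @param target_status `"Case"` or `"Control"`.
#' @param target_n rows to produce.
#' @param seed optional integer seed.
#' @param fallback_fraction pool fraction past which row-permutation
#'   fallback may start (default 0.80).
#' @param rate_floor acceptance rate (accepted / working rows per epoch)
#'   below which rectangle shuffling counts as exhausted.
#' @param max_epochs stall guard; `max_epochs = 0` with
#'   `target_n <= nrow(core)` returns the core itself (identity
#'   configuration).
#' @param prefilter drop core rows not classifying as `target_status`
#'   before shuffling (off by default: rejection alone keeps the output
#'   pure while the full core preserves the load distribution).
#' @param dedup drop duplicate pool rows before counting (default off).
#' @return list with `genotypes` (`target_n` rows, every one classifying as
#'   `target_status`) and `report` (class `expansion_report`: per-epoch
#'   acceptance counts, epochs, sweeps, fallback flag).
#' @export
expand_population <- function(core, model, target_status = c("Case", "Control"),
                              target_n, seed = NULL, fallback_fraction = 0.8,
                              rate_floor = 0.02, max_epochs = 500L,
                              prefilter = FALSE, dedup = FALSE) {
  target_status <- match.arg(target_status)
  if (!is.null(seed)) set.seed(seed)
  core <- as_genotype_matrix(core)
  if (prefilter) core <- core[classify(model, core) == target_status, , drop = FALSE]
  if (nrow(core) < 2)
    stop("need at least 2 core rows", call. = FALSE)
  report <- list(accepted = integer(0), epochs = 0L, sweeps = 1L,
                 fallback_triggered = FALSE,
                 fallback_fraction = fallback_fraction)
  if (max_epochs == 0L) {
    if (target_n > nrow(core))
      stop("max_epochs = 0 requires target_n <= nrow(core)", call. = FALSE)
    return(list(genotypes = core[seq_len(target_n), , drop = FALSE],
                report = structure(report, class = "expansion_report")))
  }
  work <- core
  pool <- vector("list", 0L)
  pool_keys <- character(0)
  pool_n <- 0L
  refill <- FALSE
  zero_streak <- 0L
  # a remainder this small is mopped up by a fresh sweep, not treated as
  # exhaustion of rectangle shuffling
  mopup_n <- max(2, ceiling(0.05 * target_n))
  while (pool_n < target_n) {
    if (report$epochs >= max_epochs)
      stop("expansion stalled: ", pool_n, "/", target_n, " rows after ",
           report$epochs, " epochs", call. = FALSE)
    # tiny remainders may admit no valid rectangle swap; exhausted
    # remainders (stubborn rows) need a fresh sweep of the core
    if (nrow(work) < 8L || refill) {
      work <- rbind(work, core)
      report$sweeps <- report$sweeps + 1L
      refill <- FALSE
    }
    n_work <- nrow(work)
    work <- if (report$fallback_triggered) permute_rows(work)
            else shuffle_epoch(work)
    keep <- classify(model, work) == target_status
    acc <- work[keep, , drop = FALSE]
    work <- work[!keep, , drop = FALSE]
    if (dedup && nrow(acc)) {
      key <- apply(acc, 1, paste, collapse = "")
      fresh <- !duplicated(key) & !(key %in% pool_keys)
      acc <- acc[fresh, , drop = FALSE]
      pool_keys <- c(pool_keys, key[fresh])
    }
    report$epochs <- report$epochs + 1L
    report$accepted <- c(report$accepted, nrow(acc))
    if (report$epochs >= 10L && sum(report$accepted) == 0L)
      stop("expansion stalled: no row of status ", target_status,
           " produced in ", report$epochs, " epochs; ",
           "is that status reachable under this model?", call. = FALSE)
    if (nrow(acc)) { pool[[length(pool) + 1L]] <- acc; pool_n <- pool_n + nrow(acc) }
    zero_streak <- if (nrow(acc) == 0L) zero_streak + 1L else 0L
    remaining <- target_n - pool_n
    if (remaining > 0L) {
      if (!report$fallback_triggered) {
        if (nrow(acc) / n_work < rate_floor) {
          if (pool_n >= fallback_fraction * target_n && remaining > mopup_n)
            report$fallback_triggered <- TRUE
          else
            refill <- TRUE  # new sweep (mid-expansion or trivial mop-up)
        }
      } else if (zero_streak >= 2L) {
        refill <- TRUE      # stubborn remainder exhausted even by permutation
      }
    }
  }
  out <- do.call(rbind, pool)[seq_len(target_n), , drop = FALSE]
  list(genotypes = out, report = structure(report, class = "expansion_report"))
}

#' @export
print.expansion_report <- function(x, ...) {
  cat(sprintf("Expansion: %d epochs, %d rows accepted, fallback %s (at %.0f%%)\n",
              x$epochs, sum(x$accepted),
              if (x$fallback_triggered) "triggered" else "not triggered",
              100 * x$fallback_fraction))
  invisible(x)
}
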