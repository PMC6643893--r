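#' Mating plan
#'
#' An ordered list of selected individuals in which consecutive entries
#' `(1,2), (3,4), ...` form the mate pairs, with one progeny count per pair.
#'
#' @param selected Integer vector of `S` individual indices (even length),
#'   in mating order.
#' @param n_progeny Integer vector of per-pair progeny counts (length `S/2`),
#'   or `NULL` if not yet allocated.
#' @return An object of class `MatingPlan`.
#' @export
MatingPlan <- function(selected, n_progeny = NULL) {
  selected <- as.integer(selected)
  if (length(selected) %% 2 != 0) stop("a mating plan needs an even number of parents")
  if (!is.null(n_progeny)) {
    n_progeny <- as.integer(n_progeny)
    if (length(n_progeny) != length(selected) / 2)
      stop("one progeny count per mate pair is required")
    if (any(n_progeny < 1)) stop("every pair must produce at least one progeny")
  }
  structure(list(selected = selected, n_progeny = n_progeny),
            class = "MatingPlan")
}

#' @export
print.MatingPlan <- function(x, ...) {
  np <- x$n_progeny %||% rep(NA_integer_, length(x$selected) / 2)
  cat("MatingPlan:\n")
  for (p in seq_len(length(x$selected) / 2))
    cat(sprintf("  cross %d: %d x %d  (%s progenies)\n", p,
                x$selected[2 * p - 1], x$selected[2 * p], np[p]))
  invisible(x)
}

#' Truncation selection
#'
#' Indices of the `S` largest scores; ties broken toward the lowest index.
#'
#' @param scores Numeric vector.
#' @param S Number to select (`<= length(scores)`).
#' @return Integer vector of length `S`, in decreasing score order.
#' @export
truncation_select <- function(scores, S) {
  if (S > length(scores)) stop("cannot select more individuals than available")
  order(scores, seq_along(scores), decreasing = c(TRUE, FALSE),
        method = "radix")[seq_len(S)]
}

#' Remove the lowest-GEBV fraction of a population
#'
#' Drops the `floor(F * N)` individuals with the lowest GEBVs before a
#' group-based optimization (ties resolved by removing the higher index
#' first); survivors are returned in their original order.
#'
#' @inheritParams compute_gebv
#' @param F Fraction to remove, in `[0, 1)`.
#' @param S Optional: error if fewer than `S` survivors remain.
#' @return Integer vector of surviving indices.
#' @export
prefilter_by_gebv <- function(pop, spec, F, S = NULL) {
  if (F < 0 || F >= 1) stop("F must lie in [0, 1)")
  N <- n_ind(pop)
  k <- floor(F * N)
  gebv <- compute_gebv(pop, spec)
  drop_order <- order(gebv, -seq_len(N), method = "radix")
  survivors <- sort(drop_order[seq(k + 1, N)])
  if (!is.null(S) && length(survivors) < S)
    stop("prefiltering left fewer survivors than the number to select")
  survivors
}

#' Random monogamous pairing
#'
#' Realizes a uniform random perfect matching of the selected individuals by
#' shuffling the list and pairing consecutive entries.
#'
#' @param selected Integer indices (even count).
#' @param seed Optional integer seed.
#' @return A [MatingPlan] without progeny counts.
#' @export
random_pairing <- function(selected, seed = NULL) {
  if (length(selected) %% 2 != 0) stop("an even number of individuals is required")
  MatingPlan(with_seed(seed, sample(selected)))
}

# Shared first-improvement swap scan over (selected position, outside
# candidate) moves; `objective(sel)` must return a scalar to maximize.
# `ordered` additionally scans cross-pair position exchanges.
swap_search <- function(candidates, S, objective, ordered = FALSE,
                        exchange_moves = TRUE, max_iters = 50, tol = 0) {
  sel <- sample(candidates, S)
  best <- objective(sel)
  for (iter in seq_len(max_iters)) {
    improved <- FALSE
    for (p in seq_len(S)) {
      for (c in candidates) {
        if (c %in% sel) next
        cand <- sel
        cand[p] <- c
        val <- objective(cand)
        if (val > best + tol) {
          sel <- cand
          best <- val
          improved <- TRUE
        }
      }
    }
    if (ordered && exchange_moves) {
      for (p in seq_len(S - 1)) for (q in seq((p + 1), S)) {
        if (ceiling(p / 2) == ceiling(q / 2)) next  # same pair: objective unchanged
        cand <- sel
        cand[c(p, q)] <- sel[c(q, p)]
        val <- objective(cand)
        if (val > best + tol) {
          sel <- cand
          best <- val
          improved <- TRUE
        }
      }
    }
    if (!improved) break
  }
  list(selected = sel, value = best)
}

#' Group selection by pairwise swaps maximizing OPV
#'
#' Starts from a random subset of the prefiltered population and repeatedly
#' scans swaps between a selected individual and every unselected one,
#' accepting any swap that strictly increases the group OPV, until a full
#' scan brings no improvement. Best of `restarts` random starts is returned.
#'
#' @inheritParams compute_ohv
#' @param S Number to select.
#' @param F GEBV prefilter fraction (see [prefilter_by_gebv()]).
#' @param seed Optional integer seed.
#' @param max_iters Maximum full scans per restart.
#' @param restarts Number of random restarts.
#' @return Integer vector of the `S` selected indices (unordered set).
#' @export
swap_optimize_opv <- function(pop, spec, blocks = spec$blocks, S, F = 0,
                              seed = NULL, max_iters = 50, restarts = 1) {
  if (is.null(blocks)) stop("a haplotype-block partition is required")
  surv <- prefilter_by_gebv(pop, spec, F, S = S)
  bs <- block_scores(pop, spec, blocks)
  obj <- function(sel) {
    sub <- bs[, hap_cols(sel), drop = FALSE]
    2 * sum(do.call(pmax, as.data.frame(sub)))
  }
  with_seed(seed, {
    best <- NULL
    for (rs in seq_len(restarts)) {
      res <- swap_search(surv, S, obj, ordered = FALSE, max_iters = max_iters)
      if (is.null(best) || res$value > best$value) best <- res
    }
    sort(best$selected)
  })
}

#' Selection and mating by pairwise swaps maximizing the look-ahead objective
#'
#' Like [swap_optimize_opv()] but the objective is the Monte-Carlo look-ahead
#' estimate [estimate_flas()] and the candidate is an ordered list whose
#' positions define the mate pairs: a swap replaces the individual at one
#' position, and (optionally) cross-pair position exchanges re-pair the
#' selected set without changing it. All candidates within one restart are
#' scored against the same sampled ancestry paths (common random numbers),
#' so accepted moves are genuinely non-decreasing in the shared-noise
#' objective; a move must improve it by more than `tol`.
#'
#' @inheritParams compute_gebv
#' @param S Number to select (even).
#' @param horizon Remaining generations `T - t`.
#' @param K,n_reps Monte-Carlo sample sizes, see [estimate_flas()].
#' @param F GEBV prefilter fraction (default 0: the whole population is
#'   searched).
#' @param seed Optional integer seed.
#' @param max_iters Maximum full scans per restart.
#' @param restarts Number of random restarts.
#' @param exchange_moves Scan re-pairing exchanges as well as swaps.
#' @param tol Minimal improvement for acceptance (guards against residual
#'   Monte-Carlo noise; default 0).
#' @inheritParams sample_terminal_gamete
#' @return A [MatingPlan] (ordered selection, progeny counts unset).
#' @export
swap_optimize_las <- function(pop, spec, S, horizon, K = 200, n_reps = 1,
                              F = 0, seed = NULL, max_iters = 50,
                              restarts = 1, exchange_moves = TRUE, tol = 0,
                              R_exponent = c("intermating", "horizon")) {
  if (S %% 2 != 0) stop("S must be even")
  surv <- prefilter_by_gebv(pop, spec, F, S = S)
  L <- n_loci(pop)
  R <- lookahead_R(spec$r, S, horizon, R_exponent)
  G <- 2L * K * n_reps
  with_seed(seed, {
    paths <- sample_ancestry_paths(L, S, spec$r, R, G)
    # Slot decomposition: a gamete's breeding value splits over ancestry
    # slots (position, homolog) as gv = sum_s contrib(s, individual in s).
    # Precomputing contrib for every candidate haplotype makes one candidate
    # evaluation 2S vector additions instead of an L x G gather.
    slot_contrib <- lapply(seq_len(2L * S), function(s) {
      crossprod((paths == s) * spec$beta, pop$haplo)  # G x 2N
    })
    rep_grp <- rep(seq_len(n_reps), each = K)
    odd <- c(TRUE, FALSE)
    obj <- function(sel) {
      cols <- hap_cols(sel)
      gv <- numeric(G)
      for (s in seq_len(2L * S)) gv <- gv + slot_contrib[[s]][, cols[s]]
      progeny <- gv[odd] + gv[!odd]
      if (n_reps == 1) max(progeny)
      else mean(vapply(split(progeny, rep_grp), max, numeric(1)))
    }
    best <- NULL
    for (rs in seq_len(restarts)) {
      res <- swap_search(surv, S, obj, ordered = TRUE,
                         exchange_moves = exchange_moves,
                         max_iters = max_iters, tol = tol)
      if (is.null(best) || res$value > best$value) best <- res
    }
    plan <- MatingPlan(best$selected)
    attr(plan, "objective") <- best$value
    plan
  })
}

#' Diversity-proportional progeny allocation
#'
#' Distributes a total progeny budget over the plan's crosses in proportion
#' to each pair's genetic diversity ([diversity()] on the pair), the idea
#' being that crosses with wider predicted progeny distributions deserve
#' more draws. Quotas are rounded by largest remainder; any cross rounded to
#' zero then receives one progeny taken from the currently largest
#' allocation, so every cross is realized. Equal diversities (or all-zero
#' diversities) give an equal split.
#'
#' @param plan A [MatingPlan].
#' @inheritParams compute_gebv
#' @param total Total progeny budget (>= number of pairs).
#' @return The plan with `n_progeny` filled in (sums to `total`).
#' @export
allocate_progenies <- function(plan, pop, spec, total) {
  np <- length(plan$selected) / 2
  if (total < np) stop("budget smaller than the number of crosses")
  d <- vapply(seq_len(np), function(p)
    diversity(pop, spec, subset = plan$selected[c(2 * p - 1, 2 * p)]),
    numeric(1))
  if (sum(d) == 0) d <- rep(1, np)
  quota <- total * d / sum(d)
  alloc <- floor(quota)
  rem <- total - sum(alloc)
  if (rem > 0) {
    extra <- order(quota - alloc, seq_len(np), decreasing = c(TRUE, FALSE),
                   method = "radix")[seq_len(rem)]
    alloc[extra] <- alloc[extra] + 1
  }
  while (any(alloc == 0)) {
    z <- which.max(alloc == 0)
    alloc[which.max(alloc)] <- alloc[which.max(alloc)] - 1
    alloc[z] <- alloc[z] + 1
  }
  MatingPlan(plan$selected, alloc)
}
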