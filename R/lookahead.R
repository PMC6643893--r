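#' Accumulated recombination over the look-ahead horizon
#'
#' Between the progeny generation and the terminal generation, random
#' intermating among the `S/2` families accumulates recombination between
#' adjacent loci. The effective interval-wise rate after `horizon` remaining
#' generations is `R[l] = (S - 2) * (1 - (1 - r[l])^horizon) / S`. With
#' `S = 2` there is a single family and no cross-family ancestry, so `R` is
#' identically 0.
#'
#' @param r Recombination-frequency vector (length `L - 1`).
#' @param S Number of selected parents (even, >= 2).
#' @param horizon Exponent of the closed form (number of accumulating
#'   meioses; `0` gives `R = 0`).
#' @return Numeric vector like `r`, entries in `[0, 1)`.
#' @export
#' @examples
#' accumulated_recomb(0.1, S = 20, horizon = 3)  # 18 * (1 - 0.9^3) / 20
accumulated_recomb <- function(r, S, horizon) {
  if (S < 2) stop("S must be >= 2")
  if (horizon < 0) stop("horizon must be >= 0")
  (S - 2) * (1 - (1 - r)^horizon) / S
}

#' Transition kernel of the gamete-ancestry chain
#'
#' One-step transition probability of the ancestry Markov chain that
#' describes a random terminal gamete: the state is the (parent, homolog)
#' pair contributing the allele at the current locus, with parents ordered so
#' that odd index `i` is mated with `i + 1`. Moving from locus `l` to
#' `l + 1`, the chain (a) keeps parent and homolog with probability
#' `(1 - r)^2 (1 - R)`, (b) switches homolog within the parent with
#' `r (1 - r) (1 - R)`, (c) moves to either homolog of the parent's mate with
#' `r (1 - R) / 2` each, or (d) moves to any homolog of another mate pair
#' with `R / (2 (S - 2))` each. Cases are distinguished in that order, so the
#' same-parent cases are never absorbed into the same-pair case. At the first
#' locus every one of the `2S` states has probability `1 / (2S)`.
#'
#' @param i0,m0 Current parent (1..S) and homolog (1..2).
#' @param i1,m1 Destination parent and homolog.
#' @param r_next Recombination frequency of the interval (in `[0, 0.5]`).
#' @param R_next Accumulated recombination of the interval (in `[0, 1)`).
#' @param S Number of selected parents.
#' @return The transition probability. For `S = 2` the cross-pair case has no
#'   valid destination and returns 0 (it is only reachable when `R > 0`,
#'   which [accumulated_recomb()] excludes for `S = 2`).
#' @export
transition_probability <- function(i0, m0, i1, m1, r_next, R_next, S) {
  r <- r_next; R <- R_next
  if (i0 == i1 && m0 == m1) return((1 - r)^2 * (1 - R))
  if (i0 == i1) return(r * (1 - r) * (1 - R))
  if (ceiling(i0 / 2) == ceiling(i1 / 2)) return(0.5 * r * (1 - R))
  if (S == 2) return(0)
  R / (2 * (S - 2))
}

#' Sample ancestry state paths of the terminal-gamete chain
#'
#' Draws `n` independent state paths of the gamete-ancestry chain over `L`
#' loci. States are encoded `s = 2 (i - 1) + m` for parent `i` in `1..S` and
#' homolog `m` in `1..2`. The paths depend only on `(r, R, S)` — not on
#' genotypes — which is what makes common-random-numbers comparison of
#' candidate selections possible: one path set can be re-indexed against any
#' ordered selection of `S` parents.
#'
#' @param L Number of loci.
#' @param S Number of parents (even).
#' @param r,R Interval vectors of length `L - 1` (see
#'   [accumulated_recomb()]).
#' @param n Number of paths.
#' @param seed Optional integer seed.
#' @return Integer matrix `L x n` of states in `1..2S`.
#' @export
sample_ancestry_paths <- function(L, S, r, R, n, seed = NULL) {
  S <- as.integer(S)
  if (S < 2 || S %% 2 != 0) stop("S must be even and >= 2")
  stopifnot(length(r) == L - 1 || L == 1, length(R) == length(r))
  if (S == 2 && any(R > 0))
    stop("S = 2 admits no cross-pair ancestry; R must be 0")
  with_seed(seed, {
    states <- matrix(0L, L, n)
    states[1, ] <- sample.int(2L * S, n, replace = TRUE)
    if (L > 1) for (l in 2:L) {
      s0 <- states[l - 1, ]
      rl <- r[l - 1]; Rl <- R[l - 1]
      i0 <- (s0 + 1L) %/% 2L
      pair0 <- (i0 + 1L) %/% 2L
      u <- stats::runif(n)
      jump <- u < Rl
      # conditional on staying within the mate pair, probabilities are
      # (1-r)^2 stay, r(1-r) other homolog, r/2 each mate homolog
      v <- stats::runif(n)
      p_stay <- (1 - rl)^2
      p_oth <- p_stay + rl * (1 - rl)
      p_m1 <- p_oth + rl / 2
      s1 <- s0
      oth <- !jump & v >= p_stay & v < p_oth
      s1[oth] <- s0[oth] + ifelse(s0[oth] %% 2L == 1L, 1L, -1L)
      mate_i <- i0 + ifelse(i0 %% 2L == 1L, 1L, -1L)
      mh1 <- !jump & v >= p_oth & v < p_m1
      s1[mh1] <- 2L * (mate_i[mh1] - 1L) + 1L
      mh2 <- !jump & v >= p_m1
      s1[mh2] <- 2L * mate_i[mh2]
      if (any(jump)) {
        k <- sample.int(2L * (S - 2L), sum(jump), replace = TRUE)
        base <- 4L * (pair0[jump] - 1L)
        s1[jump] <- k + ifelse(k > base, 4L, 0L)
      }
      states[l, ] <- s1
    }
    states
  })
}

# Interval-wise accumulated recombination used by the look-ahead evaluator.
# "intermating" counts only the meioses after the first one (horizon - 1 of
# them), matching the model's mixing generations: the first meiosis is
# resolved by the r terms of the transition kernel, and with horizon = 1 no
# intermating remains, so R = 0. "horizon" uses the deadline difference
# itself as the exponent (the printed closed form taken at face value).
lookahead_R <- function(r, S, horizon,
                        R_exponent = c("intermating", "horizon")) {
  if (horizon < 1) stop("horizon must be >= 1")
  R_exponent <- match.arg(R_exponent)
  accumulated_recomb(r, S, horizon - (R_exponent == "intermating"))
}

# Convert state paths to a gamete allele matrix for a given ordered selection.
# sel_haplo: L x 2S haplotype matrix of the ordered selected parents.
paths_to_alleles <- function(sel_haplo, states) {
  L <- nrow(states); n <- ncol(states)
  idx <- as.vector((states - 1L) * L) + rep.int(seq_len(L), n)
  matrix(sel_haplo[idx], L, n)
}

#' Sample a random terminal gamete
#'
#' Draws a gamete of the terminal generation for an ordered selection of `S`
#' mated parents (consecutive pairs are mates), per the gamete-ancestry chain
#' of [transition_probability()].
#'
#' @param selected A [Population] of the `S` selected parents, in mating
#'   order.
#' @param spec A [GenomeSpec].
#' @param horizon Remaining generations (>= 1).
#' @param n Number of gametes.
#' @param seed Optional integer seed.
#' @param R_exponent How accumulated recombination scales with the horizon:
#'   `"intermating"` (default) counts the `horizon - 1` meioses that follow
#'   the first one, so a one-generation horizon accumulates nothing;
#'   `"horizon"` uses the deadline difference itself as the exponent of the
#'   closed form.
#' @return Integer matrix `L x n` of gamete alleles (a vector if `n = 1`).
#' @export
sample_terminal_gamete <- function(selected, spec, horizon, n = 1, seed = NULL,
                                   R_exponent = c("intermating", "horizon")) {
  check_dims(selected, spec)
  S <- n_ind(selected)
  if (S %% 2 != 0) stop("the number of selected parents must be even")
  R <- lookahead_R(spec$r, S, horizon, R_exponent)
  st <- sample_ancestry_paths(n_loci(selected), S, spec$r, R, n, seed = seed)
  a <- paths_to_alleles(selected$haplo, st)
  if (n == 1) a[, 1] else a
}

#' Monte-Carlo estimate of the look-ahead objective
#'
#' `f_LAS` is the expected GEBV of the best offspring in the terminal
#' generation, given the ordered, paired selection and the remaining number
#' of generations. It is approximated by sampling `K` terminal progenies
#' (each the union of two independent terminal gametes) and taking the
#' highest GEBV; with `n_reps > 1` the maximum is averaged over repetitions.
#'
#' @inheritParams sample_terminal_gamete
#' @param K Terminal-population sample size per repetition (>= 1).
#' @param n_reps Number of repetitions averaged (1 reproduces the
#'   single-sample rule).
#' @param paths Optional precomputed state paths (`L x 2*K*n_reps`) from
#'   [sample_ancestry_paths()], for common-random-numbers comparisons.
#' @inheritParams sample_terminal_gamete
#' @return The estimated `f_LAS` (scalar).
#' @export
estimate_flas <- function(selected, spec, horizon, K = 200, n_reps = 1,
                          seed = NULL, paths = NULL,
                          R_exponent = c("intermating", "horizon")) {
  check_dims(selected, spec)
  if (K < 1) stop("K must be >= 1")
  S <- n_ind(selected)
  if (S %% 2 != 0) stop("the number of selected parents must be even")
  G <- 2L * K * n_reps
  if (is.null(paths)) {
    R <- lookahead_R(spec$r, S, horizon, R_exponent)
    paths <- sample_ancestry_paths(n_loci(selected), S, spec$r, R, G, seed = seed)
  } else {
    stopifnot(ncol(paths) == G, max(paths) <= 2L * S)
  }
  a <- paths_to_alleles(selected$haplo, paths)
  gv <- as.vector(crossprod(a, spec$beta))
  progeny <- gv[c(TRUE, FALSE)] + gv[c(FALSE, TRUE)]
  mean(vapply(split(progeny, rep(seq_len(n_reps), each = K)), max, numeric(1)))
}
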