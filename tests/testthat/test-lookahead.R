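# Exact enumeration oracle for the gamete-ancestry chain: probability of
# every state path over L loci, computed directly from the kernel.
enumerate_chain <- function(L, S, r, R) {
  states <- expand.grid(i = seq_len(S), m = 1:2)
  ns <- nrow(states)
  paths <- as.matrix(do.call(expand.grid, rep(list(seq_len(ns)), L)))
  probs <- apply(paths, 1, function(pth) {
    p <- 1 / (2 * S)
    for (l in seq_len(L - 1)) {
      a <- states[pth[l], ]; b <- states[pth[l + 1], ]
      p <- p * transition_probability(a$i, a$m, b$i, b$m, r[l], R[l], S)
    }
    p
  })
  list(paths = paths, probs = probs, states = states)
}

# Map a state-path matrix (L x n, encoded 2*(i-1)+m) to enumeration codes.
encode_paths <- function(st, S) {
  i <- (st + 1L) %/% 2L; m <- st - 2L * (i - 1L)
  # enumeration uses expand.grid(i, m) order: code = i + S * (m - 1)
  apply(i + S * (m - 1L), 2, paste, collapse = "-")
}

test_that("accumulated recombination follows the closed form", {
  expect_equal(accumulated_recomb(0.1, 20, 3), 18 * (1 - 0.9^3) / 20)
  expect_equal(accumulated_recomb(0.1, 20, 3), 0.2439, tolerance = 1e-6)
  expect_equal(accumulated_recomb(0, 7, 4), 0)        # no recombination
  expect_equal(accumulated_recomb(c(0.1, 0.5), 2, 9), c(0, 0))  # single family
  # horizon -> infinity approaches (S - 2) / S
  expect_equal(accumulated_recomb(0.2, 10, 1e6), 8 / 10, tolerance = 1e-12)
  # small r, small horizon: first-order (S - 2) * horizon * r / S
  expect_equal(accumulated_recomb(1e-5, 10, 3), 0.8 * 3e-5, tolerance = 1e-4)
})

test_that("transition kernel matches hand-computed case probabilities", {
  # r = 0.2, R = 0.3, S = 4, from parent 1 homolog 1
  expect_equal(transition_probability(1, 1, 1, 1, 0.2, 0.3, 4), 0.448)
  expect_equal(transition_probability(1, 1, 1, 2, 0.2, 0.3, 4), 0.112)
  expect_equal(transition_probability(1, 1, 2, 1, 0.2, 0.3, 4), 0.07)
  expect_equal(transition_probability(1, 1, 2, 2, 0.2, 0.3, 4), 0.07)
  expect_equal(transition_probability(1, 1, 3, 2, 0.2, 0.3, 4), 0.075)
  # r = 0, R = 0: the chain never moves
  expect_equal(transition_probability(2, 2, 2, 2, 0, 0, 8), 1)
  expect_equal(transition_probability(2, 2, 2, 1, 0, 0, 8), 0)
  # S = 2 has no cross-pair destination
  expect_equal(transition_probability(1, 1, 3, 1, 0.2, 0, 2), 0)
})

test_that("transition probabilities sum to one over all destinations", {
  for (S in c(2, 4, 20)) for (r in c(0, 0.1, 0.3, 0.5)) {
    Rs <- if (S == 2) 0 else c(0, 0.2, 0.8)
    for (R in Rs) {
      tot <- 0
      for (i1 in seq_len(S)) for (m1 in 1:2)
        tot <- tot + transition_probability(3 %% S + 1, 1, i1, m1, r, R, S)
      expect_equal(tot, 1, tolerance = 1e-12)
    }
  }
})

test_that("sampled ancestry paths match exact chain enumeration", {
  L <- 3; S <- 4
  r <- c(0.25, 0.4); R <- c(0.15, 0.3)
  en <- enumerate_chain(L, S, r, R)
  expect_equal(sum(en$probs), 1, tolerance = 1e-12)
  st <- sample_ancestry_paths(L, S, r, R, 20000, seed = 5)
  keys <- encode_paths(st, S)
  ekeys <- apply(en$paths, 1, function(pth)
    paste(en$states$i[pth] + S * (en$states$m[pth] - 1L), collapse = "-"))
  obs <- table(factor(keys, levels = ekeys))
  cs <- suppressWarnings(chisq.test(as.vector(obs), p = en$probs))
  expect_gt(cs$p.value, 0.01)
})

test_that("terminal gametes degenerate correctly", {
  spec <- toy_spec(c(1, 1, 1), r = c(0, 0))
  # S = 2, r = 0: uniform over the 4 parental haplotypes
  pop <- toy_pop(list(rep(1L, 3), rep(0L, 3)), list(rep(1L, 3), rep(1L, 3)))
  g <- sample_terminal_gamete(pop, spec, horizon = 2, n = 3000, seed = 1)
  tot <- colSums(g)
  expect_true(all(tot %in% c(0, 3)))          # intact haplotypes only
  expect_lt(abs(mean(tot == 0) - 0.25), 3 * sqrt(0.25 * 0.75 / 3000))

  # identical homozygous parents: the gamete is certain
  clones <- Population(matrix(rep(c(1L, 0L, 1L), 8), nrow = 3))
  spec2 <- toy_spec(c(1, 1, 1))
  g2 <- sample_terminal_gamete(clones, spec2, horizon = 3, n = 50, seed = 2)
  expect_true(all(g2 == c(1L, 0L, 1L)))

  expect_error(sample_terminal_gamete(subset_population(pop, 1), spec, 1),
               "even")
})

test_that("look-ahead estimate converges to the exact expectation", {
  # S = 2, r = 0, parents homozygous 'a' (GEBV 6) and 'b' (GEBV 0):
  # progeny is aa, ab, ba, bb with equal probability, so with K = 1 the
  # estimate has mean (6 + 3 + 3 + 0) / 4 = 3
  pop <- toy_pop(list(rep(1L, 3), rep(1L, 3)), list(rep(0L, 3), rep(0L, 3)))
  spec <- toy_spec(c(1, 1, 1), r = c(0, 0))
  est <- with_seed_test(9, replicate(3000, estimate_flas(pop, spec, 2, K = 1)))
  expect_lt(abs(mean(est) - 3), 3 * sd(est) / sqrt(3000))

  # degenerate population: estimate equals the shared GEBV exactly
  clones <- Population(matrix(rep(c(1L, 0L, 1L), 8), nrow = 3))
  spec2 <- toy_spec(c(1, 1, 1))
  expect_equal(estimate_flas(clones, spec2, 4, K = 7, seed = 1),
               unname(compute_gebv(clones, spec2)[1]))

  # fixed seed gives bit-identical estimates
  pop2 <- random_pop(20, 6, seed = 3)
  spec3 <- random_spec(20, seed = 4)
  e1 <- estimate_flas(pop2, spec3, 3, K = 40, n_reps = 2, seed = 77)
  e2 <- estimate_flas(pop2, spec3, 3, K = 40, n_reps = 2, seed = 77)
  expect_identical(e1, e2)
})

test_that("larger terminal samples increase the estimate in expectation", {
  pop <- random_pop(12, 4, seed = 13)
  spec <- random_spec(12, seed = 14)
  mean_k <- function(K) mean(vapply(1:300, function(s)
    estimate_flas(pop, spec, 2, K = K, seed = s), numeric(1)))
  expect_gt(mean_k(20), mean_k(2))
})

test_that("horizon exponent conventions differ only for short horizons", {
  r <- c(0.1, 0.2)
  expect_equal(lasgs:::lookahead_R(r, 10, 1, "intermating"), c(0, 0))
  expect_equal(lasgs:::lookahead_R(r, 10, 1, "horizon"),
               accumulated_recomb(r, 10, 1))
  expect_equal(lasgs:::lookahead_R(r, 10, 4, "intermating"),
               accumulated_recomb(r, 10, 3))
})
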