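# Brute-force subset maximizers used as oracles on tiny instances.
best_subset_by <- function(score_total, N, S) {
  subsets <- utils::combn(N, S)
  vals <- apply(subsets, 2, score_total)
  list(value = max(vals), subset = subsets[, which.max(vals)])
}

test_that("truncation selection takes the S largest with low-index ties", {
  expect_equal(truncation_select(c(5, 5, 3), 1), 1)
  expect_equal(truncation_select(c(1, 9, 4, 7), 2), c(2, 4))
  expect_equal(sort(truncation_select(c(2, 2, 2), 3)), 1:3)
  expect_error(truncation_select(c(1, 2), 3), "more individuals")
})

test_that("GEBV prefilter removes the stated fraction, high-index ties first", {
  pop <- random_pop(20, 10, seed = 1)
  spec <- random_spec(20, seed = 2)
  expect_equal(prefilter_by_gebv(pop, spec, 0), 1:10)
  surv7 <- prefilter_by_gebv(pop, spec, 0.7)
  expect_length(surv7, 3)
  g <- compute_gebv(pop, spec)
  expect_setequal(surv7, order(g, decreasing = TRUE)[1:3])
  expect_length(prefilter_by_gebv(pop, spec, 0.4), 6)
  # ties: equal scores drop the higher index first
  tied <- Population(matrix(0L, 2, 8))
  tspec <- toy_spec(c(1, 1))
  expect_equal(prefilter_by_gebv(tied, tspec, 0.5), 1:2)
  expect_error(prefilter_by_gebv(pop, spec, 0.7, S = 5), "fewer survivors")
})

test_that("random pairing realizes a uniform perfect matching", {
  expect_equal(sort(random_pairing(c(7, 3), seed = 1)$selected), c(3, 7))
  # 4 individuals: each of the 3 matchings with probability 1/3
  key <- function(sel) {
    pairs <- matrix(sel, 2)
    paste(sort(apply(pairs, 2, function(p) paste(sort(p), collapse = "-"))),
          collapse = "|")
  }
  ks <- vapply(1:30000, function(s) key(random_pairing(1:4, seed = s)$selected),
               character(1))
  freq <- table(ks) / length(ks)
  expect_length(freq, 3)
  expect_true(all(abs(freq - 1 / 3) < 3 * sqrt((1 / 3) * (2 / 3) / 30000)))
  expect_identical(random_pairing(1:6, seed = 5)$selected,
                   random_pairing(1:6, seed = 5)$selected)
  expect_error(random_pairing(1:3), "even number")
})

test_that("truncation equals brute-force subset maximization (separability)", {
  for (s in 1:4) {
    pop <- random_pop(12, 8, seed = 200 + s)
    spec <- random_spec(12, seed = 300 + s)
    blocks <- make_blocks(spec, 3)
    g <- compute_gebv(pop, spec)
    ohv <- compute_ohv(pop, spec, blocks)
    bf_g <- best_subset_by(function(idx) sum(g[idx]), 8, 4)
    bf_o <- best_subset_by(function(idx) sum(ohv[idx]), 8, 4)
    expect_equal(sum(g[truncation_select(g, 4)]), bf_g$value)
    expect_equal(sum(ohv[truncation_select(ohv, 4)]), bf_o$value)
  }
})

test_that("OPV swap heuristic reaches the exhaustive optimum on tiny instances", {
  hits <- 0
  for (s in 1:20) {
    pop <- random_pop(6, 8, seed = 400 + s)
    spec <- random_spec(6, seed = 500 + s)
    blocks <- seq_len(6)  # one block per locus
    bf <- best_subset_by(function(idx) compute_opv(pop, spec, blocks, idx), 8, 4)
    sel <- swap_optimize_opv(pop, spec, blocks, S = 4, seed = s, restarts = 5)
    got <- compute_opv(pop, spec, blocks, sel)
    expect_lte(got, bf$value + 1e-9)
    if (abs(got - bf$value) < 1e-9) hits <- hits + 1
  }
  expect_gte(hits, 19)
  # N = S: everything selected, no search
  pop <- random_pop(6, 4, seed = 9)
  spec <- random_spec(6, seed = 10)
  expect_setequal(swap_optimize_opv(pop, spec, 1:6, S = 4, seed = 1), 1:4)
})

test_that("LAS swap heuristic finds the best pair under common random numbers", {
  pop <- random_pop(4, 6, seed = 600)
  spec <- random_spec(4, seed = 601)
  # evaluate all 15 unordered pairs with the same ancestry paths as the
  # search (S = 2: state paths depend only on r, R = 0, so CRN paths from
  # any seed rank pairs identically given enough samples)
  K <- 400
  R <- accumulated_recomb(spec$r, 2, 1)  # 0 for S = 2
  paths <- sample_ancestry_paths(4, 2, spec$r, R, 2 * K, seed = 55)
  pairs <- utils::combn(6, 2)
  vals <- apply(pairs, 2, function(p)
    estimate_flas(subset_population(pop, p), spec, horizon = 2, K = K,
                  paths = paths))
  best_pair <- sort(pairs[, which.max(vals)])
  plan <- swap_optimize_las(pop, spec, S = 2, horizon = 2, K = K,
                            seed = 55, restarts = 3)
  expect_equal(sort(plan$selected), best_pair)

  # flat objective: identical individuals everywhere, returns without error
  clones <- Population(matrix(rep(c(1L, 0L, 1L, 1L), 12), nrow = 4))
  plan2 <- swap_optimize_las(clones, spec, S = 2, horizon = 1, K = 10, seed = 1)
  expect_length(plan2$selected, 2)
})

test_that("progeny allocation is diversity-proportional with safeguards", {
  # three crosses with pair diversities 3, 1, 0 and total 8:
  # quotas (6, 2, 0) -> floor rule moves one progeny from the largest
  spec <- toy_spec(c(1, 1, 1, 1), r = rep(0.5, 3))
  h <- function(v) list(as.integer(v), as.integer(v))
  # pair 1 diversity 3: differs at loci 1-3; pair 2 at locus 4; pair 3 equal
  pop <- toy_pop(h(c(1, 1, 1, 0)), h(c(0, 0, 0, 0)),
                 h(c(1, 1, 1, 1)), h(c(1, 1, 1, 0)),
                 h(c(0, 0, 0, 1)), h(c(0, 0, 0, 1)))
  plan <- MatingPlan(1:6)
  out <- allocate_progenies(plan, pop, spec, 8)
  expect_equal(out$n_progeny, c(5L, 2L, 1L))

  # all-zero diversities: equal split
  clones <- toy_pop(h(c(1, 0, 1, 0)), h(c(1, 0, 1, 0)),
                    h(c(1, 0, 1, 0)), h(c(1, 0, 1, 0)),
                    h(c(1, 0, 1, 0)), h(c(1, 0, 1, 0)))
  expect_equal(allocate_progenies(plan, clones, spec, 9)$n_progeny,
               c(3L, 3L, 3L))

  # invariant: positive integers summing to the budget
  for (s in 1:5) {
    pop <- random_pop(10, 8, seed = 700 + s)
    rspec <- random_spec(10, seed = 800 + s)
    out <- allocate_progenies(MatingPlan(1:8), pop, rspec, 13)
    expect_equal(sum(out$n_progeny), 13)
    expect_true(all(out$n_progeny >= 1))
  }
  expect_error(allocate_progenies(MatingPlan(1:6), pop, rspec, 2), "budget")
})
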