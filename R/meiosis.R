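#' Sample a gamete from one parent
#'
#' Gamete formation follows a two-state Markov chain along the genome: the
#' homolog contributing locus 1 is chosen fairly, and at each interval the
#' contributing homolog switches with probability equal to the local
#' recombination frequency. No crossover interference and no mutation are
#' modelled.
#'
#' @param hapA,hapB The parent's two haplotypes (0/1 vectors of length `L`).
#' @param r Recombination-frequency vector of length `L - 1`.
#' @param seed Optional integer seed for a private RNG stream.
#' @param origin If `TRUE`, attach the homolog-of-origin index (1/2 per
#'   locus) as attribute `"origin"`.
#' @return Integer 0/1 vector of length `L` (the gamete).
#' @export
#' @examples
#' g <- sample_gamete(c(1L, 1L, 0L), c(0L, 0L, 1L), r = c(0.1, 0.1), seed = 1)
sample_gamete <- function(hapA, hapB, r, seed = NULL, origin = FALSE) {
  g <- with_seed(seed, sample_gametes(hapA, hapB, r, n = 1L, origin = origin))
  out <- g$gametes[, 1]
  if (origin) attr(out, "origin") <- g$origin[, 1]
  out
}

# Batch gamete sampler: n independent gametes from one parent, vectorized
# across gametes. Returns list(gametes = L x n matrix, origin = L x n or NULL).
sample_gametes <- function(hapA, hapB, r, n, origin = FALSE) {
  L <- length(hapA)
  stopifnot(length(hapB) == L, length(r) == max(L - 1, 0), n >= 1)
  first <- sample(0:1, n, replace = TRUE)
  if (L > 1) {
    sw <- matrix(stats::rbinom((L - 1) * n, 1L, rep(r, n)), L - 1, n)
    J <- apply(rbind(first, sw), 2, cumsum) %% 2L
  } else {
    J <- matrix(first, 1, n)
  }
  P <- cbind(as.integer(hapA), as.integer(hapB))
  gam <- matrix(P[cbind(rep.int(seq_len(L), n), as.vector(J) + 1L)], L, n)
  list(gametes = gam, origin = if (origin) J + 1L else NULL)
}

#' Cross two individuals
#'
#' Produces `n_progeny` independent progenies; each progeny pairs one gamete
#' from parent `i` with one from parent `j`. Selfing (`i == j`) is allowed.
#'
#' @param pop A [Population].
#' @param i,j Parent indices (may be equal).
#' @param n_progeny Number of progenies (>= 1).
#' @param spec The [GenomeSpec] supplying the recombination vector.
#' @param seed Optional integer seed.
#' @return A [Population] of the progenies.
#' @export
cross <- function(pop, i, j, n_progeny, spec, seed = NULL) {
  check_dims(pop, spec)
  if (n_progeny < 1) stop("n_progeny must be >= 1")
  if (any(c(i, j) < 1 | c(i, j) > n_ind(pop))) stop("parent index out of range")
  with_seed(seed, {
    H <- pop$haplo
    gi <- sample_gametes(H[, 2 * i - 1], H[, 2 * i], spec$r, n_progeny)$gametes
    gj <- sample_gametes(H[, 2 * j - 1], H[, 2 * j], spec$r, n_progeny)$gametes
    haplo <- matrix(0L, n_loci(pop), 2 * n_progeny)
    haplo[, c(TRUE, FALSE)] <- gi
    haplo[, c(FALSE, TRUE)] <- gj
    Population(haplo,
               ids = paste0(pop$ids[i], "x", pop$ids[j], ".", seq_len(n_progeny)))
  })
}
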