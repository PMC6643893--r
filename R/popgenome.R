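#' Phased diploid population
#'
#' A `Population` stores phased biallelic genotypes as an `L x 2N` integer
#' matrix of 0/1 allele codes (1 = major allele). Columns `2n - 1` and `2n`
#' are the two homologs of individual `n`; rows follow the locus order of the
#' accompanying [GenomeSpec].
#'
#' @param haplo Integer/numeric matrix, `L` rows (loci) by `2N` columns
#'   (haplotypes), entries 0 or 1.
#' @param ids Character vector of `N` individual labels (defaults to
#'   `ind1..indN`).
#' @return An object of class `Population`.
#' @export
#' @examples
#' pop <- Population(matrix(c(1, 0, 1, 1, 1, 0), nrow = 3, ncol = 2))
#' n_ind(pop)
Population <- function(haplo, ids = NULL) {
  haplo <- as.matrix(haplo)
  if (ncol(haplo) %% 2 != 0)
    stop("haplotype matrix must have an even number of columns (2 per individual)")
  if (length(haplo) && !all(haplo %in% c(0, 1)))
    stop("genotypes must be phased 0/1 calls; missing or non-biallelic codes are not supported")
  storage.mode(haplo) <- "integer"
  dimnames(haplo) <- NULL
  n <- ncol(haplo) / 2
  if (is.null(ids)) ids <- paste0("ind", seq_len(n))
  if (length(ids) != n) stop("ids length must equal the number of individuals")
  structure(list(haplo = haplo, ids = as.character(ids)), class = "Population")
}

#' @export
print.Population <- function(x, ...) {
  cat(sprintf("Population: %d individuals, %d loci (phased diploid)\n",
              n_ind(x), n_loci(x)))
  invisible(x)
}

#' @rdname Population
#' @param pop A `Population`.
#' @export
n_ind <- function(pop) ncol(pop$haplo) / 2L

#' @rdname Population
#' @export
n_loci <- function(pop) nrow(pop$haplo)

# Column indices of the two homologs of individuals `idx`.
hap_cols <- function(idx) as.vector(rbind(2L * idx - 1L, 2L * idx))

#' Subset a population by individual
#'
#' @param pop A [Population].
#' @param idx Integer indices of individuals to keep, in the requested order
#'   (duplicates allowed).
#' @return A `Population` restricted to `idx`.
#' @export
subset_population <- function(pop, idx) {
  idx <- as.integer(idx)
  if (any(idx < 1 | idx > n_ind(pop))) stop("individual index out of range")
  Population(pop$haplo[, hap_cols(idx), drop = FALSE], ids = pop$ids[idx])
}

#' Genome specification: map, effects, recombination
#'
#' A `GenomeSpec` holds the marker metadata shared by a campaign: locus ids in
#' a single genome-wide order (chromosome-major, position-minor), chromosome
#' assignment, genetic-map positions in centimorgans, additive effects of the
#' major allele (`beta`, minor allele effect 0), the recombination-frequency
#' vector `r` between adjacent loci (length `L - 1`, entries in `[0, 0.5]`,
#' exactly 0.5 across chromosome boundaries), and an optional haplotype-block
#' assignment.
#'
#' @param loci Character marker ids, length `L`.
#' @param chrom Chromosome id per locus.
#' @param pos_cM Numeric map position per locus (cM), non-decreasing within a
#'   chromosome.
#' @param beta Numeric effect of the major allele per locus (trait units).
#' @param r Optional recombination vector; computed via [map_to_recomb()] when
#'   omitted.
#' @param blocks Optional integer block id per locus (contiguous, within
#'   chromosome); see [make_blocks()].
#' @param mapping_function Mapping function used when `r` must be derived.
#' @return An object of class `GenomeSpec`.
#' @export
GenomeSpec <- function(loci, chrom, pos_cM, beta, r = NULL, blocks = NULL,
                       mapping_function = c("haldane", "kosambi", "direct")) {
  L <- length(loci)
  stopifnot(length(chrom) == L, length(pos_cM) == L, length(beta) == L)
  spec <- structure(
    list(loci = as.character(loci), chrom = as.character(chrom),
         pos_cM = as.numeric(pos_cM), beta = as.numeric(beta),
         r = NULL, blocks = blocks),
    class = "GenomeSpec")
  spl <- split(spec$pos_cM, factor(spec$chrom, levels = unique(spec$chrom)))
  if (any(vapply(spl, function(p) is.unsorted(p), logical(1))))
    stop("map positions must be non-decreasing within each chromosome")
  if (is.null(r)) {
    spec$r <- map_to_recomb(spec, match.arg(mapping_function))
  } else {
    r <- as.numeric(r)
    if (length(r) != max(L - 1, 0)) stop("r must have length L - 1")
    if (any(r < 0 | r > 0.5)) stop("recombination frequencies must lie in [0, 0.5]")
    spec$r <- r
  }
  spec
}

#' @export
print.GenomeSpec <- function(x, ...) {
  cat(sprintf("GenomeSpec: %d loci on %d chromosome(s); %d nonzero effects\n",
              length(x$loci), length(unique(x$chrom)), sum(x$beta != 0)))
  invisible(x)
}

# Logical vector, length L - 1: TRUE where interval l..l+1 crosses chromosomes.
chrom_boundaries <- function(spec) {
  L <- length(spec$loci)
  if (L < 2) return(logical(0))
  spec$chrom[-L] != spec$chrom[-1]
}

#' Convert map distances to recombination frequencies
#'
#' Adjacent-locus cM distances are converted with a mapping function:
#' Haldane `r = 0.5 (1 - exp(-2d/100))` (no crossover interference, matching
#' the meiosis model used throughout), Kosambi `r = 0.5 tanh(2d/100)`, or
#' `direct`, for maps whose position column is already a cumulative
#' recombination fraction so that adjacent differences are used as `r` as-is.
#' Intervals spanning a chromosome boundary are set to 0.5 (free
#' recombination); all entries are clamped to `[0, 0.5]`.
#'
#' @param spec A [GenomeSpec] with populated `pos_cM`.
#' @param mapping_function One of `"haldane"`, `"kosambi"`, `"direct"`.
#' @return Numeric vector of length `L - 1`.
#' @export
#' @examples
#' sp <- GenomeSpec("m1", 1, 0, 1)
#' sp2 <- GenomeSpec(c("m1", "m2"), c(1, 1), c(0, 10), c(1, 1))
#' sp2$r  # Haldane: 0.5 * (1 - exp(-0.2))
map_to_recomb <- function(spec,
                          mapping_function = c("haldane", "kosambi", "direct")) {
  mapping_function <- match.arg(mapping_function)
  L <- length(spec$loci)
  if (L < 2) return(numeric(0))
  d <- diff(spec$pos_cM)
  bnd <- chrom_boundaries(spec)
  if (any(d < 0 & !bnd))
    stop("negative map distance within a chromosome")
  r <- switch(mapping_function,
    haldane = 0.5 * (1 - exp(-2 * d / 100)),
    kosambi = 0.5 * tanh(2 * d / 100),
    direct  = d)
  r <- pmin(pmax(r, 0), 0.5)
  r[bnd] <- 0.5
  r
}

#' Genomic estimated breeding values
#'
#' The GEBV of an individual is the sum of major-allele effects over both
#' homologs and all loci: `GEBV[n] = sum_l sum_m G[l, m, n] * beta[l]`.
#'
#' @param pop A [Population].
#' @param spec A [GenomeSpec] (same locus order).
#' @return Numeric vector of length `N`, named by individual id.
#' @export
#' @examples
#' pop <- Population(matrix(c(1, 0, 1, 1, 1, 0), nrow = 3))
#' spec <- GenomeSpec(paste0("m", 1:3), rep(1, 3), c(0, 10, 20), c(2, -1, 0.5))
#' compute_gebv(pop, spec)  # 2*2 + 1*(-1) + 1*0.5 = 3.5
compute_gebv <- function(pop, spec) {
  check_dims(pop, spec)
  gv <- as.vector(crossprod(pop$haplo, spec$beta))
  out <- gv[c(TRUE, FALSE)] + gv[c(FALSE, TRUE)]
  names(out) <- pop$ids
  out
}

check_dims <- function(pop, spec) {
  if (n_loci(pop) != length(spec$loci))
    stop("Population and GenomeSpec disagree on the number of loci")
  invisible(TRUE)
}

#' Selection limits of a population
#'
#' The upper selection limit is the GEBV of the best genotype assemblable from
#' alleles currently present in the population (homozygous for the per-locus
#' best allele): `2 * sum_l max_{n,m} G[l, m, n] * beta[l]`; the lower limit
#' uses the per-locus minimum. They bound every achievable descendant GEBV
#' absent mutation.
#'
#' @inheritParams compute_gebv
#' @return Named numeric vector `c(lower =, upper =)`.
#' @export
selection_limits <- function(pop, spec) {
  check_dims(pop, spec)
  has1 <- rowSums(pop$haplo) > 0L
  has0 <- rowSums(pop$haplo) < ncol(pop$haplo)
  # per-locus value set is {0 if any 0 present} U {beta if any 1 present}
  vmax <- ifelse(has1 & has0, pmax(spec$beta, 0), ifelse(has1, spec$beta, 0))
  vmin <- ifelse(has1 & has0, pmin(spec$beta, 0), ifelse(has1, spec$beta, 0))
  c(lower = 2 * sum(vmin), upper = 2 * sum(vmax))
}

#' Rescale marker effects to a target maximum potential
#'
#' Uniformly rescales `beta` so that the upper selection limit of `pop`
#' equals `target` (by default 100), leaving genotypes untouched. This puts
#' campaigns on a common scale where the founder population's maximum
#' potential reads as a percentage.
#'
#' @inheritParams compute_gebv
#' @param target Desired upper selection limit (default 100).
#' @return The rescaled [GenomeSpec].
#' @export
scale_to_potential <- function(pop, spec, target = 100) {
  up <- selection_limits(pop, spec)[["upper"]]
  if (up == 0)
    stop("upper selection limit is 0; effects cannot be scaled")
  if (up < 0)
    stop("upper selection limit is negative; a uniform rescale cannot reach a positive target")
  spec$beta <- spec$beta * (target / up)
  spec
}

#' Split each chromosome into contiguous haplotype blocks
#'
#' Each chromosome's loci are split into `B` contiguous runs of near-equal
#' locus count (any remainder spread over the first blocks). Block ids are
#' unique genome-wide and never span chromosomes.
#'
#' @param spec A [GenomeSpec].
#' @param B Number of blocks per chromosome.
#' @return Integer vector of block ids, length `L`.
#' @export
make_blocks <- function(spec, B) {
  B <- as.integer(B)
  if (B < 1) stop("B must be >= 1")
  chrom <- factor(spec$chrom, levels = unique(spec$chrom))
  offset <- 0L
  out <- integer(length(spec$loci))
  for (ch in levels(chrom)) {
    i <- which(chrom == ch)
    nb <- min(B, length(i))
    base <- length(i) %/% nb
    rem <- length(i) %% nb
    sizes <- rep(base, nb) + c(rep(1L, rem), rep(0L, nb - rem))
    out[i] <- offset + rep(seq_len(nb), times = sizes)
    offset <- offset + nb
  }
  out
}
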