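#' Rare-allele-weighted breeding values
#'
#' Weighted genomic selection divides each effect by the population frequency
#' of the favorable allele, `beta[l] / max(w[l], 1/N)`, so rare favorable
#' alleles weigh more. By default the favorable allele is the coded-1 major
#' allele irrespective of the sign of `beta` (so `w` is the major-allele
#' frequency over all `2N` haplotypes); `favorable = "sign"` instead counts
#' the allele whose effect is positive.
#'
#' @inheritParams compute_gebv
#' @param favorable `"major"` (default) or `"sign"`.
#' @return Numeric vector of length `N`.
#' @export
weighted_gebv <- function(pop, spec, favorable = c("major", "sign")) {
  check_dims(pop, spec)
  favorable <- match.arg(favorable)
  N <- n_ind(pop)
  w <- rowMeans(pop$haplo)
  if (favorable == "sign") w <- ifelse(spec$beta < 0, 1 - w, w)
  b <- spec$beta / pmax(w, 1 / N)
  gv <- as.vector(crossprod(pop$haplo, b))
  out <- gv[c(TRUE, FALSE)] + gv[c(FALSE, TRUE)]
  names(out) <- pop$ids
  out
}

# Per-haplotype block scores: nblocks x 2N matrix of sum_{l in block} G * beta.
block_scores <- function(pop, spec, blocks) {
  rowsum(pop$haplo * spec$beta, group = blocks, reorder = TRUE)
}

#' Optimal haploid values
#'
#' The OHV of an individual is the GEBV of the best doubled haploid it could
#' produce when recombination is allowed between, but not within, haplotype
#' blocks: `OHV[n] = 2 * sum_b max_m sum_{l in H(b)} G[l, m, n] * beta[l]`.
#'
#' @inheritParams compute_gebv
#' @param blocks Integer block id per locus (see [make_blocks()]); defaults
#'   to `spec$blocks`.
#' @return Numeric vector of length `N`.
#' @export
compute_ohv <- function(pop, spec, blocks = spec$blocks) {
  check_dims(pop, spec)
  if (is.null(blocks)) stop("a haplotype-block partition is required (see make_blocks)")
  bs <- block_scores(pop, spec, blocks)
  a <- bs[, c(TRUE, FALSE), drop = FALSE]
  b <- bs[, c(FALSE, TRUE), drop = FALSE]
  out <- 2 * colSums(pmax(a, b))
  names(out) <- pop$ids
  out
}

#' Optimal population value of a group
#'
#' The OPV of a set of individuals is the GEBV of the best progeny derivable
#' from the set after unlimited generations, taking the best haplotype-block
#' score over all members and homologs:
#' `OPV = 2 * sum_b max_{n in subset, m} sum_{l in H(b)} G[l, m, n] * beta[l]`.
#'
#' @inheritParams compute_ohv
#' @param subset Integer indices of the group (default: all individuals).
#' @return A single numeric value.
#' @export
compute_opv <- function(pop, spec, blocks = spec$blocks,
                        subset = seq_len(n_ind(pop))) {
  check_dims(pop, spec)
  if (is.null(blocks)) stop("a haplotype-block partition is required (see make_blocks)")
  if (length(subset) == 0) stop("subset must be non-empty")
  bs <- block_scores(pop, spec, blocks)[, hap_cols(as.integer(subset)), drop = FALSE]
  2 * sum(apply(bs, 1, max))
}

#' Genetic diversity of a group
#'
#' The diversity measure is the aggregated per-locus range of allele-effect
#' values over the group: `sum_l [max_{n,m} G[l,m,n] beta[l] - min_{n,m}
#' G[l,m,n] beta[l]]`, i.e. the sum of `|beta|` over loci still segregating
#' in the group. For a mate pair it predicts the spread of the progeny
#' distribution and drives progeny allocation. `by = "block"` aggregates the
#' range over haplotype-block scores instead of single loci.
#'
#' @inheritParams compute_ohv
#' @param subset Integer indices of the group (default: all individuals).
#' @param by `"locus"` (the printed per-locus form, default) or `"block"`.
#' @return A single non-negative numeric value.
#' @export
diversity <- function(pop, spec, subset = seq_len(n_ind(pop)),
                      by = c("locus", "block"), blocks = spec$blocks) {
  check_dims(pop, spec)
  by <- match.arg(by)
  if (length(subset) == 0) stop("subset must be non-empty")
  cols <- hap_cols(as.integer(subset))
  if (by == "locus") {
    sub <- pop$haplo[, cols, drop = FALSE]
    cnt <- rowSums(sub)
    segregating <- cnt > 0L & cnt < length(cols)
    return(sum(abs(spec$beta)[segregating]))
  }
  if (is.null(blocks)) stop("by = 'block' requires a block partition")
  bs <- block_scores(pop, spec, blocks)[, cols, drop = FALSE]
  sum(apply(bs, 1, max) - apply(bs, 1, min))
}
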