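#' Synthetic-scenario specification
#'
#' Parameters of a generated founder scenario: population and genome size,
#' chromosome count and genetic length, the per-locus major-allele frequency
#' distribution, and a sparse marker-effect model. The defaults emulate an
#' elite inbred founder panel at desk scale: 50 fully homozygous founders,
#' 300 markers on 5 chromosomes of 150 cM, major-allele frequencies uniform
#' on (0.5, 0.95), and normal effects at 20% of loci (mixed signs), later
#' rescaled so the founders' maximum potential is 100.
#'
#' @param N Number of founder individuals.
#' @param L Number of marker loci.
#' @param n_chrom Number of chromosomes.
#' @param chrom_length_cM Genetic length per chromosome (cM).
#' @param maf_range Range of the per-locus major-allele frequency (drawn
#'   uniformly; values in `[0.5, 1]`).
#' @param frac_nonzero Fraction of loci with a nonzero effect.
#' @param effect_sd Standard deviation of the (normal) nonzero effects.
#' @param prop_positive Probability a nonzero effect is positive (0.5 gives
#'   the symmetric-normal mix).
#' @param inbred Generate fully homozygous founders (default), or outbred
#'   founders with two independent haplotypes.
#' @return An object of class `ScenarioSpec`.
#' @export
scenario_spec <- function(N = 50, L = 300, n_chrom = 5, chrom_length_cM = 150,
                          maf_range = c(0.5, 0.95), frac_nonzero = 0.2,
                          effect_sd = 1, prop_positive = 0.5, inbred = TRUE) {
  stopifnot(N >= 1, L >= n_chrom, n_chrom >= 1, chrom_length_cM >= 0,
            frac_nonzero > 0, frac_nonzero <= 1,
            all(maf_range >= 0.5), all(maf_range <= 1))
  structure(list(N = N, L = L, n_chrom = n_chrom,
                 chrom_length_cM = chrom_length_cM, maf_range = maf_range,
                 frac_nonzero = frac_nonzero, effect_sd = effect_sd,
                 prop_positive = prop_positive, inbred = inbred),
            class = "ScenarioSpec")
}

#' Generate a synthetic genetic map
#'
#' Loci are spread over the chromosomes in near-equal counts and placed
#' uniformly at random along each chromosome's genetic length, then sorted;
#' recombination frequencies come from [map_to_recomb()] (Haldane), with 0.5
#' across chromosome boundaries.
#'
#' @param sspec A [scenario_spec()].
#' @param beta Optional effect vector to install (zeros by default;
#'   [make_scenario()] fills it in).
#' @param seed Optional integer seed.
#' @return A [GenomeSpec].
#' @export
synth_map <- function(sspec, beta = NULL, seed = NULL) {
  counts <- equal_split(sspec$L, sspec$n_chrom)
  pos <- with_seed(seed, lapply(counts, function(k)
    sort(stats::runif(k, 0, sspec$chrom_length_cM))))
  GenomeSpec(loci = paste0("m", seq_len(sspec$L)),
             chrom = rep(paste0("chr", seq_len(sspec$n_chrom)), counts),
             pos_cM = unlist(pos),
             beta = beta %||% numeric(sspec$L))
}

#' Generate sparse marker effects
#'
#' Each locus carries a nonzero effect with probability `frac_nonzero`;
#' nonzero effects are half-normal with scale `effect_sd`, signed positive
#' with probability `prop_positive`. This mimics the sparse architecture of
#' Bayesian whole-genome regression estimates.
#'
#' @inheritParams synth_map
#' @return Numeric vector of length `L`.
#' @export
synth_effects <- function(sspec, seed = NULL) {
  with_seed(seed, {
    nz <- stats::runif(sspec$L) < sspec$frac_nonzero
    eff <- numeric(sspec$L)
    sgn <- ifelse(stats::runif(sum(nz)) < sspec$prop_positive, 1, -1)
    eff[nz] <- sgn * abs(stats::rnorm(sum(nz), 0, sspec$effect_sd))
    eff
  })
}

#' Generate a founder population
#'
#' Haplotypes are drawn independently per locus with the locus's major-allele
#' frequency (itself drawn from `maf_range`). In `inbred` mode (default) one
#' haplotype is drawn per individual and copied to both homologs, emulating a
#' panel of fully homozygous inbred lines; otherwise the two homologs are
#' independent.
#'
#' @inheritParams synth_map
#' @return A [Population] of `N` individuals.
#' @export
synth_population <- function(sspec, seed = NULL) {
  with_seed(seed, {
    p <- stats::runif(sspec$L, sspec$maf_range[1], sspec$maf_range[2])
    nh <- if (sspec$inbred) sspec$N else 2 * sspec$N
    draws <- matrix(stats::rbinom(sspec$L * nh, 1L, rep(p, nh)), sspec$L, nh)
    haplo <- if (sspec$inbred) draws[, rep(seq_len(sspec$N), each = 2)] else draws
    Population(haplo)
  })
}

#' Build a complete synthetic scenario
#'
#' Generates map, effects and founders, and rescales the effects so the
#' founder population's upper selection limit equals `target` (default 100).
#' Optionally writes the scenario as the CSV dialects of [write_scenario()]
#' plus a JSON manifest recording the parameters and seed.
#'
#' @inheritParams synth_map
#' @param target Maximum potential after scaling.
#' @param dir Optional output directory for CSV files and manifest.
#' @return A list with `pop` ([Population]) and `spec` ([GenomeSpec]).
#' @export
#' @examples
#' sc <- make_scenario(scenario_spec(N = 10, L = 40, n_chrom = 2), seed = 7)
#' selection_limits(sc$pop, sc$spec)[["upper"]]  # 100
make_scenario <- function(sspec = scenario_spec(), seed = NULL, target = 100,
                          dir = NULL) {
  spec <- synth_map(sspec, seed = child_seed(seed, 1))
  spec$beta <- synth_effects(sspec, seed = child_seed(seed, 2))
  pop <- synth_population(sspec, seed = child_seed(seed, 3))
  if (selection_limits(pop, spec)[["upper"]] == 0)
    spec$beta[which.max(rowSums(pop$haplo) > 0)] <- 1  # degenerate draw guard
  spec <- scale_to_potential(pop, spec, target = target)
  if (!is.null(dir)) {
    paths <- write_scenario(pop, spec, dir)
    manifest <- c(unclass(sspec),
                  list(seed = seed, target = target,
                       files = as.list(basename(paths))))
    jsonlite::write_json(manifest, file.path(dir, "scenario_manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  list(pop = pop, spec = spec)
}
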