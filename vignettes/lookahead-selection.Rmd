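---
title: "Look-ahead selection: model, estimator and simulator design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Look-ahead selection: model, estimator and simulator design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lasgs)
```

## The selection problem

A breeding campaign starts from `N` phased diploid individuals with known
per-locus additive effects `β` (attached to the major allele; the minor
allele contributes 0) and a genetic map that fixes the recombination
frequency `r_l ∈ [0, 0.5]` between adjacent loci. Each generation, `S`
parents are selected and mated in `S/2` monogamous pairs, a fixed progeny
budget is spent across the crosses, and the progenies replace the
population. The campaign ends at a deadline `T`.

Classical criteria score candidates individually — GEBV (truncation
selection), rare-allele-weighted GEBV, or the optimal haploid value, which
takes the better homolog block by block and doubles it — or score a group by
its ultimate potential (the optimal population value). None of them react to
how many generations remain. Look-ahead selection scores an *ordered, paired*
candidate selection by the expected GEBV of the best offspring in the
terminal generation, and therefore trades immediate gain against convertible
diversity differently at `T − t = 5` than at `T − t = 1`.

## The gamete-ancestry chain

Scoring a candidate selection requires the distribution of a random gamete
entering the terminal generation. Under the look-ahead model's simplifying
assumptions — each selected pair contributes one progeny in the next
generation, after which the progenies intermate at random (selfing allowed),
one progeny each — that distribution is a Markov chain over ancestry states
`(parent i, homolog m)`:

* at the first locus all `2S` states are equally likely;
* between adjacent loci the chain stays on the same homolog with probability
  `(1 − r)² (1 − R)`, switches homolog within the parent with
  `r (1 − r) (1 − R)`, moves to either homolog of the parent's mate with
  `r (1 − R) / 2` each, and jumps to any homolog of another pair with
  `R / (2 (S − 2))` each,

where `R` is the recombination accumulated by the intermating generations.
The four cases are tested in that order, so the same-parent cases are never
absorbed into the same-pair case. Summing the four cases gives exactly 1 for
every `(r, R, S)` with `S > 2`; with `S = 2` no "other pair" exists and the
kernel is only normalized when `R = 0`, which is also the only value the
closed form below can produce — the unit tests check the identity on a grid
restricted accordingly.

The closed form for the accumulated term is

```
R_l = (S − 2) · [1 − (1 − r_l)^h] / S .
```

`accumulated_recomb()` implements exactly this expression with the exponent
`h` supplied by the caller. The substantive question is what `h` should be
when the horizon is `T − t` generations. The package defaults to
`h = T − t − 1` (`R_exponent = "intermating"`): the first meiosis out of the
selected parents is already resolved by the `r` terms of the kernel, and only
the `T − t − 1` subsequent meioses mix across families. Two observations
support this accounting. First, simulating the look-ahead model explicitly
(pairs produce one progeny, progenies intermate, terminal gamete drawn at
generation `T − 1`) and comparing two-locus joint distributions on tiny
genomes shows the `h = T − t − 1` chain roughly halves the total-variation
error of the `h = T − t` alternative at horizons 2 and 3. Second, with
`h = T − t` a horizon-1 evaluation has `R > 0`: a terminal gamete would
mosaic across all `S` parents even though only a single meiosis remains, so
the objective over-values cross-parent complementarity precisely when it can
no longer be realized, and the characteristic late-campaign consolidation
onto high-GEBV parents never happens. The alternative exponent remains
available (`R_exponent = "horizon"`) for sensitivity analysis.

Because the state paths depend only on `(r, R, S)` — not on genotypes — a
path set can be sampled once and re-indexed against any candidate selection.
This is what makes common-random-numbers comparison cheap (next section).

## Estimating and maximizing f_LAS

`estimate_flas()` draws `K` terminal progenies (each the union of two
independent terminal gametes), takes the highest GEBV, and averages that
maximum over `n_reps` independent repetitions. `n_reps = 1` is the
single-sample rule and the default, with `K = 200` mirroring a
200-individual generation.

`swap_optimize_las()` maximizes the estimate over ordered selections with a
first-improvement local search: every (selected position, unselected
candidate) replacement is scanned, plus cross-pair position exchanges that
re-pair the set without changing it (within-pair exchanges cannot change the
objective and are skipped). All candidates within one restart are scored
against the *same* sampled ancestry paths. Two estimator facts, found while
validating the search and worth recording:

* **A single-sample maximum is exploitable under common random numbers.**
  With `n_reps = 1` the search can tailor the selection to the handful of
  sampled mosaic paths that happen to produce the jackpot progeny; the
  objective value at the returned solution then collapses under fresh paths.
  Averaging over many repetitions removes the incentive, because an accepted
  swap must improve many independent maxima at once.
* **The maximum is flat in weak parents.** A poor parent rarely contributes
  to the best sampled progeny, so upgrading it changes a low-`n_reps`
  objective by exactly zero and the search stalls. Many repetitions make the
  small but positive true improvement visible.

The campaign-scale comparisons in this package therefore run the search with
`K = 20, n_reps = 100` (4000 paths per optimization call); a slot-wise
decomposition of gamete values (per ancestry state, contribution of every
candidate haplotype precomputed with one matrix product) makes a candidate
evaluation a few vector additions, so the larger budget costs little. The
acceptance threshold `tol` (default 0) can demand a minimum improvement
before a swap is accepted.

OPV uses the same scan over unordered subsets after the GEBV prefilter
(`F = 40%` by default); on six-locus, eight-individual instances the
heuristic with 20 restarts recovers the exhaustively enumerated optimum in
at least 95 of 100 random instances (tested), and CGS/OHV truncation
provably solves its separable program (tested against subset enumeration).

## Resource allocation

`allocate_progenies()` splits the per-generation budget across crosses in
proportion to each pair's genetic diversity — the printed per-locus form:
the summed range of `G·β` values over the pair, i.e. `Σ |β_l|` over loci
still segregating within the pair. Quotas are rounded by largest remainder
(ties toward the earlier cross), and any cross rounded to zero receives one
progeny taken from the largest allocation, so every planned cross is
realized and the budget is met exactly. All-zero diversities fall back to an
equal split. A block-wise variant of the diversity measure (range of
block-level haplotype scores) is available via `diversity(..., by =
"block")`, since the per-locus form and the "over all haplotype blocks"
reading differ for multi-locus blocks.

## Campaign defaults and bookkeeping

`campaign_config()` defaults to the standard comparison setting: `N = 200`,
`S = 20` (10 crosses), 200 progenies per generation, `T = 10`; OHV uses 12
blocks per chromosome and removes the lowest 70% by GEBV before selecting,
OPV uses 1 block per chromosome and removes 40%, LAS searches the full
population. Blocks split each chromosome into contiguous runs of near-equal
locus count. Generation-0 statistics are computed on the founders before any
selection; cumulative gain is the population mean GEBV minus the
generation-0 mean; dispersion across repetitions is reported as a standard
deviation. Within a repetition of `compare_methods()` every method receives
the same founder draw, so method contrasts are paired.

Randomness is organized as one root seed plus deterministic child streams
per repetition, generation and cross (`child_seed()`), so a trajectory is
bit-reproducible and adding a method or changing one cross's progeny count
does not perturb the other draws.

## The synthetic generator

`make_scenario()` emulates the structure the methods assume at desk scale:
by default 50 fully homozygous (inbred) founders, 300 markers spread over 5
chromosomes of 150 cM with uniformly random map positions, Haldane
conversion of adjacent distances to recombination frequencies (0.5 across
chromosome boundaries), per-locus major-allele frequencies uniform on
(0.5, 0.95), and sparse effects: 20% of loci carry a `N(0, 1)` effect with
an even sign mix, mimicking Bayesian whole-genome-regression estimates.
Effects are rescaled once so the founders' upper selection limit is exactly
100, which makes campaign statistics read as percentages of the founders'
maximum potential.

What the generator does **not** model: linkage disequilibrium beyond
inbreeding (founder loci are drawn independently), realistic site-frequency
spectra, marker-effect estimation error, and any phenotype layer. Passing
comparisons on this generator therefore demonstrate the machinery and the
qualitative method ranking under idealized founders, not performance on real
panels, where LD and effect-estimation noise matter.

## Numerical choices and degenerate inputs

* Map distances convert via Haldane by default (consistent with the
  no-interference meiosis chain); Kosambi and a pass-through for maps whose
  position column is already cumulative recombination are selectable.
  Conversions are clamped to `[0, 0.5]`; negative within-chromosome
  distances are errors.
* Truncation selection breaks ties toward the lower index; the GEBV
  prefilter removes ties at the cutoff from the higher index first; both are
  deterministic.
* Scaling to a target potential requires a positive upper selection limit
  (a uniform rescale cannot reach a positive target from a non-positive
  one); the synthetic generator guards against the measure-zero draw with no
  scorable allele by seeding one unit effect before scaling.
* Unphased VCF records, non-biallelic sites and missing genotypes are
  rejected outright rather than imputed; markers absent from any of the
  three inputs are dropped with a warning.
* `S = 2` forces `R = 0` (a single family cannot mix across families); the
  samplers refuse inconsistent inputs.

## Problem sizes used in the tests

Unit tests run on genomes of 1–60 loci where exact oracles (subset
enumeration, full path enumeration of the ancestry chain, Mendelian ratios)
are affordable. The campaign-scale checks and `scripts/acceptance.R` use the
default generator scenario with `T = 5`, `S = 10`, 5 crosses and 50
progenies per generation, 30 paired repetitions — a deliberate reduction of
the standard 200-individual, 10-generation setting that keeps a full
four-method comparison within minutes on one core while preserving the
selection pressure (`S/N = 0.2`) and crossing structure of the larger
configuration.

## Known limitations

The look-ahead model itself is an approximation: one progeny per selected
pair, random intermating afterwards, and no modelling of the *future*
selection steps the simulator will actually perform. The Monte-Carlo
objective is noisy and the swap search is a local heuristic — neither global
optimality nor invariance to the path sample is guaranteed (restarts and
`n_reps` mitigate both). Diversity-proportional allocation uses the pair's
segregating-effect mass as a variance proxy, ignoring linkage between loci.
Doubled-haploid production, non-additive gene action, multi-trait objectives
and budget allocation across generations are out of scope.
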