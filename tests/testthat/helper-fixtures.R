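# Small builders shared across the suite. Everything is constructed in code;
# no stored fixtures.

# A GenomeSpec on one chromosome with explicit recombination vector.
toy_spec <- function(beta, r = NULL, chrom = NULL, pos = NULL) {
  L <- length(beta)
  spec <- GenomeSpec(paste0("m", seq_len(L)),
                     chrom %||% rep("1", L),
                     pos %||% seq(0, by = 1, length.out = L),
                     beta)
  if (!is.null(r)) spec$r <- r
  spec
}
`%||%` <- function(a, b) if (is.null(a)) b else a

# Population from per-individual haplotype pairs: list of list(h1, h2).
toy_pop <- function(...) {
  inds <- list(...)
  Population(do.call(cbind, lapply(inds, function(x) cbind(x[[1]], x[[2]]))))
}

# Random phased population for property checks.
random_pop <- function(L, N, seed) {
  with_seed_test(seed, Population(matrix(rbinom(L * 2 * N, 1, 0.5), L, 2 * N)))
}

random_spec <- function(L, seed, n_chrom = 1) {
  with_seed_test(seed, {
    chrom <- sort(rep_len(paste0("c", seq_len(n_chrom)), L))
    pos <- ave(runif(L, 0, 100), chrom, FUN = sort)
    GenomeSpec(paste0("m", seq_len(L)), chrom, pos, rnorm(L))
  })
}

with_seed_test <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  force(code)
}

# Minimal phased VCF writer for I/O tests.
write_toy_vcf <- function(path, gt, chrom, pos, ids, ref = "A", alt = "T",
                          marker = NULL) {
  # gt: L x N character matrix like "0|1"
  L <- nrow(gt)
  marker <- marker %||% paste0("m", seq_len(L))
  header <- c("##fileformat=VCFv4.2",
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", ids), collapse = "\t"))
  body <- vapply(seq_len(L), function(l)
    paste(c(chrom[l], pos[l], marker[l], rep(ref, 1), rep(alt, 1), ".", "PASS",
            ".", "GT", gt[l, ]), collapse = "\t"), character(1))
  writeLines(c(header, body), path)
  path
}

write_map_csv <- function(path, marker, chrom, pos_cM) {
  utils::write.csv(data.frame(marker = marker, chrom = chrom, pos_cM = pos_cM),
                   path, row.names = FALSE, quote = FALSE)
  path
}

withr_like_tempdir <- function() {
  d <- tempfile("lasgs-test-")
  dir.create(d)
  d
}

write_effects_csv <- function(path, marker, beta) {
  utils::write.csv(data.frame(marker = marker, beta = beta), path,
                   row.names = FALSE, quote = FALSE)
  path
}
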