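#' Load a phased population with map and effects
#'
#' Reads phased genotypes from a phased VCF (GT field with `|` separators) or
#' a haplotype CSV (first column `marker`, then two 0/1 columns per
#' individual, headers `<id>_1`, `<id>_2`), a genetic map CSV
#' (`marker,chrom,pos_cM`) and an effects CSV (`marker,beta`). The returned
#' objects are restricted to the markers present in all three inputs, in map
#' order (chromosome-major, position-minor); markers dropped from any input
#' trigger a warning. Unphased (`/`) VCF records and non-biallelic sites are
#' rejected.
#'
#' VCF REF/ALT alleles are recoded to major/minor by frequency in the loaded
#' population (code 1 = major allele, ties broken toward REF), since marker
#' effects attach to the major allele.
#'
#' @param genotype_file Path to a phased VCF (`.vcf`/`.vcf.gz`) or haplotype
#'   CSV.
#' @param map_file Path to the genetic map CSV.
#' @param effects_file Path to the marker-effects CSV.
#' @param mapping_function cM-to-recombination conversion, see
#'   [map_to_recomb()].
#' @return A list with elements `pop` ([Population]) and `spec`
#'   ([GenomeSpec]).
#' @export
load_population <- function(genotype_file, map_file, effects_file,
                            mapping_function = c("haldane", "kosambi", "direct")) {
  mapping_function <- match.arg(mapping_function)
  map <- utils::read.csv(map_file, stringsAsFactors = FALSE)
  need(map, c("marker", "chrom", "pos_cM"), "map")
  eff <- utils::read.csv(effects_file, stringsAsFactors = FALSE)
  need(eff, c("marker", "beta"), "effects")

  geno <- if (grepl("\\.vcf(\\.gz)?$", genotype_file, ignore.case = TRUE))
    read_phased_vcf(genotype_file) else read_haplotype_csv(genotype_file)

  keep <- Reduce(intersect, list(geno$marker, map$marker, eff$marker))
  if (length(keep) == 0)
    stop("no marker ids are shared by the genotype, map and effects inputs")
  dropped <- length(union(union(geno$marker, map$marker), eff$marker)) -
    length(keep)
  if (dropped > 0)
    warning(sprintf("%d marker(s) absent from at least one input were dropped", dropped))

  map <- map[map$marker %in% keep, , drop = FALSE]
  map <- map[order(factor(map$chrom, levels = unique(map$chrom)), map$pos_cM), ,
             drop = FALSE]
  gi <- match(map$marker, geno$marker)
  ei <- match(map$marker, eff$marker)

  haplo <- geno$haplo[gi, , drop = FALSE]
  if (geno$recode) {
    # VCF entries are ALT dosage; recode so 1 = major allele, ties toward REF
    ref_major <- rowMeans(haplo) <= 0.5
    haplo[ref_major, ] <- 1L - haplo[ref_major, , drop = FALSE]
  }
  beta <- eff$beta[ei]

  pop <- Population(haplo, ids = geno$ids)
  spec <- GenomeSpec(map$marker, map$chrom, map$pos_cM, beta,
                     mapping_function = mapping_function)
  list(pop = pop, spec = spec)
}

need <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss))
    stop(sprintf("%s file is missing column(s): %s", what,
                 paste(miss, collapse = ", ")))
  invisible(TRUE)
}

# Returns list(marker, haplo (L x 2N per-haplotype codes), ids, recode):
# recode = TRUE when the codes are ALT dosage still needing major/minor
# conversion.
read_phased_vcf <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  alt <- fix[, "ALT"]
  multi <- grepl(",", alt) | alt == "." | is.na(alt)
  if (any(multi))
    stop(sprintf("non-biallelic site at %s:%s", fix[which(multi)[1], "CHROM"],
                 fix[which(multi)[1], "POS"]))
  gt <- vcfR::extract.gt(vcf, element = "GT")
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = 1, dimnames = list(NULL, names(gt)))
  unphased <- grepl("/", gt, fixed = TRUE)
  if (any(unphased)) {
    idx <- which(unphased)[1]
    wr <- (idx - 1L) %% nrow(gt) + 1L
    wc <- (idx - 1L) %/% nrow(gt) + 1L
    stop(sprintf("unphased genotype '%s' at %s:%s (sample %s); phased '|' calls are required",
                 gt[wr, wc], fix[wr, "CHROM"], fix[wr, "POS"],
                 colnames(gt)[wc]))
  }
  if (any(is.na(gt)) || any(!grepl("^[01]\\|[01]$", gt)))
    stop("genotypes must be phased biallelic calls of the form 'a|b' with a,b in {0,1}")
  ids <- colnames(gt)
  L <- nrow(gt); N <- ncol(gt)
  haplo <- matrix(0L, L, 2 * N)
  haplo[, c(TRUE, FALSE)] <- as.integer(substr(gt, 1, 1))
  haplo[, c(FALSE, TRUE)] <- as.integer(substr(gt, 3, 3))
  marker <- fix[, "ID"]
  blank <- is.na(marker) | marker == "."
  marker[blank] <- paste0(fix[blank, "CHROM"], "_", fix[blank, "POS"])
  list(marker = marker, haplo = haplo, ids = ids, recode = TRUE)
}

read_haplotype_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (names(df)[1] != "marker") stop("haplotype CSV must start with a 'marker' column")
  haplo <- as.matrix(df[, -1, drop = FALSE])
  ids <- unique(sub("_[12]$", "", colnames(haplo)))
  if (length(ids) * 2 != ncol(haplo))
    stop("haplotype CSV must carry two columns per individual (<id>_1, <id>_2)")
  # CSV input is taken as already major/minor coded
  list(marker = df$marker, haplo = haplo, ids = ids, recode = FALSE)
}

#' Write a population, map and effects as CSV files
#'
#' Emits the three CSV dialects read back by [load_population()]:
#' `<prefix>_haplotypes.csv`, `<prefix>_map.csv`, `<prefix>_effects.csv`.
#'
#' @param pop A [Population].
#' @param spec A [GenomeSpec].
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix (default `"scenario"`).
#' @return Invisibly, the named vector of paths written.
#' @export
write_scenario <- function(pop, spec, dir, prefix = "scenario") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  check_dims(pop, spec)
  hap <- as.data.frame(pop$haplo)
  names(hap) <- paste0(rep(pop$ids, each = 2), "_", c(1, 2))
  hap <- cbind(marker = spec$loci, hap)
  paths <- c(
    haplotypes = file.path(dir, paste0(prefix, "_haplotypes.csv")),
    map = file.path(dir, paste0(prefix, "_map.csv")),
    effects = file.path(dir, paste0(prefix, "_effects.csv")))
  utils::write.csv(hap, paths[["haplotypes"]], row.names = FALSE, quote = FALSE)
  utils::write.csv(data.frame(marker = spec$loci, chrom = spec$chrom,
                              pos_cM = spec$pos_cM),
                   paths[["map"]], row.names = FALSE, quote = FALSE)
  utils::write.csv(data.frame(marker = spec$loci, beta = spec$beta),
                   paths[["effects"]], row.names = FALSE, quote = FALSE)
  invisible(paths)
}
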