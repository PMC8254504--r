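#' Build a genome model for backcross simulation
#'
#' A genome model describes the chromosomes of the mapping population:
#' physical length, genetic length, centromere position and the positions of
#' the informative SNPs (sites homozygous for different alleles in the two
#' parental accessions and heterozygous in the F1).
#'
#' @param chromosomes A data frame with one row per chromosome and columns
#'   `chrom` (character), `length_bp`, `genetic_length_cM`, `centromere_bp`.
#' @param snp_positions A named list mapping each chromosome name to a
#'   strictly increasing integer vector of SNP positions (1-based, within
#'   `[1, length_bp]`).
#'
#' @return A tibble of class `genome_model` with one row per chromosome and a
#'   `snps` list-column of SNP positions.
#' @export
#' @examples
#' gm <- genome_model(
#'   data.frame(chrom = "chr1", length_bp = 1e6,
#'              genetic_length_cM = 4, centromere_bp = 5e5),
#'   list(chr1 = c(100L, 2000L, 7500L))
#' )
genome_model <- function(chromosomes, snp_positions) {
  chromosomes <- as_tibble(chromosomes)
  needed <- c("chrom", "length_bp", "genetic_length_cM", "centromere_bp")
  if (!all(needed %in% names(chromosomes))) {
    abort(paste0("`chromosomes` must have columns: ",
                 paste(needed, collapse = ", ")))
  }
  if (anyDuplicated(chromosomes$chrom)) abort("duplicated chromosome names")
  if (any(chromosomes$genetic_length_cM < 0)) {
    abort("genetic_length_cM must be >= 0")
  }
  if (any(chromosomes$centromere_bp < 1 |
          chromosomes$centromere_bp > chromosomes$length_bp)) {
    abort("centromere_bp must lie within [1, length_bp]")
  }
  snps <- lapply(chromosomes$chrom, function(cn) {
    p <- snp_positions[[cn]]
    if (is.null(p)) abort(paste0("no SNP positions for chromosome ", cn))
    p <- as.integer(p)
    if (is.unsorted(p, strictly = TRUE)) {
      abort(paste0("SNP positions on ", cn, " must be strictly increasing"))
    }
    L <- chromosomes$length_bp[chromosomes$chrom == cn]
    if (length(p) && (p[1] < 1L || p[length(p)] > L)) {
      abort(paste0("SNP positions on ", cn, " outside [1, length_bp]"))
    }
    p
  })
  out <- mutate(chromosomes, snps = snps)
  class(out) <- c("genome_model", class(out))
  out
}

#' Synthetic five-chromosome genome emulating the Col-0/Ws mapping design
#'
#' Builds a scaled-down genome with the statistical shape of the Arabidopsis
#' BC1 mapping population: five chromosomes with physical lengths in TAIR10
#' proportions, approximately uniform informative-SNP spacing (mean about
#' 1,534 bp between adjacent sites) and genetic lengths that sum to roughly
#' 5.2 Morgans genome-wide, so a gamete carries about five crossovers on
#' average.
#'
#' @param n_snps Total number of informative SNPs across the genome.
#' @param mean_spacing_bp Mean spacing between adjacent SNPs, in bp.
#' @return A [genome_model()] tibble.
#' @export
arabidopsis_like_genome <- function(n_snps = 20000, mean_spacing_bp = 1534) {
  # TAIR10 chromosome sizes (Mb): 30.4, 19.7, 23.5, 18.6, 26.9
  phys_prop <- c(30.4, 19.7, 23.5, 18.6, 26.9)
  phys_prop <- phys_prop / sum(phys_prop)
  # map lengths scaled to a 520-cM genome (mean ~5.2 COs per gamete)
  gen_cM <- round(520 * phys_prop, 1)
  n_chr_snps <- floor(n_snps * phys_prop)
  n_chr_snps[1] <- n_chr_snps[1] + (n_snps - sum(n_chr_snps))
  lens <- as.integer(round(n_chr_snps * mean_spacing_bp))
  chroms <- tibble(
    chrom = paste0("chr", 1:5),
    length_bp = lens,
    genetic_length_cM = gen_cM,
    centromere_bp = as.integer(round(lens * c(0.49, 0.18, 0.58, 0.21, 0.41)))
  )
  snps <- lapply(seq_len(5), function(i) {
    sort(sample.int(lens[i], n_chr_snps[i]))
  })
  names(snps) <- chroms$chrom
  genome_model(chroms, snps)
}

#' @export
print.genome_model <- function(x, ...) {
  cat("<genome_model> ", nrow(x), " chromosomes, ",
      sum(lengths(x$snps)), " SNPs, ",
      sum(x$genetic_length_cM), " cM total\n", sep = "")
  NextMethod()
}
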