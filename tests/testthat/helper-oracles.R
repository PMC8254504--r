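# brute-force two-sided Fisher p by hypergeometric enumeration over all
# tables with the observed margins
fisher_oracle <- function(rec1, tot1, rec2, tot2) {
  m <- rec1 + rec2
  k <- max(0, m - tot2):min(tot1, m)
  probs <- dhyper(k, tot1, tot2, m)
  p_obs <- dhyper(rec1, tot1, tot2, m)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# tiny deterministic genome: one chromosome, evenly spaced SNPs
tiny_genome <- function(n_snps = 1000, spacing = 1000, genetic_cM = 100,
                        centromere_frac = 0.4) {
  len <- n_snps * spacing
  genome_model(
    data.frame(chrom = "chr1", length_bp = len,
               genetic_length_cM = genetic_cM,
               centromere_bp = as.integer(len * centromere_frac)),
    list(chr1 = as.integer(seq(spacing, len, by = spacing)))
  )
}

# allele counts with an exact zygosity layout: HET blocks get R=A=depth/2,
# HOM blocks all-reference reads
counts_from_classes <- function(classes_per_snp, depth = 10,
                                spacing = 1000, sample_id = "s1") {
  n <- length(classes_per_snp)
  r <- ifelse(classes_per_snp == "HET", depth / 2, depth)
  a <- ifelse(classes_per_snp == "HET", depth / 2, 0)
  tibble::tibble(sample_id = sample_id, chrom = "chr1",
                 pos = seq(spacing, n * spacing, by = spacing),
                 ref_count = as.integer(r), alt_count = as.integer(a))
}
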