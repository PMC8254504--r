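#' Pooled heterozygosity score
#'
#' For a genomic region with `R` reads calling the Col-0 (reference) allele
#' and `A` reads calling the Ws (alternative) allele, the pooled
#' heterozygosity score is `h = 2RA / (R + A)^2`. It is close to 0.5 in
#' heterozygous regions (balanced allele counts) and close to 0 in
#' homozygous regions, and is symmetric in `R` and `A`.
#'
#' @param R,A Non-negative integer read counts; vectorised.
#' @return `h` in `[0, 0.5]`; `NA` where `R + A = 0` (no evidence).
#' @export
#' @examples
#' pooled_het(50, 50)  # 0.5
#' pooled_het(10, 0)   # 0
pooled_het <- function(R, A) {
  if (any(R < 0, na.rm = TRUE) || any(A < 0, na.rm = TRUE)) {
    abort("read counts must be non-negative")
  }
  tot <- R + A
  ifelse(tot > 0, 2 * R * A / tot^2, NA_real_)
}

#' Select informative ("homozygous unique") SNP sites
#'
#' Informative sites for the backcross analysis are SNPs homozygous for
#' different alleles in the two parental accessions and heterozygous in
#' their F1 hybrid. Genotype vectors use the values `"HOM_REF"`,
#' `"HOM_ALT"`, `"HET"`, `"MISSING"`.
#'
#' @param parent_ref_gt Genotypes of the reference-accession parent (Col-0).
#' @param parent_alt_gt Genotypes of the alternative-accession parent (Ws).
#' @param f1_gt Genotypes of the F1 hybrid.
#' @param mirrored Also accept the mirrored arrangement (`parent_ref_gt`
#'   homozygous-alternative and `parent_alt_gt` homozygous-reference)?
#' @return Logical mask over SNPs, `TRUE` for informative sites.
#' @export
select_informative_sites <- function(parent_ref_gt, parent_alt_gt, f1_gt,
                                     mirrored = FALSE) {
  n <- length(parent_ref_gt)
  if (length(parent_alt_gt) != n || length(f1_gt) != n) {
    abort("genotype vectors must have equal length")
  }
  keep <- parent_ref_gt == "HOM_REF" & parent_alt_gt == "HOM_ALT" &
    f1_gt == "HET"
  if (mirrored) {
    keep <- keep | (parent_ref_gt == "HOM_ALT" &
                      parent_alt_gt == "HOM_REF" & f1_gt == "HET")
  }
  keep & !is.na(keep)
}

#' Combine adjacent SNPs into fixed-size bins
#'
#' Traversing each chromosome, consecutive non-overlapping windows of
#' `bin_size` SNPs are formed; read counts are summed over each window's
#' SNPs before the pooled heterozygosity score is computed (pooling reads
#' rather than averaging per-SNP scores, which would be far noisier at
#' 1x coverage). A terminal remainder of at least `min_tail` SNPs forms its
#' own bin, otherwise it is merged into the preceding bin.
#'
#' @param counts Allele-count tibble with columns `chrom`, `pos`,
#'   `ref_count`, `alt_count` and optionally `sample_id`, sorted by
#'   position within chromosome.
#' @param bin_size Number of SNPs per bin.
#' @param min_tail Minimum SNPs for a terminal bin of its own.
#' @return A tibble of class `bc1_bins`: one row per (sample, chromosome,
#'   bin) with `bin` index, `first_snp_pos`, `last_snp_pos`, `n_snps`,
#'   `R_sum`, `A_sum` and `h`.
#' @export
bin_snps <- function(counts, bin_size = 100, min_tail = 50) {
  if (bin_size < 1) abort("`bin_size` must be >= 1")
  if (!"sample_id" %in% names(counts)) counts$sample_id <- "sample"
  grouped <- group_by(counts, sample_id, chrom)
  chk <- summarise(grouped, sorted = !is.unsorted(pos, strictly = TRUE),
                   .groups = "drop")
  if (!all(chk$sorted)) {
    abort("SNP positions must be strictly increasing within chromosome")
  }
  out <- grouped %>%
    mutate(bin = {
      idx <- (row_number() - 1L) %/% bin_size + 1L
      nb <- max(idx)
      if (nb > 1L && sum(idx == nb) < min_tail) idx[idx == nb] <- nb - 1L
      idx
    }) %>%
    group_by(sample_id, chrom, bin) %>%
    summarise(first_snp_pos = min(pos), last_snp_pos = max(pos),
              n_snps = dplyr::n(),
              R_sum = sum(ref_count), A_sum = sum(alt_count),
              .groups = "drop") %>%
    mutate(h = pooled_het(R_sum, A_sum)) %>%
    arrange(sample_id, chrom, bin)
  class(out) <- c("bc1_bins", class(out))
  out
}

#' Classify bin zygosity from the pooled heterozygosity score
#'
#' Bins are homozygous (`HOM`) when `h < hom_max`, heterozygous (`HET`) when
#' `h > het_min`, and undetermined (`UNDET`) otherwise — the inequalities
#' are strict, so a score exactly at a threshold is undetermined. Bins with
#' fewer than `min_reads` total reads (in particular zero-coverage bins,
#' where `h` is undefined) are undetermined.
#'
#' A BC1 offspring of an F1 backcrossed to the reference accession can only
#' be heterozygous or homozygous-reference; a homozygous bin dominated by
#' alternative-allele reads would imply sample contamination or a pedigree
#' error, and triggers a warning (it is still classified `HOM`, never a
#' crossover on its own).
#'
#' @param bins A `bc1_bins` tibble from [bin_snps()].
#' @param hom_max Upper (exclusive) `h` bound for the homozygous class.
#' @param het_min Lower (exclusive) `h` bound for the heterozygous class.
#' @param min_reads Minimum total reads for a bin to be classifiable.
#' @return The input with a `zygosity` factor column (`HOM`, `HET`,
#'   `UNDET`) added.
#' @export
classify_bins <- function(bins, hom_max = 0.05, het_min = 0.45,
                          min_reads = 1) {
  z <- case_when(
    is.na(bins$h) | (bins$R_sum + bins$A_sum) < min_reads ~ "UNDET",
    bins$h < hom_max ~ "HOM",
    bins$h > het_min ~ "HET",
    TRUE ~ "UNDET"
  )
  suspicious <- z == "HOM" & bins$A_sum > bins$R_sum
  if (any(suspicious)) {
    warn(paste0(sum(suspicious), " homozygous bin(s) dominated by the ",
                "alternative allele: possible contamination or sample mix-up"))
  }
  bins$zygosity <- factor(z, levels = c("HOM", "HET", "UNDET"))
  bins
}

#' Call crossover breakpoints from classified bins
#'
#' Scanning the determined (HOM/HET) bins of each chromosome in order, every
#' change of zygosity class emits one crossover call. Undetermined bins
#' never emit or suppress calls; they are skipped and counted, widening the
#' breakpoint interval. The breakpoint interval is delimited by the adjacent
#' SNPs of the two flanking determined bins: `left_pos` is the last SNP of
#' the left determined bin and `right_pos` the first SNP of the right
#' determined bin.
#'
#' Because a bin containing the true breakpoint near one of its ends can
#' still classify as a determined class (the pooled score tolerates up to
#' roughly a third of discordant reads before leaving the heterozygous
#' band), the true crossover is only guaranteed to lie within the full span
#' of the two flanking determined bins. The call therefore also carries
#' conservative bounds: `left_bound` (first SNP of the left determined bin)
#' and `right_bound` (last SNP of the right determined bin).
#'
#' @param bins A classified `bc1_bins` tibble (see [classify_bins()]).
#' @param min_block_bins Minimum run length (in determined bins) for a
#'   zygosity block to be trusted; shorter blocks are dropped before calling.
#'   The default of 1 applies no filter.
#' @return A tibble of class `co_calls`: `sample_id`, `chrom`, `left_pos`,
#'   `right_pos`, `left_class`, `right_class`, `n_undetermined_spanned`,
#'   `left_bound`, `right_bound`.
#' @export
call_crossovers <- function(bins, min_block_bins = 1) {
  stopifnot("zygosity" %in% names(bins))
  per_group <- function(df) {
    det <- df[df$zygosity != "UNDET", , drop = FALSE]
    if (min_block_bins > 1 && nrow(det) > 0) {
      rl <- rle(as.character(det$zygosity))
      keep <- rep(rl$lengths >= min_block_bins, rl$lengths)
      det <- det[keep, , drop = FALSE]
    }
    if (nrow(det) < 2) return(NULL)
    zi <- as.character(det$zygosity)
    sw <- which(zi[-1] != zi[-length(zi)])
    if (!length(sw)) return(NULL)
    tibble(
      sample_id = det$sample_id[1],
      chrom = det$chrom[1],
      left_pos = det$last_snp_pos[sw],
      right_pos = det$first_snp_pos[sw + 1],
      left_class = zi[sw],
      right_class = zi[sw + 1],
      n_undetermined_spanned = det$bin[sw + 1] - det$bin[sw] - 1L,
      left_bound = det$first_snp_pos[sw],
      right_bound = det$last_snp_pos[sw + 1]
    )
  }
  out <- bins %>%
    arrange(sample_id, chrom, bin) %>%
    group_by(sample_id, chrom) %>%
    dplyr::group_map(~ per_group(.x %>% mutate(sample_id = .y$sample_id,
                                               chrom = .y$chrom))) %>%
    bind_rows()
  if (nrow(out) == 0) {
    out <- tibble(sample_id = character(), chrom = character(),
                  left_pos = integer(), right_pos = integer(),
                  left_class = character(), right_class = character(),
                  n_undetermined_spanned = integer(),
                  left_bound = integer(), right_bound = integer())
  }
  class(out) <- c("co_calls", class(out))
  out
}

#' Summarise crossover calls per sample and chromosome
#'
#' Computes per-chromosome and genome-wide crossover counts per sample, the
#' fraction of chromosomes carrying two or more crossovers, and the
#' distribution of crossover midpoints along the normalized chromosome arm
#' (0 = centromere, 1 = telomere), using the containing arm of each call's
#' interval midpoint.
#'
#' @param calls A `co_calls` tibble.
#' @param genome The [genome_model()] providing centromere and chromosome
#'   lengths.
#' @param sample_ids Optional character vector of all samples (so samples
#'   with zero calls appear in the summary).
#' @return A list of class `co_summary` with tibbles `per_chromosome`
#'   (`sample_id`, `chrom`, `n_cos`), `per_sample` (`sample_id`, `total`),
#'   `multi_co_fraction` (scalar fraction of sample-chromosomes with >= 2
#'   calls) and `arm_positions` (`sample_id`, `chrom`, `arm_pos`).
#' @export
summarize_crossovers <- function(calls, genome, sample_ids = NULL) {
  stopifnot(inherits(genome, "genome_model"))
  sample_ids <- sample_ids %||% unique(calls$sample_id)
  grid <- tidyr::expand_grid(sample_id = sample_ids, chrom = genome$chrom)
  per_chr <- calls %>%
    count(sample_id, chrom, name = "n_cos") %>%
    right_join_grid(grid)
  per_sample <- per_chr %>%
    group_by(sample_id) %>%
    summarise(total = sum(n_cos), .groups = "drop")
  mids <- calls %>%
    mutate(midpoint = (left_pos + right_pos) / 2) %>%
    left_join(select(genome, chrom, length_bp, centromere_bp), by = "chrom")
  if (nrow(mids) > 0 &&
      any(mids$midpoint < 1 | mids$midpoint > mids$length_bp)) {
    abort("crossover midpoint outside chromosome")
  }
  arm <- mids %>%
    mutate(arm_pos = ifelse(
      midpoint <= centromere_bp,
      (centromere_bp - midpoint) / (centromere_bp - 1),
      (midpoint - centromere_bp) / (length_bp - centromere_bp))) %>%
    select(sample_id, chrom, arm_pos)
  out <- list(
    per_chromosome = per_chr,
    per_sample = per_sample,
    multi_co_fraction = mean(per_chr$n_cos >= 2),
    arm_positions = arm
  )
  class(out) <- "co_summary"
  out
}

right_join_grid <- function(counts, grid) {
  out <- left_join(grid, counts, by = c("sample_id", "chrom"))
  out$n_cos[is.na(out$n_cos)] <- 0L
  out
}

#' @export
print.co_summary <- function(x, ...) {
  cat("<co_summary> ", nrow(x$per_sample), " sample(s); mean ",
      round(mean(x$per_sample$total), 2), " COs/sample; ",
      round(100 * x$multi_co_fraction, 1),
      "% of chromosomes with >= 2 COs\n", sep = "")
  invisible(x)
}
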