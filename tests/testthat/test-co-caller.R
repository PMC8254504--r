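test_that("pooled heterozygosity score follows 2RA/(R+A)^2", {
  expect_identical(pooled_het(50, 50), 0.5)
  expect_identical(pooled_het(10, 0), 0)
  expect_identical(pooled_het(3, 1), 0.375)
  expect_identical(pooled_het(8, 1), 16 / 81)
  expect_true(is.na(pooled_het(0, 0)))
  expect_equal(pooled_het(7, 13), pooled_het(13, 7))  # symmetry
  expect_error(pooled_het(-1, 2), "non-negative")

  # bounds over a grid
  g <- expand.grid(R = 0:20, A = 0:20)
  h <- pooled_het(g$R, g$A)
  h <- h[!is.na(h)]
  expect_true(all(h >= 0 & h <= 0.5))
})

test_that("informative-site selection keeps homozygous-unique SNPs", {
  p1 <- c("HOM_REF", "HET", "HOM_REF", "HOM_ALT", "HOM_REF")
  p2 <- c("HOM_ALT", "HOM_ALT", "HOM_ALT", "HOM_REF", "MISSING")
  f1 <- c("HET", "HET", "HOM_REF", "HET", "HET")
  expect_identical(select_informative_sites(p1, p2, f1),
                   c(TRUE, FALSE, FALSE, FALSE, FALSE))
  expect_identical(select_informative_sites(p1, p2, f1, mirrored = TRUE),
                   c(TRUE, FALSE, FALSE, TRUE, FALSE))
  expect_error(select_informative_sites(p1[1:2], p2, f1), "equal length")
})

test_that("binning policy: fixed windows with tail merging", {
  cnt <- counts_from_classes(rep("HET", 250))
  b <- bin_snps(cnt, bin_size = 100, min_tail = 50)
  expect_equal(b$n_snps, c(100, 100, 50))
  expect_equal(b$first_snp_pos, c(1000, 101000, 201000))
  expect_equal(b$last_snp_pos, c(100000, 200000, 250000))

  b2 <- bin_snps(counts_from_classes(rep("HET", 120)), 100, 50)
  expect_equal(b2$n_snps, 120)  # 20-SNP remainder merged backward

  # pooled counts, not averaged per-SNP scores
  cnt3 <- tibble::tibble(sample_id = "s", chrom = "c",
                         pos = c(100L, 200L),
                         ref_count = c(3L, 5L), alt_count = c(0L, 1L))
  b3 <- bin_snps(cnt3, bin_size = 2)
  expect_equal(b3$R_sum, 8L)
  expect_equal(b3$A_sum, 1L)
  expect_equal(b3$h, 2 * 8 * 1 / 81)

  expect_error(bin_snps(dplyr::arrange(cnt3, dplyr::desc(pos)), 2),
               "strictly increasing")
})

test_that("bin classification uses strict thresholds and a partition", {
  mk <- function(h, R = 100, A = NULL) {
    if (is.null(A)) { A <- 0; R <- 100 }
    tibble::tibble(sample_id = "s", chrom = "c", bin = 1L,
                   first_snp_pos = 1L, last_snp_pos = 2L, n_snps = 2L,
                   R_sum = R, A_sum = A, h = h)
  }
  cls <- function(h) as.character(classify_bins(mk(h))$zygosity)
  expect_equal(cls(0.04), "HOM")
  expect_equal(cls(0.46), "HET")
  expect_equal(cls(0.20), "UNDET")
  expect_equal(cls(0.05), "UNDET")  # strict: h < 0.05 required for HOM
  expect_equal(cls(0.45), "UNDET")  # strict: h > 0.45 required for HET

  zero <- mk(NA_real_); zero$R_sum <- 0L; zero$A_sum <- 0L
  expect_equal(as.character(classify_bins(zero)$zygosity), "UNDET")

  # exactly one class per bin across a sweep of scores
  sweep <- dplyr::bind_rows(lapply(seq(0, 0.5, by = 0.01), mk))
  z <- classify_bins(sweep)$zygosity
  expect_true(all(!is.na(z)))

  ws <- mk(0.01, R = 1L, A = 99L)
  expect_warning(classify_bins(ws), "contamination")
})

test_that("crossover calls are emitted at determined-bin class switches", {
  call_from <- function(classes) {
    n <- length(classes) * 100
    cls_per_snp <- rep(ifelse(classes == "HOM", "HOM", "HET"), each = 100)
    cnt <- counts_from_classes(cls_per_snp)
    # zero out coverage for UNDET bins
    und <- which(rep(classes, each = 100) == "UNDET")
    cnt$ref_count[und] <- 0L; cnt$alt_count[und] <- 0L
    call_crossovers(classify_bins(bin_snps(cnt)))
  }
  c1 <- call_from(c("HET", "HET", "HOM", "HOM"))
  expect_equal(nrow(c1), 1)
  expect_equal(c1$left_pos, 200000)   # last SNP of bin 2
  expect_equal(c1$right_pos, 201000)  # first SNP of bin 3
  expect_equal(c1$left_class, "HET")
  expect_equal(c1$right_class, "HOM")
  expect_equal(c1$n_undetermined_spanned, 0L)
  expect_equal(c1$left_bound, 101000)
  expect_equal(c1$right_bound, 300000)

  c2 <- call_from(c("HET", "UNDET", "HOM"))
  expect_equal(nrow(c2), 1)
  expect_equal(c2$n_undetermined_spanned, 1L)
  expect_equal(c2$left_pos, 100000)
  expect_equal(c2$right_pos, 201000)

  expect_equal(nrow(call_from(c("HET", "HET", "HET"))), 0)
  # two adjacent switches are two calls
  c3 <- call_from(c("HET", "HOM", "HET"))
  expect_equal(nrow(c3), 2)
  expect_true(all(c3$left_pos < c3$right_pos))
})

test_that("caller matches simulated truth on clean high-coverage data", {
  gm <- tiny_genome(2000, genetic_cM = 150)
  set.seed(55)
  for (rep in 1:5) {
    truth <- simulate_meiosis(gm, nu = 5)
    cnt <- simulate_backcross_counts(truth, gm, coverage_mean = 12,
                                     error_rate = 0)
    calls <- call_crossovers(classify_bins(bin_snps(cnt)))
    tc <- truth$co_pos_bp[[1]]
    # check only meioses without terminal-bin or tightly spaced COs,
    # where bin-level switch detection is fully informative
    n_bins <- 20
    bin_of <- ceiling(tc / (gm$length_bp / n_bins))
    clean <- length(tc) == 0 ||
      (all(bin_of > 1 & bin_of < n_bins) && all(diff(bin_of) >= 2))
    if (clean) {
      expect_equal(nrow(calls), length(tc))
      if (length(tc)) {
        expect_true(all(tc > calls$left_bound & tc <= calls$right_bound))
      }
    }
  }
})

test_that("crossover summaries count, total and normalize correctly", {
  gm <- tiny_genome(1000, centromere_frac = 0.4)
  calls <- tibble::tibble(
    sample_id = "s1", chrom = "chr1",
    left_pos = c(100000L, 700000L), right_pos = c(102000L, 702000L),
    left_class = c("HET", "HOM"), right_class = c("HOM", "HET"),
    n_undetermined_spanned = 0L,
    left_bound = c(99000L, 699000L), right_bound = c(103000L, 703000L))
  s <- summarize_crossovers(calls, gm, sample_ids = c("s1", "s2"))
  expect_equal(s$per_sample$total[s$per_sample$sample_id == "s1"], 2)
  expect_equal(s$per_sample$total[s$per_sample$sample_id == "s2"], 0)
  expect_equal(s$multi_co_fraction, 0.5)  # 1 of 2 sample-chromosomes

  # arm position endpoints: midpoint at centromere -> 0, telomere -> 1
  cen <- gm$centromere_bp[1]; len <- gm$length_bp[1]
  calls2 <- tibble::tibble(
    sample_id = "s1", chrom = "chr1",
    left_pos = c(cen, len - 1L), right_pos = c(cen, len + 1L) - 0L,
    left_class = "HET", right_class = "HOM",
    n_undetermined_spanned = 0L,
    left_bound = 1L, right_bound = len)
  calls2$right_pos <- c(cen, len)
  calls2$left_pos <- c(cen, len)
  s2 <- summarize_crossovers(calls2, gm)
  expect_equal(sort(s2$arm_positions$arm_pos), c(0, 1))
})
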