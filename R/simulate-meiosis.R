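#' Simulate crossover positions by a stationary gamma renewal process
#'
#' Crossovers along a chromosome are modelled as a stationary (equilibrium)
#' renewal point process on the genetic map, with gamma-distributed
#' inter-event distances of shape `nu` and mean 100 cM, so that the expected
#' number of events on a map of length L cM is L/100. `nu = 1` gives a
#' homogeneous Poisson process (no interference); `nu > 1` makes counts
#' underdispersed and events more evenly spaced (crossover interference).
#' The first event is drawn from the equilibrium (length-biased) forward
#' recurrence distribution so the process has no origin effect.
#'
#' Randomness is taken from R's global random number generator; call
#' [set.seed()] for reproducibility.
#'
#' @param genetic_length_cM Map length of the chromosome in centimorgans.
#' @param nu Gamma shape (interference strength), `nu >= 1`.
#' @return A sorted numeric vector of crossover positions in cM.
#' @export
#' @examples
#' set.seed(1)
#' simulate_crossovers(100, nu = 5)
simulate_crossovers <- function(genetic_length_cM, nu = 1) {
  if (!is.numeric(genetic_length_cM) || length(genetic_length_cM) != 1 ||
      is.na(genetic_length_cM) || genetic_length_cM < 0) {
    abort("`genetic_length_cM` must be a single non-negative number")
  }
  if (!is.numeric(nu) || length(nu) != 1 || is.na(nu) || nu < 1) {
    abort("`nu` must be a single number >= 1")
  }
  L <- genetic_length_cM
  if (L == 0) return(numeric(0))
  rate <- nu / 100  # gamma rate giving mean gap 100 cM
  # forward recurrence time of a stationary gamma renewal process:
  # U * X where X ~ length-biased gamma = Gamma(nu + 1, rate)
  pos <- runif(1) * rgamma(1, shape = nu + 1, rate = rate)
  out <- numeric(0)
  while (pos <= L) {
    out <- c(out, pos)
    pos <- pos + rgamma(1, shape = nu, rate = rate)
  }
  out
}

#' Simulate one BC1 meiosis with known crossover truth
#'
#' Draws crossover positions on the transmitted F1 gamete for every
#' chromosome of a genome model, converts them from map to physical
#' coordinates (assuming a uniform recombination rate along the chromosome),
#' and assigns the offspring's starting zygosity phase at position 1 of each
#' chromosome (heterozygous if the gamete carries the Ws allele there,
#' homozygous Col-0 otherwise, each with probability 1/2).
#'
#' @param genome A [genome_model()].
#' @param nu Gamma interference shape passed to [simulate_crossovers()].
#' @return A tibble of class `meiosis_truth` with one row per chromosome:
#'   `chrom`, `start_phase` (`"HET"` or `"HOM_COL"`) and `co_pos_bp`
#'   (list-column of sorted integer crossover positions in bp).
#' @export
simulate_meiosis <- function(genome, nu = 5) {
  stopifnot(inherits(genome, "genome_model"))
  rows <- purrr::pmap(
    list(genome$chrom, genome$length_bp, genome$genetic_length_cM),
    function(cn, L_bp, L_cM) {
      cm <- simulate_crossovers(L_cM, nu = nu)
      bp <- if (L_cM > 0) sort(as.integer(round(cm / L_cM * L_bp))) else integer(0)
      bp <- bp[bp >= 1 & bp <= L_bp]
      tibble(chrom = cn,
             start_phase = sample(c("HET", "HOM_COL"), 1),
             co_pos_bp = list(bp))
    }
  )
  out <- bind_rows(rows)
  class(out) <- c("meiosis_truth", class(out))
  out
}

#' Zygosity of a BC1 individual at a locus
#'
#' The offspring's zygosity flips between heterozygous (Col-0/Ws) and
#' homozygous Col-0 at every crossover: the zygosity at a position equals the
#' chromosome's starting phase flipped once per crossover to its left.
#'
#' @param truth A `meiosis_truth` tibble from [simulate_meiosis()].
#' @param chrom Chromosome name.
#' @param pos_bp Position(s) in bp; vectorised.
#' @return Character vector, `"HET"` or `"HOM_COL"`.
#' @export
zygosity_at <- function(truth, chrom, pos_bp) {
  i <- match(chrom, truth$chrom)
  if (is.na(i)) abort(paste0("unknown chromosome: ", chrom))
  cos <- truth$co_pos_bp[[i]]
  flips <- findInterval(pos_bp, cos + 0.5)  # number of COs strictly < pos
  phases <- c("HET", "HOM_COL")
  start <- match(truth$start_phase[i], phases)
  phases[(start - 1 + flips) %% 2 + 1]
}

#' Simulate per-SNP allele read counts for a BC1 individual
#'
#' Sequencing depth at each informative SNP is Poisson with mean
#' `coverage_mean`. At heterozygous sites each read carries the Col-0
#' (reference) allele with probability 1/2; at homozygous-Col sites every
#' read is Col-0. Each read's allele call is then flipped with probability
#' `error_rate`, modelling sequencing and mapping error.
#'
#' @param truth A `meiosis_truth` from [simulate_meiosis()].
#' @param genome The [genome_model()] used to simulate `truth`.
#' @param coverage_mean Mean reads per site (the study's samples ranged from
#'   1.0- to 8.7-fold; the default matches its low-coverage regime).
#' @param error_rate Per-read allele-flip probability, in `[0, 0.5]`.
#' @param sample_id Sample identifier stored in the output.
#' @return A tibble of allele counts: `sample_id`, `chrom`, `pos`
#'   (1-based bp), `ref_count` (reads calling the Col-0 allele) and
#'   `alt_count` (reads calling the Ws allele).
#' @export
simulate_backcross_counts <- function(truth, genome, coverage_mean = 3,
                                      error_rate = 0.005,
                                      sample_id = "sim") {
  stopifnot(inherits(genome, "genome_model"))
  if (coverage_mean < 0) abort("`coverage_mean` must be >= 0")
  if (error_rate < 0 || error_rate > 0.5) {
    abort("`error_rate` must be in [0, 0.5]")
  }
  per_chr <- purrr::map2(genome$chrom, genome$snps, function(cn, pos) {
    zy <- zygosity_at(truth, cn, pos)
    d <- rpois(length(pos), coverage_mean)
    r_true <- ifelse(zy == "HET", rbinom(length(pos), d, 0.5), d)
    a_true <- d - r_true
    flip_r <- rbinom(length(pos), r_true, error_rate)
    flip_a <- rbinom(length(pos), a_true, error_rate)
    tibble(sample_id = sample_id, chrom = cn, pos = pos,
           ref_count = as.integer(r_true - flip_r + flip_a),
           alt_count = as.integer(a_true - flip_a + flip_r))
  })
  bind_rows(per_chr)
}

#' Simulate a cohort of BC1 individuals
#'
#' Convenience wrapper drawing `n_samples` independent meioses from the same
#' genome and sequencing each at the given coverage and error rate.
#'
#' @inheritParams simulate_backcross_counts
#' @param n_samples Number of BC1 individuals.
#' @param nu Gamma interference shape for [simulate_meiosis()].
#' @return A list with `counts` (one tibble of allele counts for all
#'   samples) and `truths` (named list of `meiosis_truth` tibbles).
#' @export
simulate_bc1_cohort <- function(genome, n_samples = 40, coverage_mean = 3,
                                error_rate = 0.005, nu = 5) {
  ids <- sprintf("BC1_%03d", seq_len(n_samples))
  truths <- vector("list", n_samples)
  names(truths) <- ids
  counts <- vector("list", n_samples)
  for (i in seq_len(n_samples)) {
    truths[[i]] <- simulate_meiosis(genome, nu = nu)
    counts[[i]] <- simulate_backcross_counts(
      truths[[i]], genome, coverage_mean = coverage_mean,
      error_rate = error_rate, sample_id = ids[i])
  }
  list(counts = bind_rows(counts), truths = truths)
}
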