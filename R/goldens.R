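#' Expand a joint ditype count table into explicit tetrad records
#'
#' Given counts of tetrads per joint ditype class over two adjacent
#' intervals (flanked by coupled markers `m1`, `m2`, `m3`), constructs one
#' canonical spore pattern per class combination: the first interval's
#' class fixes the `(m1, m2)` spore patterns (PD: 11/11/00/00, TT:
#' 11/10/01/00, NPD: 10/10/01/01) and the second interval's class then
#' fixes `m3` relative to `m2` (PD: equal, NPD: opposite, TT: one spore of
#' each combination). The expansion is deterministic and classification
#' with [interval_ditype()] recovers the input classes exactly.
#'
#' @param counts Tibble with columns `class1`, `class2` (values `PD`, `TT`,
#'   `NPD`) and `n` (tetrad count per class pair).
#' @return A tetrad tibble (`tetrad_id`, `s1_m1 ... s4_m3`).
#' @export
ditype_counts_to_tetrads <- function(counts) {
  m12 <- list(
    PD  = cbind(m1 = c(TRUE, TRUE, FALSE, FALSE),
                m2 = c(TRUE, TRUE, FALSE, FALSE)),
    TT  = cbind(m1 = c(TRUE, TRUE, FALSE, FALSE),
                m2 = c(TRUE, FALSE, TRUE, FALSE)),
    NPD = cbind(m1 = c(TRUE, TRUE, FALSE, FALSE),
                m2 = c(FALSE, FALSE, TRUE, TRUE))
  )
  m3_for <- function(m2, cls2) {
    switch(cls2,
      PD = m2,
      NPD = !m2,
      TT = {
        m3 <- logical(4)
        m3[which(m2)[1]] <- TRUE    # one of the two m2-carrying spores
        m3[which(!m2)[1]] <- TRUE   # one of the two m2-lacking spores
        m3
      },
      abort(paste0("unknown ditype class: ", cls2)))
  }
  rows <- purrr::pmap(list(counts$class1, counts$class2, counts$n),
                      function(c1, c2, nn) {
    sp12 <- m12[[c1]]
    if (is.null(sp12)) abort(paste0("unknown ditype class: ", c1))
    m3 <- m3_for(sp12[, "m2"], c2)
    one <- tibble(
      s1_m1 = sp12[1, 1], s2_m1 = sp12[2, 1],
      s3_m1 = sp12[3, 1], s4_m1 = sp12[4, 1],
      s1_m2 = sp12[1, 2], s2_m2 = sp12[2, 2],
      s3_m2 = sp12[3, 2], s4_m2 = sp12[4, 2],
      s1_m3 = m3[1], s2_m3 = m3[2], s3_m3 = m3[3], s4_m3 = m3[4])
    one[rep(1L, nn), ]
  })
  out <- bind_rows(rows)
  out <- dplyr::bind_cols(tibble(tetrad_id = sprintf("t%06d",
                                                     seq_len(nrow(out)))),
                          out)
  out
}

#' Synthetic stand-ins for the published golden data sets
#'
#' The raw tetrad, single-pollen and single-molecule overview tables behind
#' the published summary statistics are not redistributed with this
#' package. These loaders return *synthetic reconstructions*: minimal data
#' sets constructed so that the package's own estimators reproduce the
#' published summary values at their printed precision (map distances,
#' interference ratios, tetrad totals, recombinant fractions and
#' oligo/protein fold changes). They exercise the full analysis path, but
#' carry no information about the real raw data beyond those summaries.
#'
#' @param experiment For tetrads, `"I5cd"` (chromosome 5 interval pair) or
#'   `"I2ab"` (chromosome 2 interval pair).
#' @param genotype Genotype label as used in the fixture files (e.g.
#'   `"wild_type"`, `"atm-2"`, `"msh4"`, `"msh4 atm-2"`, `"tel1d"`).
#' @return `synthetic_golden_tetrads()`: a tetrad tibble with markers `m1`,
#'   `m2`, `m3` flanking the two intervals, plus attributes `intervals` and
#'   `focal`. `synthetic_golden_pollen()`: a pollen tibble (`pollen_id`,
#'   `mA`, `mB`). `synthetic_golden_sim_tirf()`: the per-image manifest
#'   tibble (`organism`, `genotype`, `channel`, `image_id`, `n_maxima`,
#'   `lysate_volume`).
#' @export
synthetic_golden_tetrads <- function(experiment = c("I5cd", "I2ab"),
                                     genotype = "wild_type") {
  experiment <- match.arg(experiment)
  path <- system.file("extdata", "tetrad_ditype_counts_synthetic.csv",
                      package = "meiorec", mustWork = TRUE)
  counts <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  counts <- counts[counts$experiment == experiment &
                     counts$genotype == genotype, ]
  if (nrow(counts) == 0) {
    abort(paste0("no golden counts for ", experiment, " / ", genotype))
  }
  out <- ditype_counts_to_tetrads(counts)
  attr(out, "intervals") <- c(counts$interval1[1], counts$interval2[1])
  attr(out, "focal") <- counts$focal[1]
  out
}

#' @rdname synthetic_golden_tetrads
#' @export
synthetic_golden_pollen <- function(genotype = "wild_type") {
  path <- system.file("extdata", "pollen_counts_synthetic.csv",
                      package = "meiorec", mustWork = TRUE)
  counts <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  counts <- counts[counts$genotype == genotype, ]
  if (nrow(counts) != 1) {
    abort(paste0("no golden pollen counts for genotype ", genotype))
  }
  n <- counts$n_pollen; nr <- counts$n_recombinant
  n_par <- n - nr
  tibble(
    pollen_id = sprintf("p%05d", seq_len(n)),
    mA = c(rep(TRUE, nr), rep(TRUE, ceiling(n_par / 2)),
           rep(FALSE, floor(n_par / 2))),
    mB = c(rep(FALSE, nr), rep(TRUE, ceiling(n_par / 2)),
           rep(FALSE, floor(n_par / 2)))
  )
}

#' @rdname synthetic_golden_tetrads
#' @export
synthetic_golden_sim_tirf <- function() {
  path <- system.file("extdata", "sim_tirf_overview_synthetic.csv",
                      package = "meiorec", mustWork = TRUE)
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}
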