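#' Simulate pollen tetrads for two adjacent marked intervals
#'
#' Each meiosis carries at most one chiasma per interval (a reasonable
#' approximation for intervals of a few centimorgans, where double chiasmata
#' within an interval are vanishingly rare). The chiasma indicator for
#' interval i is Bernoulli with probability `d_i/50` (so that the expected
#' tetratype frequency is `2 d_i/100` and Perkins' formula recovers `d_i`),
#' and the joint probability of chiasmata in both intervals is
#' `S * (d1/50) * (d2/50)`, where `S` is the coefficient of coincidence
#' (`S < 1`: interference; `S = 1`: independence; `S > 1`: clustering).
#'
#' A chiasma exchanges the chromatid segments distal to its position between
#' one chromatid of each homolog, chosen uniformly and independently per
#' interval (no chromatid interference). The three markers (`m1`, `m2`,
#' `m3`) are coupled: both chromatids of one homolog carry all three, the
#' other homolog none, as for hemizygous fluorescent transgenes.
#'
#' @param n Number of tetrads (meioses) to simulate.
#' @param d1,d2 True map lengths of the two intervals in cM, each in
#'   `[0, 50)`.
#' @param S Coefficient of coincidence, `S >= 0`; the joint probability
#'   `S*(d1/50)*(d2/50)` must not exceed `min(d1, d2)/50`.
#' @return A tibble with one row per tetrad: `tetrad_id` and logical marker
#'   presence columns `s1_m1 ... s4_m3` (spore 1..4 x marker m1..m3).
#' @export
#' @examples
#' set.seed(1)
#' tt <- simulate_tetrads(1000, d1 = 6, d2 = 6, S = 1)
#' perkins_distance(tt, c("m1", "m2"))
simulate_tetrads <- function(n, d1, d2, S = 1) {
  if (d1 < 0 || d1 >= 50 || d2 < 0 || d2 >= 50) {
    abort("interval distances must lie in [0, 50) cM")
  }
  if (S < 0) abort("`S` must be >= 0")
  p1 <- d1 / 50; p2 <- d2 / 50
  p12 <- S * p1 * p2
  if (p12 > min(p1, p2) + 1e-12 || 1 - p1 - p2 + p12 < -1e-12) {
    abort("infeasible joint chiasma probability: S too large for d1, d2")
  }
  u <- runif(n)
  both <- u < p12
  only1 <- !both & u < p1
  only2 <- !both & !only1 & u < p1 + (p2 - p12)
  c1 <- both | only1
  c2 <- both | only2

  # strands 1,2 are the two chromatids of the marker-carrying homolog,
  # strands 3,4 of the unmarked homolog. A chiasma joins the molecules
  # occupying one strand of each homolog at its position, so the molecules
  # (future spores) are tracked through the strand permutation: a marker's
  # presence in a spore is the homolog of the strand the spore's molecule
  # occupies at the marker position.
  i1 <- sample(1:2, n, replace = TRUE)  # interval-1 chiasma strands
  j1 <- sample(3:4, n, replace = TRUE)
  i2 <- sample(1:2, n, replace = TRUE)  # interval-2 chiasma strands
  j2 <- sample(3:4, n, replace = TRUE)

  m1 <- matrix(rep(c(TRUE, TRUE, FALSE, FALSE), each = n), n, 4)
  m2 <- m1
  r1 <- which(c1)
  m2[cbind(r1, i1[r1])] <- FALSE
  m2[cbind(r1, j1[r1])] <- TRUE
  # molecules occupying strands i2/j2 after the interval-1 exchange
  a <- ifelse(c1 & i2 == i1, j1, i2)
  b <- ifelse(c1 & j2 == j1, i1, j2)
  m3 <- m2
  r2 <- which(c2)
  m3[cbind(r2, a[r2])] <- FALSE
  m3[cbind(r2, b[r2])] <- TRUE

  out <- tibble(tetrad_id = sprintf("t%06d", seq_len(n)))
  mk <- list(m1, m2, m3)
  for (s in 1:4) for (k in 1:3) {
    out[[sprintf("s%d_m%d", s, k)]] <- mk[[k]][, s]
  }
  out
}

#' Expand tetrads into single-pollen records
#'
#' Each tetrad contributes its four spores as individual pollen grains,
#' scored for the two markers flanking one focal interval. This reproduces
#' the single-pollen assay used when complete tetrads cannot be recovered:
#' grains carrying exactly one of the two markers are recombinant for the
#' interval.
#'
#' @param tetrads A tetrad tibble as produced by [simulate_tetrads()] or
#'   [read_tetrads()].
#' @param markers Character vector of the two flanking marker names, e.g.
#'   `c("m1", "m2")`.
#' @return A tibble with one row per pollen grain: `pollen_id`, `mA`, `mB`
#'   (logical marker presence).
#' @export
tetrads_to_pollen <- function(tetrads, markers = c("m1", "m2")) {
  stopifnot(length(markers) == 2)
  long <- tidyr::pivot_longer(
    tetrads,
    cols = dplyr::matches("^s[1-4]_m[0-9]+$"),
    names_to = c("spore", "marker"), names_sep = "_",
    values_to = "present")
  wide <- tidyr::pivot_wider(long, names_from = "marker",
                             values_from = "present")
  tibble(
    pollen_id = paste0(wide$tetrad_id, "_", wide$spore),
    mA = wide[[markers[1]]],
    mB = wide[[markers[2]]]
  )
}
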