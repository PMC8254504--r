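#' Validate 2:2 marker segregation in tetrads
#'
#' A well-formed tetrad from a hemizygous transgene shows each marker in
#' exactly two of the four spores. Records violating this (gene conversion,
#' scoring error, incomplete tetrads) are rejected, never repaired.
#'
#' @param tetrads Tetrad tibble with columns `s1_m1 ... s4_mK`.
#' @param markers Marker names to check (default: all present).
#' @return Logical vector, `TRUE` for well-formed tetrads.
#' @export
tetrad_is_valid <- function(tetrads, markers = NULL) {
  if (is.null(markers)) {
    markers <- unique(sub("^s[1-4]_", "",
                          grep("^s[1-4]_m", names(tetrads), value = TRUE)))
  }
  ok <- rep(TRUE, nrow(tetrads))
  for (mk in markers) {
    cols <- paste0("s", 1:4, "_", mk)
    tot <- rowSums(as.matrix(tetrads[, cols]))
    ok <- ok & tot == 2L
  }
  ok
}

#' Classify the ditype of each tetrad for one marked interval
#'
#' For two linked markers, the four spores of a tetrad fall into one of
#' three classes: parental ditype (PD; two spores carry both markers, two
#' carry neither), nonparental ditype (NPD; two spores carry only the first
#' marker, two only the second) or tetratype (TT; one spore of each of the
#' four combinations). PD tetrads carry no crossover in the interval, TT one
#' and NPD two (on all four chromatids).
#'
#' @param tetrads Tetrad tibble.
#' @param markers Character vector of the two interval-flanking markers.
#' @return Factor with levels `PD`, `TT`, `NPD`; `NA` for malformed tetrads
#'   (non-2:2 segregation or an impossible spore pattern).
#' @export
#' @examples
#' t1 <- tibble::tibble(tetrad_id = "t1",
#'   s1_m1 = TRUE,  s2_m1 = TRUE,  s3_m1 = FALSE, s4_m1 = FALSE,
#'   s1_m2 = TRUE,  s2_m2 = FALSE, s3_m2 = TRUE,  s4_m2 = FALSE)
#' interval_ditype(t1, c("m1", "m2"))  # TT
interval_ditype <- function(tetrads, markers) {
  stopifnot(length(markers) == 2)
  a <- as.matrix(tetrads[, paste0("s", 1:4, "_", markers[1])])
  b <- as.matrix(tetrads[, paste0("s", 1:4, "_", markers[2])])
  n11 <- rowSums(a & b)
  n10 <- rowSums(a & !b)
  n01 <- rowSums(!a & b)
  n00 <- rowSums(!a & !b)
  cls <- rep(NA_character_, nrow(tetrads))
  cls[n11 == 2 & n00 == 2 & n10 == 0] <- "PD"
  cls[n10 == 2 & n01 == 2 & n11 == 0] <- "NPD"
  cls[n11 == 1 & n10 == 1 & n01 == 1 & n00 == 1] <- "TT"
  factor(cls, levels = c("PD", "TT", "NPD"))
}

#' Genetic distance from tetrad counts (Perkins' formula)
#'
#' Map distance in centimorgans from the ditype spectrum of an interval:
#' `cM = 100 * (TT/2 + 3*NPD) / n`. Malformed tetrads are excluded from `n`
#' and reported in the result.
#'
#' @param tetrads Tetrad tibble.
#' @param interval Character vector of the two flanking markers.
#' @param label Optional interval label for the output (defaults to
#'   `"m1:m2"` style).
#' @return A one-row tibble: `interval`, `n`, `PD`, `TT`, `NPD`,
#'   `n_malformed`, `cM`.
#' @export
#' @examples
#' set.seed(1)
#' perkins_distance(simulate_tetrads(5000, 6, 6), c("m1", "m2"))
perkins_distance <- function(tetrads, interval, label = NULL) {
  if (nrow(tetrads) == 0) abort("no tetrads supplied")
  cls <- interval_ditype(tetrads, interval)
  n_bad <- sum(is.na(cls))
  cls <- cls[!is.na(cls)]
  n <- length(cls)
  if (n == 0) abort("no classifiable tetrads")
  tab <- table(cls)
  tibble(
    interval = label %||% paste(interval, collapse = ":"),
    n = n,
    PD = as.integer(tab[["PD"]]),
    TT = as.integer(tab[["TT"]]),
    NPD = as.integer(tab[["NPD"]]),
    n_malformed = n_bad,
    cM = 100 * (tab[["TT"]] / 2 + 3 * tab[["NPD"]]) / n
  )
}

#' Crossover interference ratio between two adjacent intervals
#'
#' Tetrads are partitioned by the crossover status of the adjacent interval
#' (PD = no crossover; TT or NPD = crossover), and the Perkins map distance
#' of the focal interval is computed within each subgroup. The interference
#' ratio is `IFR = cM(focal | adjacent CO) / cM(focal | adjacent no CO)`:
#' values below 1 indicate crossover interference, values above 1 crossover
#' clustering.
#'
#' @param tetrads Tetrad tibble.
#' @param focal Markers of the focal interval (distance is measured here).
#' @param adjacent Markers of the adjacent interval (used to subgroup).
#' @return A one-row tibble with subgroup sizes, subgroup distances
#'   `cM_with` / `cM_without` and `IFR`. `IFR` is `NA` with a warning when a
#'   subgroup is empty or the no-CO subgroup distance is zero.
#' @export
interference_ratio <- function(tetrads, focal, adjacent) {
  cls_f <- interval_ditype(tetrads, focal)
  cls_a <- interval_ditype(tetrads, adjacent)
  keep <- !is.na(cls_f) & !is.na(cls_a)
  cls_f <- cls_f[keep]; cls_a <- cls_a[keep]
  adj_co <- cls_a %in% c("TT", "NPD")
  perk <- function(cl) {
    if (length(cl) == 0) return(NA_real_)
    100 * (sum(cl == "TT") / 2 + 3 * sum(cl == "NPD")) / length(cl)
  }
  cm_with <- perk(cls_f[adj_co])
  cm_without <- perk(cls_f[!adj_co])
  ifr <- if (is.na(cm_with) || is.na(cm_without) || cm_without == 0) {
    warn("interference ratio undefined: empty subgroup or zero baseline distance")
    NA_real_
  } else cm_with / cm_without
  tibble(
    focal = paste(focal, collapse = ":"),
    adjacent = paste(adjacent, collapse = ":"),
    n = length(cls_f),
    n_with = sum(adj_co),
    n_without = sum(!adj_co),
    cM_with = cm_with,
    cM_without = cm_without,
    IFR = ifr
  )
}

#' Crossover event spectrum across intervals
#'
#' Counts crossover events per tetrad, summed over intervals with PD, TT and
#' NPD contributing 0, 1 and 2 events respectively, and tabulates tetrads in
#' classes 0, 1, 2 and 3+.
#'
#' @param tetrads Tetrad tibble.
#' @param intervals List of two-marker character vectors.
#' @return A tibble with columns `events` (`"0"`, `"1"`, `"2"`, `"3+"`) and
#'   `n`; the attribute `n_malformed` counts excluded tetrads.
#' @export
tetrad_event_spectrum <- function(tetrads,
                                  intervals = list(c("m1", "m2"),
                                                   c("m2", "m3"))) {
  ev <- rep(0L, nrow(tetrads))
  ok <- rep(TRUE, nrow(tetrads))
  for (iv in intervals) {
    cls <- interval_ditype(tetrads, iv)
    ok <- ok & !is.na(cls)
    ev <- ev + dplyr::coalesce(c(PD = 0L, TT = 1L, NPD = 2L)[as.character(cls)], 0L)
  }
  ev <- ev[ok]
  cls <- cut(ev, breaks = c(-0.5, 0.5, 1.5, 2.5, Inf),
             labels = c("0", "1", "2", "3+"))
  out <- as_tibble(table(events = cls), n = "n")
  out$n <- as.integer(out$n)
  attr(out, "n_malformed") <- sum(!ok)
  out
}

#' Genetic distance from single-pollen records
#'
#' For a single marked interval scored in individual pollen grains, grains
#' carrying exactly one of the two flanking markers are recombinant, and the
#' map distance is `cM = 100 * recombinants / n`.
#'
#' @param pollen Tibble with logical columns `mA`, `mB` (one row per grain).
#' @return A one-row tibble: `n`, `n_recombinant`, `cM`.
#' @export
single_pollen_distance <- function(pollen) {
  if (nrow(pollen) == 0) abort("no pollen records supplied")
  rec <- xor(pollen$mA, pollen$mB)
  tibble(n = nrow(pollen),
         n_recombinant = sum(rec),
         cM = 100 * sum(rec) / nrow(pollen))
}

#' Fisher's exact test for a difference in recombination frequency
#'
#' Compares two recombinant proportions (recombinants out of totals) with a
#' two-sided Fisher's exact test on the 2x2 table
#' `[[rec1, tot1 - rec1], [rec2, tot2 - rec2]]`, summing the point
#' probabilities of all tables as or less probable than the observed one.
#'
#' @param rec1,tot1 Recombinant count and total for group 1.
#' @param rec2,tot2 Recombinant count and total for group 2.
#' @return Two-sided p-value.
#' @export
#' @examples
#' fisher_recombination_test(272, 4382, 291, 2723)
fisher_recombination_test <- function(rec1, tot1, rec2, tot2) {
  counts <- c(rec1, tot1, rec2, tot2)
  if (any(counts < 0) || any(counts != round(counts))) {
    abort("counts must be non-negative integers")
  }
  if (rec1 > tot1 || rec2 > tot2) abort("recombinants exceed totals")
  tab <- matrix(c(rec1, tot1 - rec1, rec2, tot2 - rec2),
                nrow = 2, byrow = TRUE)
  fisher.test(tab)$p.value
}
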