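mk_tetrad <- function(patterns) {
  # patterns: 4 strings like "11", "10" giving (m1, m2) per spore
  out <- tibble::tibble(tetrad_id = "t1")
  for (s in 1:4) {
    out[[paste0("s", s, "_m1")]] <- substr(patterns[s], 1, 1) == "1"
    out[[paste0("s", s, "_m2")]] <- substr(patterns[s], 2, 2) == "1"
  }
  out
}

test_that("ditype classification matches the PD/TT/NPD definitions", {
  expect_equal(as.character(interval_ditype(
    mk_tetrad(c("11", "11", "00", "00")), c("m1", "m2"))), "PD")
  expect_equal(as.character(interval_ditype(
    mk_tetrad(c("11", "10", "01", "00")), c("m1", "m2"))), "TT")
  expect_equal(as.character(interval_ditype(
    mk_tetrad(c("10", "10", "01", "01")), c("m1", "m2"))), "NPD")
  # non-2:2 segregation is malformed, not repaired
  expect_true(is.na(interval_ditype(
    mk_tetrad(c("11", "11", "10", "00")), c("m1", "m2"))))
  expect_false(tetrad_is_valid(mk_tetrad(c("11", "11", "10", "00")),
                               c("m1", "m2")))
})

test_that("Perkins' formula converts ditype counts to centimorgans", {
  counts <- tibble::tibble(class1 = c("PD", "TT"), class2 = "PD",
                           n = c(90, 10))
  res <- perkins_distance(ditype_counts_to_tetrads(counts), c("m1", "m2"))
  expect_equal(res$cM, 5.0)
  expect_equal(res[, c("PD", "TT", "NPD")],
               tibble::tibble(PD = 90L, TT = 10L, NPD = 0L))

  all_pd <- ditype_counts_to_tetrads(
    tibble::tibble(class1 = "PD", class2 = "PD", n = 50))
  expect_equal(perkins_distance(all_pd, c("m1", "m2"))$cM, 0)

  counts3 <- tibble::tibble(class1 = c("PD", "TT", "NPD"), class2 = "PD",
                            n = c(80, 18, 2))
  res3 <- perkins_distance(ditype_counts_to_tetrads(counts3), c("m1", "m2"))
  expect_equal(res3$cM, 15.0)  # 100 * (9 + 6) / 100

  expect_error(perkins_distance(all_pd[0, ], c("m1", "m2")), "no tetrads")
})

test_that("interference ratio compares focal distance across subgroups", {
  # adjacent-PD subgroup: 100 tetrads, focal TT = 20 -> 10 cM
  # adjacent-CO subgroup: 50 tetrads, focal TT = 2  -> 2 cM; IFR = 0.2
  counts <- tibble::tibble(
    class1 = c("PD", "PD", "TT", "TT"),   # adjacent interval
    class2 = c("PD", "TT", "PD", "TT"),   # focal interval
    n = c(80, 20, 48, 2))
  tt <- ditype_counts_to_tetrads(counts)
  res <- interference_ratio(tt, focal = c("m2", "m3"),
                            adjacent = c("m1", "m2"))
  expect_equal(res$n_with, 50)
  expect_equal(res$n_without, 100)
  expect_equal(res$cM_with, 2)
  expect_equal(res$cM_without, 10)
  expect_equal(res$IFR, 0.2)

  # no adjacent crossover anywhere: ratio undefined
  no_adj <- ditype_counts_to_tetrads(
    tibble::tibble(class1 = "PD", class2 = c("PD", "TT"), n = c(5, 5)))
  expect_warning(res2 <- interference_ratio(no_adj, c("m2", "m3"),
                                            c("m1", "m2")),
                 "undefined")
  expect_true(is.na(res2$IFR))
})

test_that("interference ratio recovers the simulated coincidence", {
  set.seed(66)
  n <- 100000
  # independence: IFR ~ 1
  t1 <- simulate_tetrads(n, 6, 6, S = 1)
  r1 <- interference_ratio(t1, c("m2", "m3"), c("m1", "m2"))
  se1 <- r1$IFR * sqrt(1 / (r1$cM_with / 100 * r1$n_with * 2) +
                         1 / (r1$cM_without / 100 * r1$n_without * 2))
  expect_lt(abs(r1$IFR - 1), 3 * se1)

  # interference S = 0.2: exact model value S(1-p2)/(1-S*p2)
  t2 <- simulate_tetrads(n, 6, 6, S = 0.2)
  r2 <- interference_ratio(t2, c("m2", "m3"), c("m1", "m2"))
  p2 <- 6 / 50
  theo <- 0.2 * (1 - p2) / (1 - 0.2 * p2)
  se2 <- r2$IFR * sqrt(1 / (r2$cM_with / 100 * r2$n_with * 2) +
                         1 / (r2$cM_without / 100 * r2$n_without * 2))
  expect_lt(abs(r2$IFR - theo), 3 * se2)
  expect_lt(abs(r2$IFR - 0.2), 0.05)
})

test_that("event spectrum counts crossovers per tetrad", {
  counts <- tibble::tibble(
    class1 = c("PD", "TT", "TT"), class2 = c("PD", "PD", "TT"),
    n = c(70, 20, 10))
  sp <- tetrad_event_spectrum(ditype_counts_to_tetrads(counts))
  expect_equal(sp$n, c(70L, 20L, 10L, 0L))
  expect_equal(sum(sp$n), 100L)  # conservation

  one_tt_tt <- ditype_counts_to_tetrads(
    tibble::tibble(class1 = "TT", class2 = "TT", n = 1))
  sp2 <- tetrad_event_spectrum(one_tt_tt)
  expect_equal(sp2$n[sp2$events == "2"], 1L)

  # NPD counts two events: TT + NPD lands in class 3+
  tt_npd <- ditype_counts_to_tetrads(
    tibble::tibble(class1 = "TT", class2 = "NPD", n = 1))
  sp3 <- tetrad_event_spectrum(tt_npd)
  expect_equal(sp3$n[sp3$events == "3+"], 1L)
})

test_that("single-pollen distance is the recombinant fraction", {
  pollen <- tibble::tibble(
    pollen_id = sprintf("p%d", 1:1000),
    mA = c(rep(TRUE, 62), rep(TRUE, 469), rep(FALSE, 469)),
    mB = c(rep(FALSE, 62), rep(TRUE, 469), rep(FALSE, 469)))
  expect_equal(single_pollen_distance(pollen)$cM, 6.2)
  none <- pollen[63:1000, ]
  expect_equal(single_pollen_distance(none)$cM, 0)
  expect_error(single_pollen_distance(pollen[0, ]), "no pollen")
})

test_that("Fisher test matches exhaustive hypergeometric enumeration", {
  expect_equal(fisher_recombination_test(10, 100, 10, 100), 1.0)
  cases <- list(c(10, 100, 20, 100), c(3, 40, 9, 35), c(0, 25, 5, 25),
                c(69, 4038, 118, 1685))
  for (cs in cases) {
    expect_equal(fisher_recombination_test(cs[1], cs[2], cs[3], cs[4]),
                 fisher_oracle(cs[1], cs[2], cs[3], cs[4]),
                 tolerance = 1e-10)
  }
  expect_lt(fisher_recombination_test(0, 50, 50, 50), 1e-10)
  expect_error(fisher_recombination_test(10, 5, 1, 10), "exceed")
})
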