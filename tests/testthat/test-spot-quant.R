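test_that("maxima finder matches ImageJ-style prominence semantics", {
  # constant image: nothing stands out
  expect_equal(nrow(find_maxima(matrix(500, 20, 20), 100)), 0)

  # single interior peak
  img <- matrix(0, 9, 9); img[5, 5] <- 10000
  mx <- find_maxima(img, 6000)
  expect_equal(nrow(mx), 1)
  expect_equal(c(mx$row, mx$col), c(5, 5))

  # peak not exceeding its surroundings by more than the tolerance is
  # absorbed: two peaks connected by a high ridge
  img2 <- matrix(0, 5, 9)
  img2[3, 2] <- 10000; img2[3, 8] <- 9000
  img2[3, 3:7] <- 8000  # ridge within 9000 - 6000? no: 9000 - 8000 < 6000
  expect_equal(nrow(find_maxima(img2, 6000, exclude_border = FALSE)), 1)
  # a deep valley separates them at a smaller tolerance
  expect_equal(nrow(find_maxima(img2, 500, exclude_border = FALSE)), 2)

  # plateau: one maximum at the centroid, halves rounded toward top-left
  img3 <- matrix(0, 9, 9); img3[4:5, 4:5] <- 8000
  mx3 <- find_maxima(img3, 1000)
  expect_equal(nrow(mx3), 1)
  expect_equal(c(mx3$row, mx3$col), c(4, 4))

  expect_error(find_maxima(matrix(numeric(0), 0, 0)), "non-empty")
})

test_that("border maxima are excluded when requested", {
  img <- matrix(0, 9, 9); img[1, 5] <- 10000
  expect_equal(nrow(find_maxima(img, 6000, exclude_border = TRUE)), 0)
  expect_equal(nrow(find_maxima(img, 6000, exclude_border = FALSE)), 1)

  set.seed(5)
  st <- render_spot_image(c(64, 64), n_spots = 4, amplitude = 10000,
                          sigma_px = 1.5, background = 500,
                          border_margin_px = 10)
  expect_equal(nrow(find_maxima(st$image, 6000)), 4)
})

test_that("synthetic ground truth is recovered with full recall/precision", {
  set.seed(6)
  st <- render_spot_image(c(256, 256), n_spots = 50, amplitude = 10000,
                          sigma_px = 2, background = 1000, noise_sd = 0)
  mx <- find_maxima(st$image, 6000)
  expect_equal(nrow(mx), 50)
  found <- paste(mx$row, mx$col)
  truth <- paste(st$centers$row, st$centers$col)
  expect_setequal(found, truth)

  # and with moderate noise
  set.seed(7)
  stn <- render_spot_image(c(256, 256), n_spots = 50, amplitude = 10000,
                           sigma_px = 2, background = 1000, noise_sd = 100)
  expect_equal(nrow(find_maxima(stn$image, 6000)), 50)
})

test_that("maxima counts are monotone non-increasing in tolerance", {
  set.seed(8)
  st <- render_spot_image(c(96, 96), n_spots = 8, amplitude = 9000,
                          sigma_px = 2, background = 800, noise_sd = 150)
  tols <- c(0, 200, 1000, 3000, 6000, 8000, 12000)
  counts <- vapply(tols, function(t) nrow(find_maxima(st$image, t)),
                   integer(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("maxima positions are translation-equivariant", {
  set.seed(9)
  st <- render_spot_image(c(64, 64), n_spots = 5, amplitude = 10000,
                          sigma_px = 1.5, background = 500,
                          border_margin_px = 16)
  img <- st$image
  shifted <- matrix(500L, 64, 64)
  shifted[7:64, 5:64] <- img[1:58, 1:60]  # shift by (+6, +4)
  m0 <- find_maxima(img, 6000)
  m1 <- find_maxima(shifted, 6000)
  expect_equal(nrow(m1), nrow(m0))
  expect_setequal(paste(m1$row, m1$col), paste(m0$row + 6, m0$col + 4))
})

test_that("noiseless renders hit background + amplitude at each center", {
  set.seed(10)
  st <- render_spot_image(c(64, 64), n_spots = 3, amplitude = 7000,
                          sigma_px = 2, background = 1200, noise_sd = 0)
  at_centers <- st$image[as.matrix(st$centers)]
  expect_true(all(abs(at_centers - 8200) <= 1))
  empty <- render_spot_image(c(16, 16), n_spots = 0, noise_sd = 0,
                             background = 300)
  expect_true(all(empty$image == 300))
  expect_error(render_spot_image(c(8, 8), n_spots = 50, sigma_px = 2),
               "separation|room")
})

test_that("oligo fractions normalize by lysate volume", {
  expect_equal(oligo_fraction(c(100, 100), c(200, 200)), 0.5)
  expect_equal(oligo_fraction(200, 400, oligo_volume = 2,
                              protein_volume = 1), 0.25)
  expect_equal(oligo_fraction(0, 400), 0)
  expect_warning(fr <- oligo_fraction(10, 0), "undefined")
  expect_true(is.na(fr))

  man <- tibble::tibble(
    genotype = "wt",
    channel = c("oligo", "oligo", "protein"),
    n_maxima = c(60, 40, 400),
    lysate_volume = c(50, 50, 100))
  expect_equal(genotype_fractions(man)$fraction, (100 / 50) / (400 / 100))
  # image order within the batch is irrelevant
  expect_equal(genotype_fractions(man[c(3, 1, 2), ])$fraction,
               genotype_fractions(man)$fraction)
})

test_that("fold changes divide mutant by wild-type fractions", {
  expect_equal(fold_change(0.4, 0.2)$fold_change, 2)
  expect_equal(fold_change(0.3, 0.3)$fold_change, 1)
  fc <- fold_change(c(0.4, 0.5), c(0.2, 0.25))
  expect_equal(fc$ratios, c(2, 2))
  expect_equal(fc$mean, 2)
  expect_equal(fc$sd, 0)
  expect_error(fold_change(0.4, 0), "> 0")
})
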