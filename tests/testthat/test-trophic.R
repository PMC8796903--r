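test_that("scaled TP model reproduces the published worked values (log10)", {
  p <- tp_params()
  # baseline: the two logs cancel exactly
  expect_identical(trophic_position(5.3, p), 2)
  expect_equal(round(trophic_position(12.3, p), 1), 3.7)
  expect_equal(round(trophic_position(8.9, p), 1), 2.8)
  expect_equal(round(trophic_position(14.8, p), 1), 4.6)
  expect_equal(round(trophic_position(14.2, p), 1), 4.4)
  expect_equal(round(trophic_position(11.5, p), 2), 3.45)
  expect_error(trophic_position(21.93, p), "saturating")
  expect_error(trophic_position(25, p), "saturating")
})

test_that("TP is baseline-exact, monotone and invertible for any valid params", {
  set.seed(31)
  for (i in 1:20) {
    base <- runif(1, 2, 8)
    lim <- base + runif(1, 5, 25)
    p <- tp_params(d15N_base = base, TP_base = runif(1, 1, 3),
                   d15N_lim = lim, k = runif(1, 0.05, 0.3))
    expect_equal(trophic_position(base, p), p$TP_base)
    d <- sort(runif(5, base - 2, lim - 0.1))
    tp <- trophic_position(d, p)
    expect_true(all(diff(tp) > 0))
    # round trip through the inverse
    expect_equal(d15n_for_tp(tp, p), d, tolerance = 1e-9)
  }
  expect_error(tp_params(d15N_base = 10, d15N_lim = 9), "exceed")
  expect_error(tp_params(k = 0), "k must be")
})

test_that("tp_series maps bands through the model with context in errors", {
  x <- tiny_band_table(bands = 1:2, d13C = c(-15, -14),
                       d15N = c(5.3, 12.3))
  s <- tp_series(x)
  expect_equal(s$tp, c(2, trophic_position(12.3)))
  expect_equal(s$band_index, 1:2)
  # constant series -> constant TP
  s2 <- tp_series(tiny_band_table(bands = 1:4, d13C = rep(-14, 4),
                                  d15N = rep(11, 4)))
  expect_equal(length(unique(s2$tp)), 1L)
  # empty in, empty out
  expect_equal(nrow(tp_series(x[0, ])), 0L)
  # saturating band is named
  bad <- tiny_band_table(bands = 1:2, d13C = c(-15, -14),
                         d15N = c(12, 22))
  expect_error(tp_series(bad), "band 2")
})

test_that("enrichment follows the printed form, including negative deltas", {
  x <- tiny_band_table(bands = 1:2, d13C = c(-15, -14),
                       d15N = c(10, 12.5))
  eN <- enrichment_series(x, element = "15N")
  expect_equal(eN$enrichment, c(0, (12.5 - 10) / 12.5))  # 0.2
  eC <- enrichment_series(x, element = "13C")
  expect_equal(eC$enrichment, c(0, -1 / 14))  # sign flips for negative delta
  # identical series -> all zeros
  flat <- enrichment_series(tiny_band_table(bands = 1:5,
                                            d13C = rep(-14, 5),
                                            d15N = rep(12, 5)),
                            element = "13C")
  expect_equal(flat$enrichment, rep(0, 5))
})

test_that("enrichment anchors at band 0 when present and ignores relabelling", {
  with0 <- tiny_band_table(bands = 0:2, d13C = c(-16, -15, -14),
                           d15N = rep(12, 3))
  e <- enrichment_series(with0, element = "13C")
  expect_equal(e$enrichment[1], 0)
  expect_equal(e$enrichment[2], (-15 - -16) / -15)
  # same deltas under shifted band labels -> same enrichment values
  shifted <- tiny_band_table(age = 9, bands = c(3, 5, 7),
                             d13C = c(-16, -15, -14), d15N = rep(12, 3))
  e2 <- enrichment_series(shifted, element = "13C")
  expect_equal(e2$enrichment, e$enrichment)
  # explicit birth band must exist; zero delta is a domain error
  expect_error(enrichment_series(with0, element = "13C", birth_band = 4),
               "not present")
  zero <- tiny_band_table(bands = 1:2, d13C = c(-1, 0) + 1,
                          d15N = c(12, 12), validate = FALSE)
  expect_error(enrichment_series(zero, element = "13C"), "division by zero")
})

test_that("cohort enrichment aligns individuals by band", {
  a <- tiny_band_table(id = "A", bands = 1:4, d13C = rep(-14, 4),
                       d15N = c(10, 10, 10, 12.5))
  b <- tiny_band_table(id = "B", bands = 1:3, d13C = rep(-14, 3),
                       d15N = c(10, 10, 13))
  x <- rbind(a, b)
  class(x) <- c("band_table", "data.frame")
  ce <- suppressWarnings(cohort_enrichment(x, "15N", by = "combined"))
  b3 <- ce[ce$band_index == 3, ]
  expect_equal(b3$n, 2L)
  expect_equal(b3$mean_enrichment, mean(c(0, 3 / 13)))
  # individual lacking band 4 is excluded from that band only
  b4 <- ce[ce$band_index == 4, ]
  expect_equal(b4$n, 1L)
  expect_equal(b4$se_enrichment, 0)
  expect_warning(cohort_enrichment(x, "15N"), "single individual")
  # hand-computed SE: enrichments 0.1 and 0.3 -> mean 0.2, SE 0.1
  expect_equal(vertiso:::se_mean(c(0.1, 0.3)), 0.1)
})
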