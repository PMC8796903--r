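test_that("standard ellipse areas match closed forms exactly", {
  pts <- exact_cov_cloud(40, diag(2))
  expect_equal(sea_ml(pts), pi, tolerance = 1e-12)
  pts2 <- exact_cov_cloud(40, diag(c(4, 1)))
  expect_equal(sea_ml(pts2), 2 * pi, tolerance = 1e-12)
  # rotation and translation invariance
  th <- 0.7
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  expect_equal(sea_ml(sweep(pts2 %*% t(R), 2, c(5, -3), "+")), 2 * pi)
  # linear map scales area by |det(A)|
  A <- matrix(c(2, 0.5, 0.3, 1.5), 2, 2)
  expect_equal(sea_ml(pts2 %*% t(A)), 2 * pi * abs(det(A)))
  expect_error(sea_ml(pts2[1:2, ]), "3 points")
  degen <- cbind(1:10, 2 * (1:10))  # collinear
  expect_error(sea_ml(degen), "degenerate")
})

test_that("small-sample correction is (n-1)/(n-2)", {
  p3 <- exact_cov_cloud(3, diag(2))
  expect_equal(sea_c(p3), 2 * sea_ml(p3))
  p4 <- exact_cov_cloud(4, diag(2))
  expect_equal(sea_c(p4), 1.5 * pi)
  p500 <- exact_cov_cloud(500, diag(2))
  expect_equal(sea_c(p500) / sea_ml(p500), 499 / 498)
})

test_that("probabilistic niche regions have chi-square areas", {
  e95 <- niche_region(c(0, 0), diag(2), p = 0.95)
  expect_equal(e95$area, qchisq(0.95, 2) * pi)
  expect_equal(e95$area, -2 * log(0.05) * pi)  # closed form
  # q = 1 recovers the standard ellipse
  e1 <- niche_region(c(0, 0), diag(2), q = 1)
  expect_equal(e1$area, pi)
  # area -> 0 as p -> 0
  expect_lt(niche_region(c(0, 0), diag(2), p = 1e-8)$area, 1e-6)
  expect_error(niche_region(c(0, 0), diag(2), p = 1.2), "between 0 and 1")
  expect_error(niche_region(c(0, 0), matrix(c(1, 2, 2, 1), 2), p = 0.5),
               "positive-definite")
  # boundary points sit at Mahalanobis radius sqrt(q)
  S <- matrix(c(2, 0.6, 0.6, 1), 2)
  e <- niche_region(c(1, -1), S, p = 0.9)
  b <- ellipse_boundary(e, 50)
  expect_equal(unname(mahalanobis(b, e$center, e$sigma)),
               rep(e$q, 50), tolerance = 1e-9)
})

test_that("posterior niche fit is seeded-reproducible and consistent", {
  pts <- simulate_two_group_cloud(2000, 3, c(0, 0), c(0, 0),
                                  diag(c(4, 1)), diag(2), seed = 5)$a
  f1 <- fit_niche(pts, n_draws = 4000, seed = 99)
  f2 <- fit_niche(pts, n_draws = 4000, seed = 99)
  expect_identical(f1$mu, f2$mu)
  expect_identical(f1$sea, f2$sea)
  # large-n: posterior median SEA_B within 5% of pi * sqrt(det(true cov))
  expect_equal(median(f1$sea), 2 * pi, tolerance = 0.05)
  # covariance draws are symmetric positive-definite
  dets <- apply(f1$sigma, 3, det)
  expect_true(all(dets > 0))
  expect_equal(f1$sigma[1, 2, ], f1$sigma[2, 1, ])
  # minimal n = 3 runs and yields a wide posterior
  f3 <- fit_niche(exact_cov_cloud(3, diag(2)), n_draws = 2000, seed = 1)
  expect_gt(diff(quantile(f3$sea, c(0.025, 0.975))), median(f3$sea))
})

test_that("posterior summary and print expose SEA, SEAc and intervals", {
  f <- fit_niche(exact_cov_cloud(30, diag(2)), n_draws = 2000, seed = 3,
                 group_label = "unit circle")
  sm <- summary(f)
  expect_equal(sm$sea_ml, pi)
  expect_equal(sm$sea_c, pi * 29 / 28)
  expect_true(sm$sea_b_ci["95%", "lower"] < sm$sea_b_median &&
                sm$sea_b_median < sm$sea_b_ci["95%", "upper"])
  expect_output(print(f), "unit circle")
  expect_output(print(sm), "SEA_B median")
})

test_that("directional overlap: self ~ p, separation ~ 0, containment ~ 1", {
  cl <- simulate_two_group_cloud(60, 60, c(0, 0), c(100, 100),
                                 diag(2), diag(2), seed = 21)
  fa <- fit_niche(cl$a, n_draws = 1500, seed = 7, group_label = "a")
  fb <- fit_niche(cl$b, n_draws = 1500, seed = 8, group_label = "b")
  self <- overlap_mc(fa, fa, p = 0.95, n_posterior = 600, n_mc = 4000,
                     seed = 10)
  expect_lt(abs(self$prob_a_in_region_b - 0.95),
            3 * self$prob_a_in_region_b_se)
  expect_equal(self$pct_of_a, 100)
  far <- overlap_mc(fa, fb, p = 0.95, n_posterior = 400, n_mc = 2000,
                    seed = 11)
  expect_lt(far$prob_a_in_region_b, 0.001)
  expect_equal(far$intersection_area, 0)
  # tiny cloud inside a broad region: probability ~ 1
  # closed form oracle: X ~ N(0, 0.01 I) => mahalanobis wrt I is 0.01*chisq2,
  # so P(inside 95% region of N(0, I)) = pchisq(qchisq(.95,2)/0.01, 2) ~ 1
  cl2 <- simulate_two_group_cloud(500, 500, c(0, 0), c(0, 0),
                                  0.01 * diag(2), diag(2), seed = 22)
  fs <- fit_niche(cl2$a, n_draws = 1000, seed = 12, group_label = "small")
  fl <- fit_niche(cl2$b, n_draws = 1000, seed = 13, group_label = "large")
  inb <- overlap_mc(fs, fl, p = 0.95, n_posterior = 300, n_mc = 2000,
                    seed = 14)
  expect_gt(inb$prob_a_in_region_b, 0.999)
})

test_that("ellipse intersection area is symmetric, bounded and exact in limits", {
  e1 <- niche_region(c(0, 0), diag(2), q = 1)       # circle r = 1, area pi
  e2 <- niche_region(c(0, 0), diag(2), q = 4)       # circle r = 2
  # containment: intersection = smaller area
  i12 <- ellipse_intersection_area(e1, e2, n_mc = 50000, seed = 2)
  expect_equal(unname(i12["area"]), pi, tolerance = 0.02)
  # symmetry in arguments (same seed, ellipses swapped)
  i21 <- ellipse_intersection_area(e2, e1, n_mc = 50000, seed = 2)
  expect_identical(i12, i21)
  # self-intersection
  iself <- ellipse_intersection_area(e1, e1, n_mc = 20000, seed = 3)
  expect_equal(unname(iself["area"]), e1$area)
  expect_equal(unname(iself["mc_se"]), 0)
  # disjoint
  e3 <- niche_region(c(10, 0), diag(2), q = 1)
  idis <- ellipse_intersection_area(e1, e3, n_mc = 10000, seed = 4)
  expect_equal(unname(idis["area"]), 0)
  # bounded by the smaller area for overlapping general ellipses
  e4 <- niche_region(c(0.5, 0), matrix(c(2, 0.5, 0.5, 1), 2), p = 0.9)
  i14 <- ellipse_intersection_area(e1, e4, n_mc = 20000, seed = 5)
  expect_lte(unname(i14["area"]), min(e1$area, e4$area))
})

test_that("posterior credible intervals are calibrated at small n", {
  # 100 replicates of n = 50 from a fixed truth: the central 95% interval
  # of the SEA_B posterior should cover pi*sqrt(det(cov)) in >= 90%
  S_true <- matrix(c(2, 0.7, 0.7, 1.2), 2)
  truth <- pi * sqrt(det(S_true))
  covered <- vapply(1:100, function(r) {
    pts <- simulate_two_group_cloud(50, 3, c(0, 0), c(0, 0), S_true,
                                    diag(2), seed = 1000 + r)$a
    f <- fit_niche(pts, n_draws = 1000, seed = 2000 + r)
    ci <- quantile(f$sea, c(0.025, 0.975))
    ci[1] <= truth && truth <= ci[2]
  }, logical(1))
  expect_gte(mean(covered), 0.90)
})
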