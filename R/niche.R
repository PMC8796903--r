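#' Maximum-likelihood standard ellipse area
#'
#' Area of the bivariate "standard ellipse" of an isotope point cloud:
#' pi * sqrt(det(S)), with S the unbiased sample covariance of (d13C, d15N).
#' Equivalently pi times the product of the covariance-eigenvalue square
#' roots. Invariant under rotation and translation of the cloud; under a
#' linear map A the area scales by |det(A)|.
#'
#' @param x two-column matrix/data frame of points, or the d13C vector.
#' @param y d15N vector when `x` is a vector.
#' @return area in per-mil squared.
#' @export
sea_ml <- function(x, y = NULL) {
  pts <- as_points(x, y)
  S <- stats::cov(pts)
  d <- det(S)
  if (!is.finite(d) || d <= .Machine$double.eps)
    stop("degenerate point cloud: sample covariance not positive-definite",
         call. = FALSE)
  pi * sqrt(d)
}

#' Small-sample corrected standard ellipse area
#'
#' `sea_ml * (n - 1) / (n - 2)`, the usual correction that makes the
#' expected area unbiased for small samples.
#'
#' @inheritParams sea_ml
#' @return area in per-mil squared.
#' @export
sea_c <- function(x, y = NULL) {
  pts <- as_points(x, y)
  n <- nrow(pts)
  sea_ml(pts) * (n - 1) / (n - 2)
}

as_points <- function(x, y = NULL) {
  pts <- if (is.null(y)) as.matrix(x) else cbind(x, y)
  if (ncol(pts) != 2L) stop("points must be bivariate", call. = FALSE)
  if (!all(is.finite(pts))) stop("points must be finite", call. = FALSE)
  if (nrow(pts) < 3L)
    stop("need at least 3 points for an ellipse", call. = FALSE)
  dimnames(pts) <- list(NULL, c("x", "y"))
  pts
}

#' Fit the Bayesian bivariate-normal isotopic niche
#'
#' Draws from the conjugate posterior of a bivariate normal under the
#' noninformative (Jeffreys-style) prior: with n observations, sample mean
#' x-bar and unbiased covariance S,
#' Sigma ~ inverse-Wishart(n - 1, (n - 1) S) and mu | Sigma ~ N(x-bar,
#' Sigma / n). Each draw yields a standard ellipse area pi * sqrt(det(Sigma)),
#' giving the posterior of the niche width (SEA_B). Draws are reproducible
#' given `seed`.
#'
#' @inheritParams sea_ml
#' @param n_draws number of posterior draws (default 10000).
#' @param seed integer seed, or `NULL` to use the current RNG stream.
#' @param group_label optional label carried into summaries.
#' @return an object of class `"niche_posterior"`: list with `mu`
#'   (n_draws x 2), `sigma` (2 x 2 x n_draws), `sea` (n_draws areas),
#'   `n_obs`, `xbar`, `S`, `group_label`, `seed`.
#' @export
fit_niche <- function(x, y = NULL, n_draws = 10000, seed = NULL,
                      group_label = "group") {
  pts <- as_points(x, y)
  n <- nrow(pts)
  S <- stats::cov(pts)
  if (det(S) <= .Machine$double.eps)
    stop("degenerate point cloud: sample covariance not positive-definite",
         call. = FALSE)
  xbar <- colMeans(pts)
  Sn <- (n - 1) * S
  with_seed(seed, {
    # Sigma ~ IW(n-1, Sn): invert Wishart(n-1, Sn^-1) draws.
    W <- stats::rWishart(n_draws, df = n - 1, Sigma = inv2(Sn))
    detW <- W[1, 1, ] * W[2, 2, ] - W[1, 2, ] * W[2, 1, ]
    sigma <- array(0, c(2, 2, n_draws))
    sigma[1, 1, ] <- W[2, 2, ] / detW
    sigma[2, 2, ] <- W[1, 1, ] / detW
    sigma[1, 2, ] <- sigma[2, 1, ] <- -W[1, 2, ] / detW
    sea <- pi / sqrt(detW)
    # mu | Sigma ~ N(xbar, Sigma/n), via the lower Cholesky of each Sigma.
    z1 <- stats::rnorm(n_draws); z2 <- stats::rnorm(n_draws)
    l11 <- sqrt(sigma[1, 1, ])
    l21 <- sigma[2, 1, ] / l11
    l22 <- sqrt(sigma[2, 2, ] - l21^2)
    mu <- cbind(xbar[1] + l11 * z1 / sqrt(n),
                xbar[2] + (l21 * z1 + l22 * z2) / sqrt(n))
    colnames(mu) <- c("x", "y")
    structure(list(mu = mu, sigma = sigma, sea = sea, n_obs = n,
                   xbar = xbar, S = S, group_label = group_label,
                   seed = seed),
              class = "niche_posterior")
  })
}

#' @export
print.niche_posterior <- function(x, ...) {
  cat(sprintf(
    "Bayesian bivariate-normal niche: %s (n = %d, %d posterior draws)\n",
    x$group_label, x$n_obs, length(x$sea)))
  cat(sprintf("  SEA (ML): %.3f   SEAc: %.3f   SEA_B median: %.3f\n",
              pi * sqrt(det(x$S)),
              pi * sqrt(det(x$S)) * (x$n_obs - 1) / (x$n_obs - 2),
              stats::median(x$sea)))
  invisible(x)
}

#' Summarize a fitted niche posterior
#'
#' @param object a [fit_niche()] result.
#' @param probs credible-interval levels for the SEA_B posterior.
#' @param ... unused.
#' @return list with the point summaries (posterior median SEA_B, SEA,
#'   SEAc) and the requested credible intervals.
#' @export
summary.niche_posterior <- function(object, probs = c(0.5, 0.75, 0.95),
                                    ...) {
  ci <- t(vapply(probs, function(p)
    stats::quantile(object$sea, c((1 - p) / 2, 1 - (1 - p) / 2),
                    names = FALSE), numeric(2)))
  dimnames(ci) <- list(paste0(probs * 100, "%"), c("lower", "upper"))
  out <- list(group_label = object$group_label, n_obs = object$n_obs,
              sea_ml = pi * sqrt(det(object$S)),
              sea_c = pi * sqrt(det(object$S)) *
                (object$n_obs - 1) / (object$n_obs - 2),
              sea_b_median = stats::median(object$sea),
              sea_b_ci = ci)
  class(out) <- "summary.niche_posterior"
  out
}

#' @export
print.summary.niche_posterior <- function(x, ...) {
  cat(sprintf("niche '%s' (n = %d)\n", x$group_label, x$n_obs))
  cat(sprintf("  SEA %.3f | SEAc %.3f | SEA_B median %.3f (per-mil^2)\n",
              x$sea_ml, x$sea_c, x$sea_b_median))
  print(round(x$sea_b_ci, 3))
  invisible(x)
}

#' Plot a fitted niche
#'
#' Data cloud with the maximum-likelihood standard ellipse (q = 1) and the
#' p-probability niche region.
#'
#' @param x a [fit_niche()] result.
#' @param p probability level of the outer region (default 0.95).
#' @param ... passed to [graphics::plot()].
#' @export
plot.niche_posterior <- function(x, p = 0.95, ...) {
  e1 <- niche_region(x$xbar, x$S, p = p)
  e0 <- structure(list(center = x$xbar, sigma = x$S, q = 1,
                       area = pi * sqrt(det(x$S))), class = "niche_ellipse")
  b1 <- ellipse_boundary(e1)
  graphics::plot(b1, type = "l", xlab = "d13C (per-mil)",
                 ylab = "d15N (per-mil)", main = x$group_label, ...)
  graphics::lines(ellipse_boundary(e0), lty = 2)
  invisible(x)
}

#' Probabilistic niche region (p-probability ellipse)
#'
#' The region {z : (z - mu)' Sigma^-1 (z - mu) <= q} with q the chi-square
#' (2 df) quantile at p, i.e. the set holding probability p under
#' N(mu, Sigma). Its area is q * pi * sqrt(det(Sigma)); at q = 1 it is the
#' standard ellipse.
#'
#' @param mean length-2 center.
#' @param sigma 2x2 positive-definite covariance.
#' @param p coverage probability in (0, 1), default 0.95.
#' @param q optional explicit Mahalanobis-squared radius overriding `p`
#'   (q = 1 gives the standard ellipse).
#' @return object of class `"niche_ellipse"`: `center`, `sigma`, `q`,
#'   `area`, plus half-axis lengths and orientation.
#' @export
niche_region <- function(mean, sigma, p = 0.95, q = NULL) {
  sigma <- as.matrix(sigma)
  if (any(dim(sigma) != 2L) || det(sigma) <= 0 || sigma[1, 1] <= 0)
    stop("covariance must be 2x2 positive-definite", call. = FALSE)
  if (is.null(q)) {
    if (!is.numeric(p) || p <= 0 || p >= 1)
      stop("p must lie strictly between 0 and 1", call. = FALSE)
    q <- stats::qchisq(p, df = 2)
  }
  ev <- eigen(sigma, symmetric = TRUE)
  structure(list(center = as.numeric(mean), sigma = sigma, q = q,
                 area = q * pi * sqrt(det(sigma)),
                 half_axes = sqrt(q * ev$values),
                 orientation = atan2(ev$vectors[2, 1], ev$vectors[1, 1])),
            class = "niche_ellipse")
}

#' @export
print.niche_ellipse <- function(x, ...) {
  cat(sprintf(
    "ellipse: center (%.3f, %.3f), half-axes %.3f x %.3f, area %.3f\n",
    x$center[1], x$center[2], x$half_axes[1], x$half_axes[2], x$area))
  invisible(x)
}

#' Boundary polyline of an ellipse
#'
#' @param e a [niche_region()] ellipse.
#' @param n number of vertices.
#' @return n x 2 matrix tracing the boundary (closed).
#' @export
ellipse_boundary <- function(e, n = 200) {
  L <- t(chol(e$sigma))
  th <- seq(0, 2 * pi, length.out = n)
  t(e$center + sqrt(e$q) * L %*% rbind(cos(th), sin(th)))
}

in_ellipse <- function(pts, e) {
  stats::mahalanobis(pts, e$center, e$sigma) <= e$q
}

#' Directional niche overlap between two fitted groups
#'
#' For each of `n_posterior` paired posterior draws, estimates by Monte
#' Carlo the probability that a point from group A's bivariate normal falls
#' inside group B's p-probability niche region (and symmetrically). Reports
#' the posterior mean of each directional probability with its Monte-Carlo
#' standard error, plus the geometric intersection of the two
#' point-estimate (sample mean / sample covariance) p-ellipses, both in
#' per-mil squared and as a percentage of each group's ellipse area.
#'
#' @param post_a,post_b [fit_niche()] results.
#' @param p niche-region probability level (default 0.95).
#' @param n_posterior posterior draws used (default 1000).
#' @param n_mc Monte-Carlo points per draw (default 10000).
#' @param seed integer seed for reproducibility.
#' @return list of class `"niche_overlap"` with `prob_a_in_region_b`,
#'   `prob_b_in_region_a` (each value + `mc_se`), `intersection_area` (+
#'   `mc_se`), `pct_of_a`, `pct_of_b`, and the labels.
#' @export
overlap_mc <- function(post_a, post_b, p = 0.95, n_posterior = 1000,
                       n_mc = 10000, seed = NULL) {
  stopifnot(inherits(post_a, "niche_posterior"),
            inherits(post_b, "niche_posterior"))
  q <- stats::qchisq(p, df = 2)
  n_posterior <- min(n_posterior, length(post_a$sea), length(post_b$sea))
  with_seed(seed, {
    dir_prob <- function(src, dst) {
      fr <- vapply(seq_len(n_posterior), function(i) {
        mu <- src$mu[i, ]
        Sg <- src$sigma[, , i]
        L <- t(chol(Sg))
        z <- matrix(stats::rnorm(2 * n_mc), 2, n_mc)
        pts <- t(mu + L %*% z)
        mean(stats::mahalanobis(pts, dst$mu[i, ], dst$sigma[, , i]) <= q)
      }, numeric(1))
      c(value = mean(fr), mc_se = stats::sd(fr) / sqrt(n_posterior))
    }
    ab <- dir_prob(post_a, post_b)
    ba <- dir_prob(post_b, post_a)
    ea <- niche_region(post_a$xbar, post_a$S, p = p)
    eb <- niche_region(post_b$xbar, post_b$S, p = p)
    inter <- ellipse_intersection_area(ea, eb, n_mc = 20000)
    structure(list(group_a = post_a$group_label,
                   group_b = post_b$group_label, p = p,
                   prob_a_in_region_b = ab[["value"]],
                   prob_a_in_region_b_se = ab[["mc_se"]],
                   prob_b_in_region_a = ba[["value"]],
                   prob_b_in_region_a_se = ba[["mc_se"]],
                   intersection_area = inter[["area"]],
                   intersection_area_se = inter[["mc_se"]],
                   pct_of_a = 100 * inter[["area"]] / ea$area,
                   pct_of_b = 100 * inter[["area"]] / eb$area),
              class = "niche_overlap")
  })
}

#' @export
print.niche_overlap <- function(x, ...) {
  cat(sprintf("niche overlap at p = %.2f\n", x$p))
  cat(sprintf("  P(%s in region of %s) = %.3f (MC SE %.4f)\n",
              x$group_a, x$group_b, x$prob_a_in_region_b,
              x$prob_a_in_region_b_se))
  cat(sprintf("  P(%s in region of %s) = %.3f (MC SE %.4f)\n",
              x$group_b, x$group_a, x$prob_b_in_region_a,
              x$prob_b_in_region_a_se))
  cat(sprintf(
    "  ellipse intersection %.3f per-mil^2 (%.1f%% of %s, %.1f%% of %s)\n",
    x$intersection_area, x$pct_of_a, x$group_a, x$pct_of_b, x$group_b))
  invisible(x)
}

#' Monte-Carlo area of an ellipse intersection
#'
#' Samples points uniformly inside the smaller ellipse and scales its known
#' area by the fraction falling inside the other, giving |e1 intersect e2|
#' with a binomial standard error. Symmetric in its arguments and
#' deterministic given `seed`.
#'
#' @param e1,e2 [niche_region()] ellipses.
#' @param n_mc number of Monte-Carlo points (default 100000).
#' @param seed integer seed.
#' @return named numeric vector: `area`, `mc_se`.
#' @export
ellipse_intersection_area <- function(e1, e2, n_mc = 1e5, seed = NULL) {
  stopifnot(inherits(e1, "niche_ellipse"), inherits(e2, "niche_ellipse"))
  if (e2$area < e1$area) { tmp <- e1; e1 <- e2; e2 <- tmp }
  with_seed(seed, {
    # uniform points in e1: uniform on the unit disk, then affine map
    r <- sqrt(stats::runif(n_mc))
    th <- stats::runif(n_mc, 0, 2 * pi)
    L <- t(chol(e1$sigma))
    pts <- t(e1$center + sqrt(e1$q) * L %*% rbind(r * cos(th), r * sin(th)))
    f <- mean(in_ellipse(pts, e2))
    c(area = e1$area * f,
      mc_se = e1$area * sqrt(f * (1 - f) / n_mc))
  })
}
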