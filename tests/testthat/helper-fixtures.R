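# Shared fixtures, built in code.

# Point cloud whose *sample* covariance equals `sigma` exactly (whiten the
# centred draws, then recolour), so ellipse-area identities hold to
# machine precision.
exact_cov_cloud <- function(n, sigma, mean = c(0, 0), seed = 42) {
  stopifnot(n >= 3)
  x <- vertiso:::with_seed(seed, matrix(rnorm(2 * n), n, 2))
  x <- scale(x, center = TRUE, scale = FALSE)
  x <- x %*% solve(chol(cov(x))) %*% chol(sigma)
  sweep(x, 2, mean, "+")
}

# Minimal hand-built band table: one individual, explicit bands/deltas.
tiny_band_table <- function(id = "A", sex = "male", age = 5,
                            bands = 1:5,
                            d13C = seq(-15, -14, length.out = length(bands)),
                            d15N = rep(12, length(bands)),
                            cn = rep(3.1, length(bands)), ...) {
  band_table(individual_id = id, sex = sex, total_length_cm = 180,
             age = age, maturity = "immature", band_index = bands,
             d13C = d13C, d15N = d15N, cn_ratio = cn, ...)
}
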