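# independent univariate oracle: e^{-B} = integral sqrt(p_a p_b) by quadrature
bhatt_quadrature <- function(mu_a, sd_a, mu_b, sd_b) {
  pooled <- sqrt((sd_a^2 + sd_b^2) / 2)
  lo <- min(mu_a, mu_b) - 10 * pooled
  hi <- max(mu_a, mu_b) + 10 * pooled
  f <- function(x) sqrt(dnorm(x, mu_a, sd_a) * dnorm(x, mu_b, sd_b))
  -log(integrate(f, lo, hi, rel.tol = 1e-10, abs.tol = 0,
                 subdivisions = 2000L)$value)
}

test_that("M-statistic: forced arithmetic, symmetry, domain errors", {
  expect_equal(m_statistic(gsum(0.6, 0.1^2), gsum(0.2, 0.1^2)), 2.0)
  expect_equal(m_statistic(gsum(0.4, 0.05^2), gsum(0.4, 0.2^2)), 0)  # equal means
  a <- gsum(0.3, 0.02^2); b <- gsum(0.5, 0.07^2)
  expect_equal(m_statistic(a, b), m_statistic(b, a))
  expect_gt(m_statistic(a, b), 0)
  expect_error(m_statistic(gsum(0, 0), gsum(0, 0)), "zero")
  expect_error(m_statistic(gsum(c(0, 0), diag(2)), gsum(c(1, 1), diag(2))),
               "d = 1")
})

test_that("Bhattacharyya: closed form, zero at identity, quadrature oracle", {
  expect_equal(bhattacharyya(gsum(0, 1), gsum(2, 1)), 0.5)
  expect_equal(bhattacharyya(gsum(0.4, 0.01), gsum(0.4, 0.01)), 0)
  set.seed(2718)
  for (i in 1:100) {
    mu <- runif(2, 0, 1); sd <- runif(2, 0.01, 0.3)
    B <- bhattacharyya(gsum(mu[1], sd[1]^2), gsum(mu[2], sd[2]^2))
    expect_equal(B, bhatt_quadrature(mu[1], sd[1], mu[2], sd[2]),
                 tolerance = 1e-6)
    expect_gte(B, 0)
  }
})

test_that("Bhattacharyya agrees with a Monte-Carlo importance estimate", {
  # e^{-B} = E_{x ~ p_a}[ sqrt(p_b(x) / p_a(x)) ]
  set.seed(161803)
  mu_a <- 0.30; sd_a <- 0.05; mu_b <- 0.38; sd_b <- 0.08
  n <- 1e6
  x <- rnorm(n, mu_a, sd_a)
  w <- sqrt(dnorm(x, mu_b, sd_b) / dnorm(x, mu_a, sd_a))
  est <- mean(w); se <- sd(w) / sqrt(n)
  B_mc <- -log(est)
  se_B <- se / est  # delta method
  B <- bhattacharyya(gsum(mu_a, sd_a^2), gsum(mu_b, sd_b^2))
  expect_lt(abs(B - B_mc), 3 * se_B)
})

test_that("Bhattacharyya is additive over independent dimensions", {
  set.seed(99)
  for (i in 1:20) {
    mu <- matrix(runif(4), 2); v <- matrix(runif(4, 0.01, 0.1), 2)
    B2 <- bhattacharyya(gsum(mu[, 1], diag(v[, 1])), gsum(mu[, 2], diag(v[, 2])))
    B_each <- bhattacharyya(gsum(mu[1, 1], v[1, 1]), gsum(mu[1, 2], v[1, 2])) +
      bhattacharyya(gsum(mu[2, 1], v[2, 1]), gsum(mu[2, 2], v[2, 2]))
    expect_equal(B2, B_each, tolerance = 1e-12)
  }
})

test_that("Jeffries-Matusita transform and both conventions", {
  expect_equal(jeffries_matusita(0), 0)
  expect_equal(round(jeffries_matusita(0.81), 2), 1.11)
  expect_equal(jeffries_matusita(50), 2, tolerance = 1e-15)
  expect_equal(jeffries_matusita(0.81, sqrt_convention = TRUE),
               sqrt(2 * (1 - exp(-0.81))))
  expect_error(jeffries_matusita(-0.1), "nonnegative")
  # strictly increasing in B, bounded by 2 (sqrt(2) under the flag)
  B <- seq(0, 20, by = 0.25)
  jm <- jeffries_matusita(B)
  expect_true(all(diff(jm) > 0))
  expect_true(all(jm <= 2))
  expect_true(all(jeffries_matusita(B, TRUE) <= sqrt(2)))
})

test_that("divergence: closed form, symmetry, additivity, TD transform", {
  expect_equal(divergence(gsum(0, 1), gsum(2, 1)), 4)
  expect_equal(divergence(gsum(0.2, 0.04), gsum(0.2, 0.04)), 0)
  a <- gsum(0.3, 0.03^2); b <- gsum(0.44, 0.09^2)
  expect_equal(divergence(a, b), divergence(b, a))
  set.seed(55)
  for (i in 1:20) {
    mu <- matrix(runif(4), 2); v <- matrix(runif(4, 0.01, 0.1), 2)
    D2 <- divergence(gsum(mu[, 1], diag(v[, 1])), gsum(mu[, 2], diag(v[, 2])))
    D_each <- divergence(gsum(mu[1, 1], v[1, 1]), gsum(mu[1, 2], v[1, 2])) +
      divergence(gsum(mu[2, 1], v[2, 1]), gsum(mu[2, 2], v[2, 2]))
    expect_equal(D2, D_each, tolerance = 1e-10)
  }
  expect_equal(transformed_divergence(gsum(0, 1), gsum(2, 1)),
               2 * (1 - exp(-0.5)))  # D = 4 -> ~0.7869
  expect_equal(transformed_divergence(a, a), 0)
  expect_lte(transformed_divergence(gsum(0, 1e-4), gsum(1, 1e-4)), 2)
})

test_that("all four metrics are scale-equivariant", {
  set.seed(8)
  for (i in 1:25) {
    mu <- runif(2); sd <- runif(2, 0.01, 0.2); k <- runif(1, 0.1, 50)
    a <- gsum(mu[1], sd[1]^2); b <- gsum(mu[2], sd[2]^2)
    ak <- gsum(k * mu[1], (k * sd[1])^2); bk <- gsum(k * mu[2], (k * sd[2])^2)
    expect_equal(m_statistic(ak, bk), m_statistic(a, b))
    expect_equal(bhattacharyya(ak, bk), bhattacharyya(a, b), tolerance = 1e-9)
    expect_equal(divergence(ak, bk), divergence(a, b), tolerance = 1e-9)
    expect_equal(transformed_divergence(ak, bk), transformed_divergence(a, b),
                 tolerance = 1e-9)
  }
})

test_that("degenerate variances are floored, not fatal", {
  a <- gsum(0.2, 0); b <- gsum(0.4, 0)
  expect_true(is.finite(bhattacharyya(a, b)))
  expect_true(is.finite(divergence(a, b)))
  expect_equal(bhattacharyya(a, a), 0)
  u <- separability_univariate(0.2, 0, 0.4, 0)
  expect_true(all(is.finite(unlist(u))))
})

test_that("normalize_metric maps every criterion onto [0, 1]", {
  expect_equal(normalize_metric(2, "TD"), 1)
  expect_equal(normalize_metric(0, "B"), 0)
  expect_equal(normalize_metric(1, "M"), 0.5)
  expect_equal(normalize_metric(2, "JM"), 1)
  expect_equal(normalize_metric(sqrt(2), "JM", jm_sqrt = TRUE), 1)
  # strictly increasing, 0 at 0, limit 1
  for (m in c("M", "B", "JM", "TD")) {
    v <- if (m %in% c("JM", "TD")) seq(0, 2, by = 0.1) else seq(0, 30, by = 0.5)
    nv <- normalize_metric(v, m)
    expect_equal(nv[1], 0)
    expect_true(all(diff(nv) > 0))
    expect_true(all(nv <= 1))
  }
  expect_error(normalize_metric(-1, "B"), "nonnegative")
})

test_that("separability_univariate matches the scalar operations band-wise", {
  set.seed(12)
  mu_a <- runif(6); mu_b <- runif(6)
  sd_a <- runif(6, 0.01, 0.1); sd_b <- runif(6, 0.01, 0.1)
  u <- separability_univariate(mu_a, sd_a^2, mu_b, sd_b^2)
  for (k in 1:6) {
    a <- gsum(mu_a[k], sd_a[k]^2); b <- gsum(mu_b[k], sd_b[k]^2)
    expect_equal(u$M[k], m_statistic(a, b))
    expect_equal(u$B[k], bhattacharyya(a, b), tolerance = 1e-12)
    expect_equal(u$JM[k], jeffries_matusita(bhattacharyya(a, b)),
                 tolerance = 1e-12)
    expect_equal(u$D[k], divergence(a, b), tolerance = 1e-12)
    expect_equal(u$TD[k], transformed_divergence(a, b), tolerance = 1e-12)
  }
})

test_that("gaussian_class_summary validates covariances", {
  expect_error(gaussian_class_summary(c(0, 1), matrix(c(1, 2, 0, 1), 2)),
               "symmetric")
  expect_error(gaussian_class_summary(c(0, 1), matrix(c(1, 2, 2, 1), 2)),
               "semidefinite")
  expect_error(gaussian_class_summary(c(0, 1), 1), "dimension")
  expect_error(bhattacharyya(gsum(0, 1), gsum(c(0, 1), diag(2))), "dimension")
})
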