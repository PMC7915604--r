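## Gaussian class-separability criteria.
##
## All four criteria assume Gaussian class-conditional reflectance and are
## symmetric in the two classes. The band-by-band pipeline uses them with
## d = 1 (per-band mean and variance); the multivariate forms are provided
## for completeness and cross-checking.
##
## Note on formulations: the source field literature sometimes prints the
## Bhattacharyya distance and the symmetric divergence with sign typos
## (pooled covariance written as a difference, mismatched inverse sums) that
## make them zero or negative for identical classes. The standard textbook
## forms are implemented here:
##   B = 1/8 (mu_a-mu_b)' S^-1 (mu_a-mu_b) + 1/2 ln( |S| / sqrt(|Sa||Sb|) ),
##       S = (Sa + Sb)/2
##   D = 1/2 tr[(Ca-Cb)(Cb^-1 - Ca^-1)]
##     + 1/2 tr[(Ca^-1 + Cb^-1)(mu_a-mu_b)(mu_a-mu_b)']
## both of which are 0 iff the two Gaussians coincide.

#' Gaussian summary of a class
#'
#' @param mu Mean vector (length d >= 1).
#' @param cov Covariance: a positive scalar variance for d = 1, or a
#'   symmetric positive-semidefinite `d x d` matrix.
#' @return A `gaussian_class_summary`.
#' @export
gaussian_class_summary <- function(mu, cov) {
  mu <- as.numeric(mu)
  d <- length(mu)
  if (d == 1L && length(cov) == 1L) cov <- matrix(as.numeric(cov), 1, 1)
  cov <- as.matrix(cov)
  if (!all(dim(cov) == d)) stop("dimension mismatch between mu and cov")
  if (max(abs(cov - t(cov))) > 1e-8 * max(1, max(abs(cov)))) {
    stop("covariance must be symmetric")
  }
  if (min(eigen(cov, symmetric = TRUE, only.values = TRUE)$values) < -1e-8) {
    stop("covariance must be positive semidefinite")
  }
  structure(list(mu = mu, cov = cov), class = "gaussian_class_summary")
}

# floor near-singular covariances with a ridge so constant synthetic classes
# do not crash band loops; the floor is part of the documented contract
regularize_cov <- function(cov, eps = 1e-10) {
  if (any(diag(cov) < 1e-12) || rcond_safe(cov) < 1e-12) {
    cov <- cov + diag(eps, nrow(cov))
  }
  cov
}

rcond_safe <- function(m) {
  if (nrow(m) == 1L) return(if (m[1, 1] == 0) 0 else 1)
  tryCatch(rcond(m), error = function(e) 0)
}

check_pair <- function(a, b) {
  stopifnot(inherits(a, "gaussian_class_summary"),
            inherits(b, "gaussian_class_summary"))
  if (length(a$mu) != length(b$mu)) stop("dimension mismatch between classes")
}

#' M-statistic (normalized mean separation), univariate only
#'
#' `M = |mu_a - mu_b| / (sigma_a + sigma_b)`: the distance between the two
#' distributional peaks in units of their summed spreads. Zero when the means
#' coincide regardless of the variances, which is its known blind spot.
#'
#' @param a,b Univariate [gaussian_class_summary()] objects.
#' @return Nonnegative scalar.
#' @export
m_statistic <- function(a, b) {
  check_pair(a, b)
  if (length(a$mu) != 1L) stop("the M-statistic is defined for d = 1 only")
  sa <- sqrt(a$cov[1, 1]); sb <- sqrt(b$cov[1, 1])
  if (sa + sb <= 0) stop("both standard deviations are zero")
  abs(a$mu - b$mu) / (sa + sb)
}

#' Bhattacharyya distance between two Gaussian classes
#'
#' Mean term plus covariance term; accounts for separability carried by
#' covariance differences even at equal means. Near-singular covariances are
#' floored by a ridge `eps * I`.
#'
#' @param a,b [gaussian_class_summary()] objects of equal dimension.
#' @param eps Ridge used when a covariance is near-singular.
#' @return Nonnegative scalar `B`.
#' @export
bhattacharyya <- function(a, b, eps = 1e-10) {
  check_pair(a, b)
  Sa <- regularize_cov(a$cov, eps); Sb <- regularize_cov(b$cov, eps)
  S <- (Sa + Sb) / 2
  dm <- a$mu - b$mu
  sol <- tryCatch(solve(S, dm), error = function(e)
    stop("pooled covariance is singular beyond regularization"))
  term_mean <- as.numeric(crossprod(dm, sol)) / 8
  ld <- function(m) determinant(m, logarithm = TRUE)$modulus
  term_cov <- 0.5 * as.numeric(ld(S) - 0.5 * (ld(Sa) + ld(Sb)))
  term_mean + term_cov
}

#' Jeffries-Matusita distance from a Bhattacharyya distance
#'
#' Default convention: `JM = 2 (1 - exp(-B))`, bounded by 2, the form used in
#' the published separability tables this package reproduces. The alternative
#' square-root convention `sqrt(2 (1 - exp(-B)))`, asymptotic to `sqrt(2)`,
#' is available via `sqrt_convention = TRUE`.
#'
#' @param B Nonnegative Bhattacharyya distance(s).
#' @param sqrt_convention Use the `sqrt(2)`-bounded convention.
#' @return JM distance(s), same length as `B`.
#' @export
jeffries_matusita <- function(B, sqrt_convention = FALSE) {
  if (any(B < -1e-12)) stop("B must be nonnegative")
  jm <- 2 * (1 - exp(-pmax(B, 0)))
  if (sqrt_convention) sqrt(jm) else jm
}

#' Symmetric divergence between two Gaussian classes
#'
#' The covariance-weighted distance between the class means plus the
#' covariance-shape term; symmetric and zero iff the classes coincide.
#'
#' @inheritParams bhattacharyya
#' @return Nonnegative scalar `D`.
#' @export
divergence <- function(a, b, eps = 1e-10) {
  check_pair(a, b)
  Ca <- regularize_cov(a$cov, eps); Cb <- regularize_cov(b$cov, eps)
  Cai <- tryCatch(solve(Ca), error = function(e) stop("singular covariance"))
  Cbi <- tryCatch(solve(Cb), error = function(e) stop("singular covariance"))
  dm <- a$mu - b$mu
  term_cov <- 0.5 * sum(diag((Ca - Cb) %*% (Cbi - Cai)))
  term_mean <- 0.5 * as.numeric(crossprod(dm, (Cai + Cbi) %*% dm))
  term_cov + term_mean
}

#' Transformed divergence
#'
#' `TD = 2 (1 - exp(-D / 8))` with `D` the symmetric [divergence()]; bounded
#' in `[0, 2]`, reaching 2 only in the infinite-divergence limit.
#'
#' @inheritParams bhattacharyya
#' @return Scalar in `[0, 2]`.
#' @export
transformed_divergence <- function(a, b, eps = 1e-10) {
  2 * (1 - exp(-divergence(a, b, eps = eps) / 8))
}

#' Map a separability value onto [0, 1]
#'
#' The four criteria live on different scales (JM and TD bounded by 2, B and
#' M unbounded), so averaging them requires a common one. Each map is 0 at 0,
#' strictly increasing, with limit 1:
#' `JM/2` (or `JM^2/2` under the square-root convention), `TD/2`,
#' `1 - exp(-B)`, `M/(1+M)`.
#'
#' @param value Nonnegative metric value(s).
#' @param metric One of `"M"`, `"B"`, `"JM"`, `"TD"`.
#' @param jm_sqrt Whether JM values were computed under the square-root
#'   convention.
#' @return Normalized value(s) in `[0, 1]`.
#' @export
normalize_metric <- function(value, metric, jm_sqrt = FALSE) {
  if (any(value < -1e-12, na.rm = TRUE)) stop("metric values must be nonnegative")
  value <- pmax(value, 0)
  switch(match.arg(metric, c("M", "B", "JM", "TD")),
         M = value / (1 + value),
         B = 1 - exp(-value),
         JM = if (jm_sqrt) value^2 / 2 else value / 2,
         TD = value / 2)
}

#' All four separability criteria for one univariate class pair
#'
#' Convenience wrapper evaluating M, B, JM and TD for per-band (d = 1)
#' summaries, vectorized over bands.
#'
#' @param mu_a,mu_b Per-band means.
#' @param var_a,var_b Per-band variances (floored at `eps` when below 1e-12).
#' @param jm_sqrt JM convention flag, see [jeffries_matusita()].
#' @param eps Variance floor.
#' @return `data.frame(M, B, JM, TD, D)` with one row per band.
#' @export
separability_univariate <- function(mu_a, var_a, mu_b, var_b,
                                    jm_sqrt = FALSE, eps = 1e-10) {
  stopifnot(length(mu_a) == length(mu_b), length(var_a) == length(var_b),
            length(mu_a) == length(var_a))
  var_a <- ifelse(var_a < 1e-12, var_a + eps, var_a)
  var_b <- ifelse(var_b < 1e-12, var_b + eps, var_b)
  dm <- mu_a - mu_b
  s <- (var_a + var_b) / 2
  M <- abs(dm) / (sqrt(var_a) + sqrt(var_b))
  B <- dm^2 / (8 * s) + 0.5 * log(s / sqrt(var_a * var_b))
  D <- 0.5 * (var_a - var_b) * (1 / var_b - 1 / var_a) +
    0.5 * (1 / var_a + 1 / var_b) * dm^2
  data.frame(M = M, B = B, JM = jeffries_matusita(B, jm_sqrt),
             TD = 2 * (1 - exp(-D / 8)), D = D)
}
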