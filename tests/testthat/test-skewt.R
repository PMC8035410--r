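test_that("standardization is exact, reversible, and rejects constants", {
  df <- tibble::tibble(a = rnorm(50, 5, 3), b = runif(50))
  st <- standardize(df)
  expect_equal(vapply(st, mean, numeric(1)), c(a = 0, b = 0), tolerance = 1e-12)
  expect_equal(vapply(st, sd, numeric(1)), c(a = 1, b = 1), tolerance = 1e-12)
  back <- unstandardize(st)
  expect_equal(back$a, df$a, tolerance = 1e-12)
  df$c <- 7
  expect_error(standardize(df), "zero-variance.*c")
})

test_that("skew-t density integrates to 1 and matches Monte Carlo probabilities", {
  mu <- 1; S <- matrix(2); dl <- 1.5; nu <- 5
  f <- function(x) exp(vapply(x, function(xi)
    dmst(matrix(xi, 1, 1), mu, S, dl, nu), numeric(1)))
  expect_equal(integrate(f, -50, 50, rel.tol = 1e-9)$value, 1,
               tolerance = 1e-5)
  set.seed(3)
  X <- rmst(2e5, mu, S, dl, nu)
  for (q in c(-1, 1, 3)) {
    pn <- integrate(f, -50, q)$value
    expect_lt(abs(mean(X < q) - pn), 4 * sqrt(pn * (1 - pn) / 2e5) + 1e-4)
  }
})

test_that("density at the location with zero skew equals the elliptical-t value", {
  # at x = mu, delta = 0: f = 2 * t_d(center) * T(0) = t_d(center);
  # for large nu this approaches the Gaussian (2*pi)^(-d/2) |Sigma|^(-1/2)
  S <- diag(c(2, 3))
  val <- dmst(matrix(c(1, -1), 1, 2), c(1, -1), S, c(0, 0), 1e4)
  expect_equal(exp(val), (2 * pi)^(-1) * det(S)^(-0.5), tolerance = 1e-3)
})

test_that("E-step posterior moments match a Monte Carlo oracle", {
  mu <- 1; S <- matrix(2); dl <- 1.5; nu <- 5; y0 <- 2.5
  set.seed(11)
  n <- 2e6
  w <- rgamma(n, nu / 2, nu / 2)
  gam <- abs(rnorm(n)) / sqrt(w)
  lik <- dnorm(y0, mu + dl * gam, sqrt(2 / w))
  mc <- c(sum(w * lik), sum(w * gam * lik), sum(w * gam^2 * lik)) / sum(lik)
  g <- synaptoscope:::mst_geometry(matrix(y0, 1, 1), mu, S, dl)
  mom <- synaptoscope:::mst_moments(g, nu, 1, synaptoscope:::mst_quad(nu, 1))
  expect_equal(mom$e1, mc[1], tolerance = 5e-3)
  expect_equal(mom$e2, mc[2], tolerance = 5e-3)
  expect_equal(mom$e3, mc[3], tolerance = 5e-3)
})

test_that("with zero skew and large fixed nu the fit reduces to Gaussian MLE", {
  set.seed(4)
  X <- cbind(rnorm(400, 3, 2), rnorm(400, -1, 1))
  fit <- fit_skewt_mixture(X, 1, fix_delta = TRUE, fix_nu = 1e6, n_start = 1)
  cp <- fit$components[[1]]
  n <- nrow(X); d <- ncol(X)
  expect_equal(cp$mu, colMeans(X), tolerance = 1e-6, ignore_attr = TRUE)
  S_mle <- cov(X) * (n - 1) / n
  ll_gauss <- -n / 2 * (d * log(2 * pi) + log(det(S_mle)) + d)
  expect_equal(fit$loglik, ll_gauss, tolerance = 1e-6 * abs(ll_gauss))
  # recovered mean within 3 standard errors, variances within sampling error
  expect_lt(max(abs(cp$mu - c(3, -1)) / c(2 / sqrt(n), 1 / sqrt(n))), 3)
})

test_that("EM log-likelihood is monotone and labels recover the fixture", {
  fx <- skewt_fixture(600, seed = 1)
  fit <- fit_skewt_mixture(fx$X, 3, seed = 1, n_start = 3)
  expect_true(all(diff(fit$loglik_trace) > -1e-8 * abs(fit$loglik)))
  skip_if_not_installed("mclust")
  ari <- mclust::adjustedRandIndex(fit$labels, fx$labels)
  expect_gte(ari, 0.9)
  # responsibilities are row-stochastic
  expect_equal(rowSums(fit$responsibilities), rep(1, 600), tolerance = 1e-9)
})

test_that("relabelling components leaves likelihood and BIC unchanged", {
  fx <- skewt_fixture(300, seed = 2)
  fit <- fit_skewt_mixture(fx$X, 2, seed = 1, n_start = 2, max_iter = 60)
  perm <- fit
  perm$components <- rev(fit$components)
  ll <- function(f) {
    logd <- vapply(f$components, function(cp)
      dmst(fx$X, cp$mu, cp$Sigma, cp$delta, cp$nu), numeric(nrow(fx$X)))
    lw <- sweep(logd, 2, log(vapply(f$components, `[[`, numeric(1), "pi")), `+`)
    mx <- apply(lw, 1, max)
    sum(mx + log(rowSums(exp(lw - mx))))
  }
  expect_equal(ll(perm), ll(fit), tolerance = 1e-10)
})

test_that("BIC arithmetic and parameter count are as documented", {
  # logL = -100, p = 5, n = 100 -> BIC = 200 + 5 ln(100)
  expect_equal(-2 * -100 + 5 * log(100), 223.0259, tolerance = 1e-4)
  fx <- skewt_fixture(200, seed = 3)
  fit <- fit_skewt_mixture(fx$X, 2, seed = 1, n_start = 1, max_iter = 30)
  d <- 2; G <- 2
  p <- (G - 1) + G * (2 * d + d * (d + 1) / 2 + 1)
  expect_equal(fit$n_params, p)
  expect_equal(fit$bic, -2 * fit$loglik + p * log(200))
})

test_that("BIC selects one component for a single Gaussian cloud", {
  set.seed(6)
  X <- matrix(rnorm(400), ncol = 2)
  sel <- select_components(X, G_range = 1:3, seed = 2, n_start = 2,
                           max_iter = 120)
  expect_equal(sel$best$G, 1)
})

test_that("cluster condition summaries expose proportions and medians", {
  labels <- c(1, 1, 1, 2, 2, 2)
  cond <- c("a", "a", "b", "b", "b", "b")
  extras <- data.frame(amplitude = c(-50, -60, -55, -80, -90, -100))
  cs <- cluster_condition_summary(labels, cond, extras)
  p1 <- cs$proportions[cs$proportions$cluster == 1, ]
  expect_equal(p1$proportion[p1$condition == "a"], 2 / 3)
  expect_equal(sum(cs$proportions$n), 6)
  med <- cs$summaries
  expect_equal(med$median_amplitude[med$cluster == 2 & med$condition == "b"],
               -90)
  # single-condition data: proportions are 1 everywhere
  cs2 <- cluster_condition_summary(labels, rep("a", 6))
  expect_true(all(cs2$proportions$proportion == 1))
})
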