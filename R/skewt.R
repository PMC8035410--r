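#' Standardize feature columns
#'
#' Centres and scales every numeric column to zero mean and unit SD,
#' storing the parameters as attributes so the transform can be inverted.
#'
#' @param features Data frame of event features.
#' @param cols Columns to standardize; defaults to all numeric columns.
#' @return The standardized tibble with attributes `center` and `scale`.
#' @export
standardize <- function(features, cols = NULL) {
  if (is.null(cols))
    cols <- names(features)[vapply(features, is.numeric, logical(1))]
  if (nrow(features) < 2) abort("need at least 2 rows to standardize.")
  ctr <- vapply(features[cols], mean, numeric(1))
  scl <- vapply(features[cols], sd, numeric(1))
  bad <- cols[!is.finite(scl) | scl == 0]
  if (length(bad))
    abort(sprintf("zero-variance column(s): %s.", paste(bad, collapse = ", ")))
  out <- features
  for (cl in cols) out[[cl]] <- (out[[cl]] - ctr[[cl]]) / scl[[cl]]
  attr(out, "center") <- ctr
  attr(out, "scale") <- scl
  tibble::as_tibble(out)
}

#' @rdname standardize
#' @param standardized A tibble produced by `standardize()`.
#' @export
unstandardize <- function(standardized) {
  ctr <- attr(standardized, "center"); scl <- attr(standardized, "scale")
  if (is.null(ctr)) abort("no standardization attributes found.")
  out <- standardized
  for (cl in names(ctr)) out[[cl]] <- out[[cl]] * scl[[cl]] + ctr[[cl]]
  attr(out, "center") <- NULL; attr(out, "scale") <- NULL
  out
}

# ---- restricted multivariate skew-t distribution --------------------------
# Hierarchy: w ~ Gamma(nu/2, nu/2); gamma | w ~ half-N(0, 1/w);
# y | gamma, w ~ N(mu + delta*gamma, Sigma/w).  Marginally
# f(y) = 2 t_d(y; mu, Omega, nu) T_1(q(y); nu + d)  with Omega = Sigma +
# delta delta', q(y) = (m_y/s_g) sqrt((nu+d)/(nu+d_Om)),
# m_y = delta' Omega^-1 (y-mu), s_g^2 = 1 - delta' Omega^-1 delta.

# per-component geometry shared by density and E-step
mst_geometry <- function(X, mu, Sigma, delta) {
  Omega <- Sigma + tcrossprod(delta)
  R <- tryCatch(chol(Omega), error = function(e) NULL)
  if (is.null(R)) {
    Omega <- Omega + diag(1e-8 * mean(diag(Omega)), nrow(Omega))
    R <- chol(Omega)
  }
  ctr <- sweep(X, 2, mu)
  Z <- backsolve(R, t(ctr), transpose = TRUE)   # d x n
  d_om <- colSums(Z^2)
  oid <- backsolve(R, backsolve(R, delta, transpose = TRUE))
  m_y <- drop(ctr %*% oid)
  s2 <- max(1 - sum(delta * oid), 1e-12)
  list(d_om = d_om, m_y = m_y, s_g = sqrt(s2), s2 = s2,
       logdet = 2 * sum(log(diag(R))))
}

#' Restricted multivariate skew-t log-density
#'
#' @param X Numeric matrix (rows = observations) or vector.
#' @param mu Location vector.
#' @param Sigma Scale matrix (positive-definite).
#' @param delta Skew direction vector.
#' @param nu Degrees of freedom (> 2 for finite covariance).
#' @return Log-density vector.
#' @export
dmst <- function(X, mu, Sigma, delta, nu) {
  X <- as.matrix(X)
  d <- ncol(X)
  g <- mst_geometry(X, mu, Sigma, delta)
  logt <- lgamma((nu + d) / 2) - lgamma(nu / 2) - (d / 2) * log(pi * nu) -
    g$logdet / 2 - ((nu + d) / 2) * log1p(g$d_om / nu)
  q <- (g$m_y / g$s_g) * sqrt((nu + d) / (nu + g$d_om))
  log(2) + logt + pt(q, df = nu + d, log.p = TRUE)
}

#' Sample from the restricted multivariate skew-t
#'
#' Draws through the hierarchical representation (gamma-mixed scale,
#' half-normal skewing variable), which is also the independent route the
#' tests use to validate the density and the EM posterior moments.
#'
#' @inheritParams dmst
#' @param n Number of draws.
#' @return An n x d matrix.
#' @export
rmst <- function(n, mu, Sigma, delta, nu) {
  d <- length(mu)
  w <- rgamma(n, nu / 2, nu / 2)
  gam <- abs(rnorm(n)) / sqrt(w)
  Zm <- matrix(rnorm(n * d), n, d) %*% chol(Sigma) / sqrt(w)
  sweep(Zm + gam %o% delta, 2, mu, `+`)
}

# E-step posterior moments e1 = E[w|y], e2 = E[w gamma|y], e3 =
# E[w gamma^2|y] by generalized Gauss-Laguerre quadrature over the latent
# gamma weight (substitution u = w (nu + d_Om)/2; the Phi skew factor is
# the only non-gamma term).
mst_moments <- function(g, nu, d, quad) {
  if (nu > 5000) {
    # near-Gaussian limit: w | y is sharply concentrated at its mode
    wh <- (nu + d) / (nu + g$d_om)
    a <- sqrt(wh) * (g$m_y / g$s_g)
    lam <- exp(dnorm(a, log = TRUE) - pnorm(a, log.p = TRUE))
    gE <- sqrt(wh) * lam
    return(list(e1 = wh,
                e2 = g$m_y * wh + g$s_g * gE,
                e3 = g$m_y^2 * wh + g$s2 + g$m_y * g$s_g * gE))
  }
  wq <- 2 * outer(1 / (nu + g$d_om), quad$x)       # n x K latent w at nodes
  alpha <- sqrt(wq) * (g$m_y / g$s_g)
  Phi <- pnorm(alpha); phi <- dnorm(alpha)
  wts <- rep(1, length(g$d_om)) %o% quad$w
  Zn <- rowSums(wts * Phi)
  e1 <- rowSums(wts * wq * Phi) / Zn
  gE <- rowSums(wts * sqrt(wq) * phi) / Zn         # E[sqrt(w) phi/Phi-term]
  e2 <- g$m_y * e1 + g$s_g * gE
  e3 <- g$m_y^2 * e1 + g$s2 + g$m_y * g$s_g * gE
  list(e1 = e1, e2 = e2, e3 = e3)
}

mst_quad <- function(nu, d, n_nodes = 32) {
  if (nu > 5000) return(NULL)          # moments use the Gaussian limit
  q <- pracma::gaussLaguerre(n_nodes, (nu + d) / 2 - 1)
  list(x = q$x, w = q$w)
}

#' Fit a mixture of restricted multivariate skew-t distributions
#'
#' EM estimation of a G-component mixture in which each component has a
#' location vector, a positive-definite scale matrix, a single skew
#' direction vector and its own degrees of freedom.  The E-step posterior
#' moments of the latent scale/skew variables are computed by
#' Gauss-Laguerre quadrature; location, skew and scale updates are in
#' closed form; the degrees of freedom are updated by direct maximization
#' of the observed log-likelihood (box-constrained to [2.5, 200]).
#' Initialization is k-means on the (ideally standardized) features with
#' zero initial skew; `n_start` short runs are launched and the best
#' continued to convergence.  The log-likelihood is non-decreasing across
#' iterations.
#'
#' @param X Numeric matrix or data frame of features (rows = events).
#' @param G Number of components.
#' @param seed Integer seed controlling initialization.
#' @param max_iter Maximum EM iterations (default 500).
#' @param tol Relative log-likelihood change declaring convergence
#'   (default 1e-6).
#' @param n_start Number of k-means initializations (default 5).
#' @param fix_delta Keep all skew vectors at zero (reduces the family to
#'   multivariate t).
#' @param fix_nu Fix all degrees of freedom at this value instead of
#'   estimating them.
#' @return An object of class `mixture_fit`: `components` (list of
#'   `pi`, `mu`, `Sigma`, `delta`, `nu`), `responsibilities`, `labels`,
#'   `loglik`, `bic`, `loglik_trace`, `converged`, `n_iter`, `G`, `d`,
#'   `n`.
#' @export
fit_skewt_mixture <- function(X, G, seed = 1, max_iter = 500, tol = 1e-6,
                              n_start = 5, fix_delta = FALSE, fix_nu = NULL) {
  X <- as.matrix(X)
  if (!all(is.finite(X))) abort("X must be finite; drop incomplete rows first.")
  n <- nrow(X); d <- ncol(X)
  if (n <= G * (d + 1))
    abort("too few rows for this many components.")
  set.seed(seed)
  starts <- lapply(seq_len(max(1, n_start)), function(s) {
    km <- suppressWarnings(kmeans(X, centers = G, nstart = 1, iter.max = 30))
    init_components(X, km$cluster, G, fix_nu)
  })
  short <- lapply(starts, function(cp)
    em_skewt(X, cp, max_iter = min(25, max_iter), tol = tol,
             fix_delta = fix_delta, fix_nu = fix_nu))
  best <- short[[which.max(vapply(short, function(f) f$loglik, numeric(1)))]]
  fit <- em_skewt(X, best$components, max_iter = max_iter, tol = tol,
                  fix_delta = fix_delta, fix_nu = fix_nu,
                  loglik_trace = best$loglik_trace)
  p <- (G - 1) + G * (2 * d + d * (d + 1) / 2 + 1)
  fit$bic <- -2 * fit$loglik + p * log(n)
  fit$n_params <- p
  fit$G <- G; fit$d <- d; fit$n <- n
  class(fit) <- "mixture_fit"
  fit
}

init_components <- function(X, cluster, G, fix_nu) {
  d <- ncol(X)
  lapply(seq_len(G), function(g) {
    rows <- X[cluster == g, , drop = FALSE]
    if (nrow(rows) < 2) rows <- X
    S <- cov(rows)
    S <- S + diag(max(1e-6, 1e-3 * mean(diag(S))), d)
    list(pi = max(mean(cluster == g), 1e-3), mu = colMeans(rows), Sigma = S,
         delta = numeric(d), nu = fix_nu %||% 40)
  })
}

em_skewt <- function(X, comps, max_iter, tol, fix_delta, fix_nu,
                     loglik_trace = numeric(), nu_every = 5L) {
  n <- nrow(X); d <- ncol(X); G <- length(comps)
  ll_old <- -Inf
  converged <- FALSE
  ridged <- FALSE
  for (iter in seq_len(max_iter)) {
    geo <- lapply(comps, function(cp)
      mst_geometry(X, cp$mu, cp$Sigma, cp$delta))
    logd <- vapply(seq_len(G), function(g)
      dmst_from_geometry(geo[[g]], comps[[g]]$nu, d), numeric(n))
    logw <- sweep(logd, 2, log(vapply(comps, `[[`, numeric(1), "pi")), `+`)
    mx <- apply(logw, 1, max)
    lse <- mx + log(rowSums(exp(logw - mx)))
    ll <- sum(lse)
    loglik_trace <- c(loglik_trace, ll)
    if (is.finite(ll_old) && abs(ll - ll_old) <= tol * abs(ll_old)) {
      converged <- TRUE
      z <- exp(logw - lse)
      break
    }
    ll_old <- ll
    z <- exp(logw - lse)

    for (g in seq_len(G)) {
      cp <- comps[[g]]
      quad <- mst_quad(cp$nu, d)
      mom <- mst_moments(geo[[g]], cp$nu, d, quad)
      zg <- z[, g]
      sz <- sum(zg)
      comps[[g]]$pi <- sz / n
      ze1 <- zg * mom$e1; ze2 <- zg * mom$e2; ze3 <- zg * mom$e3
      mu <- colSums(ze1 * X - ze2 %o% cp$delta) / sum(ze1)
      r <- sweep(X, 2, mu)
      delta <- if (fix_delta) numeric(d) else colSums(ze2 * r) / sum(ze3)
      S <- (crossprod(r, ze1 * r) -
              tcrossprod(colSums(ze2 * r), delta) -
              tcrossprod(delta, colSums(ze2 * r)) +
              sum(ze3) * tcrossprod(delta)) / sz
      S <- (S + t(S)) / 2
      ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
      if (min(ev) < 1e-8 * max(ev)) {
        ridged <- TRUE
        S <- S + diag(1e-6 * mean(diag(S)), d)
      }
      comps[[g]]$mu <- mu; comps[[g]]$delta <- delta; comps[[g]]$Sigma <- S
    }
    if (is.null(fix_nu) && iter %% nu_every == 0L)
      comps <- update_nu(X, comps, d)
  }
  if (!exists("z", inherits = FALSE)) z <- matrix(1 / G, n, G)
  if (ridged)
    warn("near-singular scale matrix ridge-regularized during EM (correlated features).")
  list(components = comps, responsibilities = z,
       labels = max.col(z),
       loglik = loglik_trace[length(loglik_trace)],
       loglik_trace = loglik_trace,
       converged = converged, n_iter = length(loglik_trace))
}

dmst_from_geometry <- function(g, nu, d) {
  logt <- lgamma((nu + d) / 2) - lgamma(nu / 2) - (d / 2) * log(pi * nu) -
    g$logdet / 2 - ((nu + d) / 2) * log1p(g$d_om / nu)
  q <- (g$m_y / g$s_g) * sqrt((nu + d) / (nu + g$d_om))
  log(2) + logt + pt(q, df = nu + d, log.p = TRUE)
}

# ECME step: each component's degrees of freedom maximizes the observed
# mixture log-likelihood with everything else held fixed
update_nu <- function(X, comps, d) {
  n <- nrow(X); G <- length(comps)
  logd <- vapply(comps, function(cp)
    dmst(X, cp$mu, cp$Sigma, cp$delta, cp$nu), numeric(n))
  lpi <- log(vapply(comps, `[[`, numeric(1), "pi"))
  for (g in seq_len(G)) {
    cp <- comps[[g]]
    obj <- function(lnu) {
      cand <- logd
      cand[, g] <- dmst(X, cp$mu, cp$Sigma, cp$delta, exp(lnu))
      lw <- sweep(cand, 2, lpi, `+`)
      mx <- apply(lw, 1, max)
      sum(mx + log(rowSums(exp(lw - mx))))
    }
    opt <- optimize(obj, c(log(2.5), log(200)), maximum = TRUE, tol = 0.02)
    if (opt$objective > obj(log(cp$nu))) {
      comps[[g]]$nu <- exp(opt$maximum)
      logd[, g] <- dmst(X, cp$mu, cp$Sigma, cp$delta, comps[[g]]$nu)
    }
  }
  comps
}

#' Select the number of mixture components by BIC
#'
#' Fits the skew-t mixture for every component count in `G_range` (with
#' multi-start per count) and returns the fit minimizing the Bayesian
#' information criterion, `BIC = -2 logL + p log(n)` with `p = (G-1) +
#' G(2d + d(d+1)/2 + 1)` free parameters, together with the full BIC
#' table.
#'
#' @inheritParams fit_skewt_mixture
#' @param G_range Component counts to try.
#' @return A list: `best` (`mixture_fit`), `bic_table` (tibble `G`,
#'   `loglik`, `bic`, `converged`).
#' @export
select_components <- function(X, G_range = 1:6, seed = 1, n_start = 3,
                              max_iter = 300, tol = 1e-6) {
  fits <- lapply(G_range, function(G) {
    tryCatch(
      fit_skewt_mixture(X, G, seed = seed + G, n_start = n_start,
                        max_iter = max_iter, tol = tol),
      error = function(e) NULL)
  })
  ok <- !vapply(fits, is.null, logical(1))
  if (!any(ok)) abort("all mixture fits failed.")
  tab <- tibble::tibble(
    G = G_range[ok],
    loglik = vapply(fits[ok], function(f) f$loglik, numeric(1)),
    bic = vapply(fits[ok], function(f) f$bic, numeric(1)),
    converged = vapply(fits[ok], function(f) f$converged, logical(1))
  )
  list(best = fits[ok][[which.min(tab$bic)]], bic_table = tab)
}

#' Per-cluster condition summary
#'
#' Cross-tabulates cluster assignments against experimental condition:
#' event counts and within-cluster condition proportions, plus per
#' cluster-by-condition medians of any additional columns supplied (for
#' example amplitude, rise time, instantaneous frequency) — amplitude may
#' be re-attached here for reporting even though it is never used in the
#' fit.
#'
#' @param labels Cluster labels (integer vector).
#' @param conditions Condition labels, same length.
#' @param extras Optional data frame of per-event quantities to summarise.
#' @return A list of tibbles: `proportions` (cluster x condition counts
#'   and proportions) and, if `extras` given, `summaries` (medians per
#'   cluster and condition).
#' @export
cluster_condition_summary <- function(labels, conditions, extras = NULL) {
  df <- tibble::tibble(cluster = labels, condition = conditions)
  props <- df |>
    dplyr::count(.data$cluster, .data$condition, .drop = FALSE) |>
    dplyr::group_by(.data$cluster) |>
    dplyr::mutate(proportion = .data$n / sum(.data$n)) |>
    dplyr::ungroup()
  out <- list(proportions = props)
  if (!is.null(extras)) {
    out$summaries <- dplyr::bind_cols(df, tibble::as_tibble(extras)) |>
      dplyr::group_by(.data$cluster, .data$condition) |>
      dplyr::summarise(dplyr::across(dplyr::where(is.numeric),
                                     ~ median(.x, na.rm = TRUE),
                                     .names = "median_{.col}"),
                       n = dplyr::n(), .groups = "drop")
  }
  out
}
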