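#' Tidy a multi-exponential decay fit
#'
#' @param x An `exp_fit`.
#' @param ... Unused.
#' @return One row per component: `component`, `a`, `tau_ms`.
#' @method tidy exp_fit
#' @export
tidy.exp_fit <- function(x, ...) {
  dplyr::mutate(x$components, component = dplyr::row_number(), .before = 1)
}

#' @rdname tidy.exp_fit
#' @return `glance()`: one row with `n_components`, `tau_w_ms`, `offset`,
#'   `sse`.
#' @method glance exp_fit
#' @export
glance.exp_fit <- function(x, ...) {
  tibble::tibble(n_components = x$n_components,
                 tau_w_ms = weighted_tau(x),
                 offset = x$offset, sse = x$sse)
}

#' @export
print.exp_fit <- function(x, ...) {
  cat(sprintf("%d-component exponential decay fit (T_w = %.3g ms, SSE = %.3g)\n",
              x$n_components, weighted_tau(x), x$sse))
  print(x$components)
  invisible(x)
}

#' Tidy a fluctuation-analysis result
#'
#' @param x An `nsfa_result`.
#' @param ... Unused.
#' @return One row per parameter: `term`, `estimate`.
#' @method tidy nsfa_result
#' @export
tidy.nsfa_result <- function(x, ...) {
  tibble::tibble(term = c("i", "n_channels", "var_baseline"),
                 estimate = c(x$i, x$n_channels, x$var_baseline))
}

#' @rdname tidy.nsfa_result
#' @return `glance()`: one row of fit diagnostics.
#' @method glance nsfa_result
#' @export
glance.nsfa_result <- function(x, ...) {
  tibble::tibble(r_squared = x$r_squared, n_pairs = x$n_pairs,
                 n_bins = x$n_bins,
                 n_events = x$n_events %||% NA_integer_)
}

#' @export
print.nsfa_result <- function(x, ...) {
  cat(sprintf("peak-scaled NSFA: i = %.3g pA, N = %.3g, baseline var = %.3g pA^2 (R^2 = %.3f)\n",
              x$i, x$n_channels, x$var_baseline, x$r_squared))
  invisible(x)
}

#' Tidy a skew-t mixture fit
#'
#' @param x A `mixture_fit`.
#' @param ... Unused.
#' @return One row per component: `component`, `weight`, `nu`, and the
#'   location coordinates `mu_1`, ..., `mu_d`.
#' @method tidy mixture_fit
#' @export
tidy.mixture_fit <- function(x, ...) {
  purrr::map_dfr(seq_along(x$components), function(g) {
    cp <- x$components[[g]]
    row <- tibble::tibble(component = g, weight = cp$pi, nu = cp$nu)
    for (j in seq_along(cp$mu)) row[[paste0("mu_", j)]] <- cp$mu[j]
    row
  })
}

#' @rdname tidy.mixture_fit
#' @return `glance()`: one row with `G`, `loglik`, `bic`, `n_iter`,
#'   `converged`.
#' @method glance mixture_fit
#' @export
glance.mixture_fit <- function(x, ...) {
  tibble::tibble(G = x$G, loglik = x$loglik, bic = x$bic,
                 n_params = x$n_params, n = x$n,
                 n_iter = x$n_iter, converged = x$converged)
}

#' @export
print.mixture_fit <- function(x, ...) {
  cat(sprintf("restricted skew-t mixture: G = %d, logL = %.2f, BIC = %.2f (%s)\n",
              x$G, x$loglik, x$bic,
              if (x$converged) "converged" else "max iterations"))
  invisible(x)
}

#' Tidy a paired-pulse recovery curve
#'
#' @param x A `recovery_curve`.
#' @param ... Unused.
#' @return The per-interval curve tibble.
#' @method tidy recovery_curve
#' @export
tidy.recovery_curve <- function(x, ...) x$curve

#' @rdname tidy.recovery_curve
#' @return `glance()`: one row with the fitted suppression depth `d` and
#'   recovery time constant `tau_rec_s`.
#' @method glance recovery_curve
#' @export
glance.recovery_curve <- function(x, ...) {
  tibble::tibble(d = x$d, tau_rec_s = x$tau_rec_s,
                 n_intervals = nrow(x$curve))
}

#' @export
print.recovery_curve <- function(x, ...) {
  cat(sprintf("paired-pulse recovery over %d intervals", nrow(x$curve)))
  if (is.finite(x$d))
    cat(sprintf(": 1 - %.3g * exp(-dt / %.3g s)", x$d, x$tau_rec_s))
  cat("\n")
  print(x$curve)
  invisible(x)
}
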