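#' Deviance Information Criterion
#'
#' DIC = mean posterior deviance + p_D, with effective parameters
#' p_D = mean deviance - deviance at the posterior mean predictor.
#'
#' @param deviance_draws per-draw deviances (-2 log-likelihood), >= 100.
#' @param deviance_at_mean deviance evaluated at the posterior mean of eta.
#' @return list: `dic`, `p_d`, `mean_deviance`.
#' @export
compute_dic <- function(deviance_draws, deviance_at_mean) {
  if (length(deviance_draws) < 100L) stop("need at least 100 draws")
  if (any(!is.finite(deviance_draws)) || !is.finite(deviance_at_mean)) {
    stop("non-finite deviance")
  }
  dbar <- mean(deviance_draws)
  p_d <- dbar - deviance_at_mean
  list(dic = dbar + p_d, p_d = p_d, mean_deviance = dbar)
}

# numerically safe log(mean(exp(x)))
.log_mean_exp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(mean(exp(x - m)))
}

#' Watanabe-Akaike Information Criterion
#'
#' From the per-row per-draw log-likelihood matrix:
#' lppd = sum_r log mean_m exp(L[m, r]),
#' p_WAIC = sum_r var_m(L[m, r]), WAIC = -2 (lppd - p_WAIC).
#' Log-sum-exp is used throughout.
#'
#' @param loglik matrix, draws in rows, observations in columns.
#' @return list: `waic`, `p_waic`, `lppd`, `flagged_rows` (columns with zero
#'   variance across a very large draw set — suspicious degeneracy).
#' @export
compute_waic <- function(loglik) {
  loglik <- as.matrix(loglik)
  lppd_r <- apply(loglik, 2L, .log_mean_exp)
  p_r <- if (nrow(loglik) > 1L) apply(loglik, 2L, stats::var) else
    numeric(ncol(loglik))
  flagged <- if (nrow(loglik) > 1e4) which(p_r == 0) else integer(0)
  lppd <- sum(lppd_r); p_waic <- sum(p_r)
  list(waic = -2 * (lppd - p_waic), p_waic = p_waic, lppd = lppd,
       lppd_rows = lppd_r, flagged_rows = flagged)
}

#' Conditional predictive ordinates
#'
#' CPO for each observation is estimated by the harmonic-mean identity from
#' posterior draws: CPO_r = 1 / mean_m(1 / L[m, r]). A row is a CPO failure
#' when the estimator is numerically unstable: a single draw carries more
#' than 95 percent of the harmonic-mean weight, or the estimate is
#' non-finite (e.g., a zero-likelihood draw). Failures are counted, not
#' dropped. LCPO is reported both as the sum and the mean of log CPO.
#'
#' @param loglik matrix of per-draw per-row log-likelihoods.
#' @param weight_threshold failure threshold on the maximum weight share.
#' @return list: `cpo` (per row), `log_cpo`, `lcpo` (sum), `lcpo_mean`,
#'   `failures` (row indices), `n_failures`.
#' @export
compute_cpo <- function(loglik, weight_threshold = 0.95) {
  loglik <- as.matrix(loglik)
  M <- nrow(loglik)
  log_cpo <- numeric(ncol(loglik))
  maxw <- numeric(ncol(loglik))
  for (r in seq_len(ncol(loglik))) {
    nl <- -loglik[, r]                     # log inverse likelihoods
    m <- max(nl)
    if (!is.finite(m)) { log_cpo[r] <- NA_real_; maxw[r] <- 1; next }
    w <- exp(nl - m)
    log_cpo[r] <- -(m + log(sum(w)) - log(M))
    maxw[r] <- max(w) / sum(w)
  }
  failures <- which(!is.finite(log_cpo) | maxw > weight_threshold)
  list(cpo = exp(log_cpo), log_cpo = log_cpo,
       lcpo = sum(log_cpo[is.finite(log_cpo)]),
       lcpo_mean = mean(log_cpo[is.finite(log_cpo)]),
       failures = failures, n_failures = length(failures))
}

#' Probability integral transform for counts
#'
#' Discrete mid-PIT of each observation under its posterior predictive
#' distribution, estimated over draws of the Poisson mean:
#' PIT_r = P(Y_rep < y_r) + 0.5 P(Y_rep = y_r). Under a calibrated model the
#' PIT sample is approximately uniform on [0, 1].
#'
#' @param y observed counts.
#' @param mu_draws matrix of posterior-draw Poisson means (draws x rows).
#' @return numeric vector of PIT values in [0, 1].
#' @export
compute_pit <- function(y, mu_draws) {
  mu_draws <- as.matrix(mu_draws)
  if (nrow(mu_draws) < 1L || ncol(mu_draws) != length(y)) {
    stop("mu_draws must be a non-empty draws x length(y) matrix")
  }
  vapply(seq_along(y), function(r) {
    mu <- mu_draws[, r]
    p_lt <- if (y[r] > 0) mean(stats::ppois(y[r] - 1, mu)) else 0
    p_lt + 0.5 * mean(stats::dpois(y[r], mu))
  }, numeric(1))
}

#' Observed-versus-fitted table
#'
#' Posterior mean fitted count E theta and a central 95 percent posterior
#' predictive interval per observation (mixture-Poisson quantiles over the
#' draws), with the empirical interval coverage.
#'
#' @param y observed counts.
#' @param mu_draws matrix of posterior-draw Poisson means (draws x rows).
#' @param level interval level, default 0.95.
#' @return list: `table` (data.frame y, fitted, lo, hi), `coverage`.
#' @export
observed_vs_fitted <- function(y, mu_draws, level = 0.95) {
  mu_draws <- as.matrix(mu_draws)
  a <- (1 - level) / 2
  mix_q <- function(mu, p) {
    # smallest k with mean ppois(k, mu) >= p
    lo <- 0L; hi <- max(stats::qpois(p, max(mu)), 1L) * 2L + 10L
    while (mean(stats::ppois(hi, mu)) < p) hi <- hi * 2L
    while (lo < hi) {
      mid <- (lo + hi) %/% 2L
      if (mean(stats::ppois(mid, mu)) >= p) hi <- mid else lo <- mid + 1L
    }
    lo
  }
  n <- length(y)
  fitted <- colMeans(mu_draws)
  lo <- hi <- integer(n)
  for (r in seq_len(n)) {
    lo[r] <- mix_q(mu_draws[, r], a)
    hi[r] <- mix_q(mu_draws[, r], 1 - a)
  }
  tab <- data.frame(y = y, fitted = fitted, lo = lo, hi = hi)
  list(table = tab, coverage = mean(y >= lo & y <= hi))
}

#' Full Bayesian adequacy report for a fitted model
#'
#' Computes DIC, WAIC, CPO/LCPO with failure detection, PIT values and the
#' observed-vs-fitted comparison from a fitted posterior, reusing the stored
#' per-row log-likelihood matrix.
#'
#' @param posterior a `posterior_result`.
#' @return a `diagnostics_report` list.
#' @export
model_diagnostics <- function(posterior) {
  stopifnot(inherits(posterior, "posterior_result"))
  y <- posterior$model$y; E <- posterior$model$E
  L <- posterior$loglik
  dev_draws <- -2 * rowSums(L)
  eta_bar <- colMeans(posterior$eta)
  dev_at_mean <- -2 * poisson_loglik(y, E, eta_bar)$total
  dic <- compute_dic(dev_draws, dev_at_mean)
  waic <- compute_waic(L)
  cpo <- compute_cpo(L)
  mu_draws <- sweep(exp(posterior$eta), 2L, E, `*`)
  pit <- compute_pit(y, mu_draws)
  ovf <- observed_vs_fitted(y, mu_draws)
  structure(list(dic = dic$dic, p_d = dic$p_d,
                 waic = waic$waic, p_waic = waic$p_waic, lppd = waic$lppd,
                 lcpo = cpo$lcpo, lcpo_mean = cpo$lcpo_mean,
                 cpo = cpo$cpo, cpo_failures = cpo$n_failures,
                 pit = pit, observed_vs_fitted = ovf$table,
                 predictive_coverage = ovf$coverage),
            class = "diagnostics_report")
}

#' @export
print.diagnostics_report <- function(x, ...) {
  cat("Model adequacy diagnostics\n")
  cat(sprintf("  DIC  %10.2f  (p_D %.1f)\n", x$dic, x$p_d))
  cat(sprintf("  WAIC %10.2f  (p_WAIC %.1f, lppd %.1f)\n",
              x$waic, x$p_waic, x$lppd))
  cat(sprintf("  LCPO %10.2f  (mean %.4f), CPO failures: %d\n",
              x$lcpo, x$lcpo_mean, x$cpo_failures))
  cat(sprintf("  95%% predictive coverage: %.3f\n", x$predictive_coverage))
  invisible(x)
}
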