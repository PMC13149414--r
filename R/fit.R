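#' Assemble a shared-component model from a panel and a graph
#'
#' Binds a validated mortality panel to an adjacency graph and a latent
#' specification, standardizes the covariates (recording the moments), and
#' precomputes the design and prior structures the inference engine uses.
#'
#' @param panel a `mortality_panel` (see [validate_panel()]).
#' @param graph a `country_graph` whose nodes are the panel's countries.
#' @param priors hyperprior settings, see [default_hyperpriors()].
#' @param standardize logical; z-score the covariates (default TRUE).
#' @return a `shared_model` list: `spec`, `panel`, `y`, `E`, `X`,
#'   standardization `record`, design `B`, layout, prior diagonal.
#' @export
build_model <- function(panel, graph, priors = default_hyperpriors(),
                        standardize = TRUE) {
  stopifnot(inherits(panel, "mortality_panel"), inherits(graph, "country_graph"))
  if (!setequal(attr(panel, "countries"), graph$nodes)) {
    stop("panel countries and graph nodes differ")
  }
  record <- NULL
  if (standardize) {
    sc <- standardize_covariates(panel)
    panel <- sc$panel; record <- sc$record
  }
  covs <- attr(panel, "covariates")
  spec <- build_latent_spec(graph, attr(panel, "years"),
                            attr(panel, "diseases"), covs, priors)
  # panel rows are already canonical (disease, country, year, all sorted)
  X <- as.matrix(as.data.frame(panel)[, covs, drop = FALSE])
  p <- ncol(X)
  layout <- .spec_layout(spec, p)
  ix <- panel_index_map(spec)
  n <- spec$n
  Mi <- matrix(0, n, spec$I); Mi[cbind(seq_len(n), ix$i)] <- 1
  Mt <- matrix(0, n, spec$T); Mt[cbind(seq_len(n), ix$t)] <- 1
  Md <- matrix(0, n, spec$D); Md[cbind(seq_len(n), ix$d)] <- 1
  Vs <- spec$icar$vectors; Vt <- spec$rw1$vectors
  Bs <- Mi %*% Vs                       # country basis, n x rank(icar)
  Bt <- Mt %*% Vt                       # year basis, n x rank(rw1)
  per_disease <- function(Bbase) {
    out <- matrix(0, n, ncol(Bbase) * spec$D)
    for (d in seq_len(spec$D)) {
      rows <- ix$d == d
      out[rows, (d - 1L) * ncol(Bbase) + seq_len(ncol(Bbase))] <- Bbase[rows, ]
    }
    out
  }
  B <- cbind(X, 1, Md, Bs, Bs, per_disease(Bs), per_disease(Bs), Bt,
             per_disease(Bt))
  stopifnot(ncol(B) == layout$m)
  structure(list(spec = spec, panel = panel, record = record,
                 y = panel$deaths, E = panel$expected_deaths, X = X,
                 B = B, layout = layout, ix = ix),
            class = "shared_model")
}

#' @export
print.shared_model <- function(x, ...) {
  cat(sprintf("shared_model: %d rows, %d structured coordinates + %d interaction\n",
              x$spec$n, x$layout$m, x$spec$n))
  print(x$spec)
  invisible(x)
}

#' Laplace approximation of the latent field given hyperparameters
#'
#' Runs the constrained Newton optimization of [poisson_laplace()] on the
#' model's spectral coordinates at a fixed hyperparameter setting.
#'
#' @param hyper named hyperparameters (see [hyper_names()]).
#' @param model a `shared_model`.
#' @param start optional warm start (a previous fit's `z`/`psi`).
#' @param ... passed to [poisson_laplace()].
#' @return a `poisson_laplace` fit.
#' @export
laplace_latent <- function(hyper, model, start = NULL, ...) {
  stopifnot(inherits(model, "shared_model"))
  cf <- .spec_coefs(model$spec, model$layout, hyper)
  n <- model$spec$n
  A <- model$B * rep(cf, each = n)
  h <- .check_hyper(hyper)
  poisson_laplace(model$y, model$E, A, model$layout$q0,
                  c_psi = 1 / sqrt(h[["tau_psi"]]), start = start, ...)
}

#' Natural-scale latent state from spectral coordinates
#'
#' Maps inference coordinates (z, psi) at a hyperparameter setting back to
#' the model's natural parameters: beta, global level mu, disease intercepts
#' alpha, BYM2 effects lambda and u (with structured/unstructured halves),
#' temporal effects phi and v, and the interaction psi.
#'
#' @param model a `shared_model`.
#' @param hyper named hyperparameters.
#' @param z,psi coordinate vectors as returned by [laplace_latent()] /
#'   [draw_laplace()].
#' @return list of natural-scale components.
#' @export
latent_state_from_coords <- function(model, hyper, z, psi) {
  spec <- model$spec; idx <- model$layout$idx
  h <- .check_hyper(hyper)
  Vs <- spec$icar$vectors; Vt <- spec$rw1$vectors
  D <- spec$D
  lambda_struct <- drop(Vs %*% z[idx$s_lambda])
  lambda_iid <- drop(Vs %*% z[idx$w_lambda])
  rs <- spec$icar$rank; rt <- spec$rw1$rank
  u_struct <- u_iid <- matrix(0, spec$I, D)
  v <- matrix(0, spec$T, D)
  for (d in seq_len(D)) {
    u_struct[, d] <- drop(Vs %*% z[idx$s_u][(d - 1L) * rs + seq_len(rs)])
    u_iid[, d] <- drop(Vs %*% z[idx$w_u][(d - 1L) * rs + seq_len(rs)])
    v[, d] <- drop(Vt %*% z[idx$s_v][(d - 1L) * rt + seq_len(rt)]) /
      sqrt(h[["tau_v"]])
  }
  u <- matrix(0, spec$I, D)
  for (d in seq_len(D)) {
    u[, d] <- bym2_combine(h[["rho_u"]], h[["tau_u"]], u_struct[, d], u_iid[, d])
  }
  list(beta = z[idx$beta], mu = z[idx$mu],
       alpha = z[idx$a_alpha] / sqrt(h[["tau_alpha"]]),
       lambda = bym2_combine(h[["rho_lambda"]], h[["tau_lambda"]],
                             lambda_struct, lambda_iid),
       lambda_struct = lambda_struct, lambda_iid = lambda_iid,
       u = u, u_struct = u_struct, u_iid = u_iid,
       phi = drop(Vt %*% z[idx$s_phi]) / sqrt(h[["tau_phi"]]),
       v = v, psi = psi / sqrt(h[["tau_psi"]]))
}

#' Latent-field objective and analytic gradient at fixed hyperparameters
#'
#' The log posterior (up to hyperprior terms, which are constant in the
#' latent field) as a function of the inference coordinates (z, psi), with
#' its analytic gradient: the quantity the Newton-Laplace optimizer ascends.
#'
#' @param model a `shared_model`.
#' @param hyper named hyperparameters.
#' @param z structured coordinates (length `model$layout$m`).
#' @param psi standardized interaction coordinates (length n).
#' @return list: `value`, `grad_z`, `grad_psi`.
#' @export
latent_objective <- function(model, hyper, z, psi) {
  cf <- .spec_coefs(model$spec, model$layout, hyper)
  n <- model$spec$n
  A <- model$B * rep(cf, each = n)
  h <- .check_hyper(hyper)
  c_psi <- 1 / sqrt(h[["tau_psi"]])
  q0 <- model$layout$q0
  eta <- drop(A %*% z) + c_psi * psi
  ll <- poisson_loglik(model$y, model$E, eta)
  list(value = ll$total - 0.5 * sum(q0 * z^2) - 0.5 * sum(psi^2),
       grad_z = drop(crossprod(A, ll$grad_eta)) - q0 * z,
       grad_psi = c_psi * ll$grad_eta - psi)
}

#' MCMC control settings
#'
#' @param n_iter total Metropolis iterations over the hyperparameters.
#' @param burnin iterations discarded (adaptation is frozen afterwards).
#' @param thin keep every `thin`-th post-burn-in iteration.
#' @param seed mandatory RNG seed.
#' @param target_accept adaptive-scaling target acceptance rate.
#' @return list of settings.
#' @export
fit_control <- function(n_iter = 3000L, burnin = 1000L, thin = 2L,
                        seed = NULL, target_accept = 0.35) {
  if (is.null(seed)) stop("a seed is mandatory for reproducible inference")
  if (burnin >= n_iter) stop("burnin must be smaller than n_iter")
  list(n_iter = as.integer(n_iter), burnin = as.integer(burnin),
       thin = as.integer(thin), seed = as.integer(seed),
       target_accept = target_accept)
}

# Transform between natural hyperparameters and the unconstrained MCMC scale
.hyper_to_theta <- function(h) c(log(h[1:6]), stats::qlogis(h[7:8]))
.theta_to_hyper <- function(th) {
  h <- c(exp(th[1:6]), stats::plogis(th[7:8]))
  names(h) <- hyper_names()
  h
}
# log |d hyper / d theta|: tau = e^theta and rho = logistic(theta)
.theta_log_jacobian <- function(th) {
  sum(th[1:6]) + sum(stats::plogis(th[7:8], log.p = TRUE) +
                       stats::plogis(-th[7:8], log.p = TRUE))
}

.hyper_log_prior <- function(h, spec, rho_rates) {
  pr <- spec$priors
  taus <- c("tau_lambda", "tau_u", "tau_phi", "tau_v", "tau_psi", "tau_alpha")
  lp <- 0
  for (nm in taus) {
    lp <- lp + pc_prior_precision_logpdf(h[[nm]], pr[[nm]]$U, pr[[nm]]$alpha)
  }
  # mixing PC prior with pre-solved rate (same scaled ICAR for both)
  for (nm in c("rho_lambda", "rho_u")) {
    dist <- .bym2_distance(h[[nm]], spec$icar)
    d1 <- .bym2_distance(1 - 1e-12, spec$icar)$d
    lam <- rho_rates[[nm]]
    lp <- lp + log(lam) - lam * dist$d + log(abs(dist$d_prime)) -
      log1p(-exp(-lam * d1))
  }
  lp
}

#' Posterior sampling of the hyperparameters (Metropolis within Laplace)
#'
#' Adaptive random-walk Metropolis on the transformed hyperparameters
#' (log precisions, logit mixings) targeting the Laplace-marginalized
#' posterior pi(hyper | y) proportional to Laplace evidence x PC hyperpriors.
#' Proposal covariance and scale adapt during burn-in (frozen afterwards);
#' at every retained iteration one latent draw is taken from the conditional
#' Gaussian approximation at the current hyperparameters, giving joint
#' posterior draws of all model components.
#'
#' @param model a `shared_model`.
#' @param control a [fit_control()] list (seed mandatory).
#' @param hyper_init optional named initial hyperparameters.
#' @param fix character vector of hyperparameter names to hold at their
#'   initial values (not sampled); with all eight fixed the latent field is
#'   still drawn from its conditional Gaussian at that setting.
#' @return a `posterior_result`: natural-scale draw matrices for `hyper`,
#'   `beta`, `mu`, `alpha`, `lambda`, `u`, `phi`, `v`, `psi`, `eta`, per-row
#'   log-likelihood matrix `loglik`, and sampler metadata.
#' @export
sample_hyperparameters <- function(model, control, hyper_init = NULL,
                                   fix = character(0)) {
  stopifnot(inherits(model, "shared_model"))
  spec <- model$spec
  set.seed(control$seed)
  pr <- spec$priors
  rho_rates <- list(
    rho_lambda = .pc_mixing_lambda(spec$icar, pr$rho_lambda$U, pr$rho_lambda$alpha),
    rho_u = .pc_mixing_lambda(spec$icar, pr$rho_u$U, pr$rho_u$alpha))

  if (is.null(hyper_init)) {
    # PC prior median of sigma for each precision; mixing at 1/2
    med_tau <- vapply(
      c("tau_lambda", "tau_u", "tau_phi", "tau_v", "tau_psi", "tau_alpha"),
      function(nm) {
        lam <- -log(pr[[nm]]$alpha) / pr[[nm]]$U
        (lam / log(2))^2
      }, numeric(1))
    hyper_init <- c(med_tau, rho_lambda = 0.5, rho_u = 0.5)
    names(hyper_init) <- hyper_names()
  }
  th <- .hyper_to_theta(.check_hyper(hyper_init))
  k <- length(th)
  bad_fix <- setdiff(fix, hyper_names())
  if (length(bad_fix)) stop("unknown hyperparameter(s) in fix: ",
                            paste(bad_fix, collapse = ", "))
  fixed_idx <- match(fix, hyper_names())

  log_target <- function(th, start) {
    h <- .theta_to_hyper(th)
    fit <- tryCatch(laplace_latent(h, model, start = start),
                    error = function(e) NULL)
    if (is.null(fit)) return(list(lp = -Inf, fit = NULL))
    lp <- fit$log_evidence + .hyper_log_prior(h, spec, rho_rates) +
      .theta_log_jacobian(th)
    list(lp = lp, fit = fit)
  }
  cur <- log_target(th, NULL)
  if (!is.finite(cur$lp)) stop("initial hyperparameters have zero posterior density")

  n_iter <- control$n_iter; burnin <- control$burnin; thin <- control$thin
  keep_at <- seq.int(burnin + thin, n_iter, by = thin)
  n_keep <- length(keep_at)
  if (n_keep < 1L) stop("no retained draws; increase n_iter")

  p <- length(model$layout$idx$beta); D <- spec$D; I <- spec$I; Tn <- spec$T
  n <- spec$n
  out <- list(
    hyper = matrix(NA_real_, n_keep, k, dimnames = list(NULL, hyper_names())),
    beta = matrix(NA_real_, n_keep, p,
                  dimnames = list(NULL, spec$covariates)),
    mu = numeric(n_keep),
    alpha = matrix(NA_real_, n_keep, D, dimnames = list(NULL, spec$diseases)),
    lambda = matrix(NA_real_, n_keep, I, dimnames = list(NULL, spec$countries)),
    u = matrix(NA_real_, n_keep, I * D),
    phi = matrix(NA_real_, n_keep, Tn, dimnames = list(NULL, spec$years)),
    v = matrix(NA_real_, n_keep, Tn * D),
    psi = matrix(NA_real_, n_keep, n),
    eta = matrix(NA_real_, n_keep, n),
    loglik = matrix(NA_real_, n_keep, n),
    log_evidence = numeric(n_keep))
  colnames(out$u) <- paste(rep(spec$countries, times = D),
                           rep(spec$diseases, each = I), sep = ":")
  colnames(out$v) <- paste(rep(spec$years, times = D),
                           rep(spec$diseases, each = Tn), sep = ":")

  log_s <- log(0.3 / sqrt(k))
  Cchol <- diag(k)
  hist_th <- matrix(NA_real_, burnin, k)
  acc_post <- 0L; n_post <- 0L
  ki <- 0L
  for (it in seq_len(n_iter)) {
    prop <- th + exp(log_s) * drop(Cchol %*% stats::rnorm(k))
    if (length(fixed_idx)) prop[fixed_idx] <- th[fixed_idx]
    cand <- log_target(prop, start = list(z = cur$fit$z, psi = cur$fit$psi))
    a <- if (is.finite(cand$lp)) min(1, exp(cand$lp - cur$lp)) else 0
    accepted <- stats::runif(1) < a
    if (accepted) {
      th <- prop; cur <- cand
    }
    if (it <= burnin) {
      hist_th[it, ] <- th
      log_s <- log_s + (a - control$target_accept) / it^0.6
      if (it >= 50L && it %% 50L == 0L) {
        Ce <- stats::cov(hist_th[seq_len(it), , drop = FALSE]) +
          1e-8 * diag(k)
        Cchol <- t(chol(Ce))
      }
    } else {
      n_post <- n_post + 1L
      acc_post <- acc_post + accepted
    }
    if (it > burnin && it %in% keep_at) {
      ki <- ki + 1L
      h <- .theta_to_hyper(th)
      dr <- draw_laplace(cur$fit, 1L)
      st <- latent_state_from_coords(model, h, drop(dr$z), drop(dr$psi))
      eta <- assemble_predictor(
        list(beta = st$beta, alpha = st$alpha, mu = st$mu),
        list(lambda = st$lambda, u = st$u, phi = st$phi, v = st$v,
             psi = st$psi), spec, X = model$X)
      ll <- poisson_loglik(model$y, model$E, eta)
      out$hyper[ki, ] <- h
      out$beta[ki, ] <- st$beta
      out$mu[ki] <- st$mu
      out$alpha[ki, ] <- st$alpha
      out$lambda[ki, ] <- st$lambda
      out$u[ki, ] <- as.vector(st$u)
      out$phi[ki, ] <- st$phi
      out$v[ki, ] <- as.vector(st$v)
      out$psi[ki, ] <- st$psi
      out$eta[ki, ] <- eta
      out$loglik[ki, ] <- ll$rows
      out$log_evidence[ki] <- cur$fit$log_evidence
    }
  }
  acc_rate <- if (n_post > 0L) acc_post / n_post else NA_real_
  if (length(fixed_idx) == k) acc_rate <- NA_real_  # degenerate fixed chain
  warn <- character(0)
  if (is.finite(acc_rate) && (acc_rate < 0.05 || acc_rate > 0.95)) {
    warn <- sprintf("post-adaptation acceptance rate %.2f outside [0.05, 0.95]",
                    acc_rate)
    warning(warn)
  }
  structure(c(out, list(
    model = model, control = control, accept_rate = acc_rate,
    seed = control$seed, n_draws = n_keep, warnings = warn)),
    class = "posterior_result")
}

#' @export
print.posterior_result <- function(x, ...) {
  cat(sprintf("posterior_result: %d retained draws (seed %d, acceptance %.2f)\n",
              x$n_draws, x$seed, x$accept_rate))
  cat("hyperparameter posterior means:\n")
  print(round(colMeans(x$hyper), 4))
  invisible(x)
}

#' Posterior summary table
#'
#' Mean, sd, 2.5/50/97.5 percent quantiles and mode (Gaussian-kernel density
#' argmax, Silverman bandwidth) for each column of a draw matrix.
#'
#' @param draws matrix (draws x parameters) or numeric vector; >= 100 draws.
#' @param names optional parameter names.
#' @return data.frame: parameter, mean, sd, q2.5, median, q97.5, mode.
#' @export
summarize_draws <- function(draws, names = NULL) {
  if (is.vector(draws)) draws <- matrix(draws, ncol = 1L)
  if (nrow(draws) < 100L) stop("need at least 100 draws per parameter")
  if (is.null(names)) {
    names <- colnames(draws)
    if (is.null(names)) names <- paste0("par", seq_len(ncol(draws)))
  }
  mode_est <- function(x) {
    if (stats::sd(x) == 0) return(x[1L])
    dd <- stats::density(x, bw = "nrd0")
    dd$x[which.max(dd$y)]
  }
  qs <- t(apply(draws, 2L, stats::quantile, probs = c(0.025, 0.5, 0.975)))
  data.frame(parameter = names,
             mean = colMeans(draws),
             sd = apply(draws, 2L, stats::sd),
             q2.5 = qs[, 1L], median = qs[, 2L], q97.5 = qs[, 3L],
             mode = apply(draws, 2L, mode_est),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Fixed-effect summary of a fitted model
#' @param posterior a `posterior_result`.
#' @return summary data.frame (one row per covariate), as [summarize_draws()].
#' @export
fixed_effect_summary <- function(posterior) {
  summarize_draws(posterior$beta)
}

#' Hyperparameter summary of a fitted model
#' @param posterior a `posterior_result`.
#' @return summary data.frame, as [summarize_draws()].
#' @export
hyper_summary <- function(posterior) {
  summarize_draws(posterior$hyper)
}
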