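#' Row index map of the canonical panel order
#'
#' Canonical order is disease-major, then country, then year. Returns the
#' per-row component indices used to broadcast latent vectors onto panel rows.
#' @param spec a `latent_spec`.
#' @return list of integer vectors: `i` (country), `t` (year), `d` (disease),
#'   `id` (country-within-disease cell), `td` (year-within-disease cell).
#' @export
panel_index_map <- function(spec) {
  I <- spec$I; D <- spec$D; Tn <- spec$T
  d <- rep(seq_len(D), each = I * Tn)
  i <- rep(rep(seq_len(I), each = Tn), times = D)
  t <- rep(seq_len(Tn), times = I * D)
  list(i = i, t = t, d = d, id = (d - 1L) * I + i, td = (d - 1L) * Tn + t)
}

#' Assemble the structured additive predictor
#'
#' The log relative risk for panel row (i, t, d) is
#' eta = alpha_d + x_it' beta + lambda_i + u_id + phi_t + v_td + psi_itd,
#' mapped by index with no aggregation. Any component may be omitted (NULL),
#' in which case it contributes zero.
#'
#' @param fixed list with `beta` (length p), `alpha` (length D) and optional
#'   global `mu` (scalar, default 0).
#' @param latent list with `lambda` (length I), `u` (I x D matrix), `phi`
#'   (length T), `v` (T x D matrix), `psi` (length I*T*D in canonical order).
#' @param spec a `latent_spec`.
#' @param X covariate matrix (rows in canonical panel order, p columns);
#'   NULL if `fixed$beta` is NULL.
#' @return numeric vector eta of length I*T*D.
#' @export
assemble_predictor <- function(fixed, latent, spec, X = NULL) {
  ix <- panel_index_map(spec)
  n <- spec$n
  eta <- rep(if (is.null(fixed$mu)) 0 else fixed$mu, n)
  if (!is.null(fixed$alpha)) {
    if (length(fixed$alpha) != spec$D) stop("alpha must have length D")
    eta <- eta + fixed$alpha[ix$d]
  }
  if (!is.null(fixed$beta)) {
    if (is.null(X)) stop("X required when beta is supplied")
    if (nrow(X) != n || ncol(X) != length(fixed$beta)) {
      stop("X must be n x length(beta)")
    }
    eta <- eta + drop(X %*% fixed$beta)
  }
  add <- function(eta, vec, idx, len, nm) {
    if (is.null(vec)) return(eta)
    vec <- as.numeric(vec)
    if (length(vec) != len) stop(nm, " has length ", length(vec), ", expected ", len)
    eta + vec[idx]
  }
  eta <- add(eta, latent$lambda, ix$i, spec$I, "lambda")
  eta <- add(eta, latent$u, ix$id, spec$I * spec$D, "u")
  eta <- add(eta, latent$phi, ix$t, spec$T, "phi")
  eta <- add(eta, latent$v, ix$td, spec$T * spec$D, "v")
  if (!is.null(latent$psi)) {
    psi <- as.numeric(latent$psi)
    if (length(psi) != n) stop("psi has length ", length(psi), ", expected ", n)
    eta <- eta + psi
  }
  eta
}

# Overflow guard: Poisson mean exp(eta) is only trusted on |eta| <= 35.
.eta_guard <- 35

#' Poisson log-likelihood of the count panel
#'
#' Y_itd ~ Poisson(E_itd exp(eta_itd)). Per-row contributions are
#' y (log E + eta) - E exp(eta) - log Gamma(y + 1); the row vector is
#' retained for the CPO/WAIC diagnostics. Predictors beyond the overflow
#' guard (|eta| > 35) yield a -Inf total rather than silent overflow.
#'
#' @param y non-negative integer counts.
#' @param E positive expected deaths.
#' @param eta finite log relative risks.
#' @return list: `total` (scalar), `rows` (per-row log-likelihood),
#'   `grad_eta` (d loglik / d eta = y - E exp(eta)).
#' @export
poisson_loglik <- function(y, E, eta) {
  if (any(E <= 0)) stop("E must be positive")
  if (any(!is.finite(eta)) || any(abs(eta) > .eta_guard)) {
    n <- length(y)
    return(list(total = -Inf, rows = rep(-Inf, n), grad_eta = rep(NA_real_, n)))
  }
  mu <- E * exp(eta)
  rows <- y * (log(E) + eta) - mu - lgamma(y + 1)
  list(total = sum(rows), rows = rows, grad_eta = y - mu)
}

# Gaussian log prior of intrinsic-structure coordinates. Projects the
# natural-scale vector onto the positive eigenbasis of the scaled structure;
# a residual beyond tolerance means a violated sum-to-zero constraint and is
# an error, not a silent projection.
.structure_logprior <- function(x, structure, tau = 1, name = "component",
                                tol = 1e-6) {
  coords <- drop(crossprod(structure$vectors, x))
  resid <- x - drop(structure$vectors %*% coords)
  if (max(abs(resid)) > tol * (1 + max(abs(x)))) {
    stop(name, " violates its sum-to-zero constraint (residual ",
         format(max(abs(resid))), ")")
  }
  prec <- structure$values * tau
  sum(0.5 * log(prec / (2 * pi)) - 0.5 * prec * coords^2)
}

# iid-but-constrained (sum-to-zero) standard normal half of a BYM2 effect:
# standard normal coordinates on the same constraint-orthogonal basis.
.constrained_iid_logprior <- function(x, structure, name, tol = 1e-6) {
  coords <- drop(crossprod(structure$vectors, x))
  resid <- x - drop(structure$vectors %*% coords)
  if (max(abs(resid)) > tol * (1 + max(abs(x)))) {
    stop(name, " violates its sum-to-zero constraint")
  }
  sum(stats::dnorm(coords, log = TRUE))
}

#' Joint log posterior of the shared-component model
#'
#' Poisson log likelihood plus the Gaussian log priors of every latent block
#' under its scaled, constrained precision, the fixed-effect Gaussian prior,
#' and the penalized-complexity hyperprior log densities. The additive
#' decomposition is returned per block.
#'
#' The BYM2 effects must be supplied through their internal halves
#' (`lambda_struct`/`lambda_iid`, `u_struct`/`u_iid`, unit-scale vectors);
#' the combined effects used in the predictor are
#' `bym2_combine(rho, tau, struct, iid)` per component.
#'
#' @param fixed list: `beta`, `alpha`, `mu`.
#' @param latent list: `lambda_struct`, `lambda_iid` (length I),
#'   `u_struct`, `u_iid` (I x D), `phi` (length T), `v` (T x D),
#'   `psi` (length n).
#' @param hyper named vector/list of the eight hyperparameters
#'   (see [hyper_names()]).
#' @param y,E counts and expected deaths in canonical order.
#' @param spec a `latent_spec`.
#' @param X covariate matrix in canonical order.
#' @return list: `total`, named `blocks` vector, and `eta`.
#' @export
log_posterior <- function(fixed, latent, hyper, y, E, spec, X = NULL) {
  h <- .check_hyper(hyper)
  D <- spec$D
  lambda <- bym2_combine(h["rho_lambda"], h["tau_lambda"],
                         latent$lambda_struct, latent$lambda_iid)
  u <- matrix(0, spec$I, D)
  for (d in seq_len(D)) {
    u[, d] <- bym2_combine(h["rho_u"], h["tau_u"],
                           latent$u_struct[, d], latent$u_iid[, d])
  }
  eta <- assemble_predictor(fixed,
                            list(lambda = lambda, u = u, phi = latent$phi,
                                 v = latent$v, psi = latent$psi),
                            spec, X = X)
  ll <- poisson_loglik(y, E, eta)

  lp_lambda <- .structure_logprior(latent$lambda_struct, spec$icar,
                                   name = "lambda_struct") +
    .constrained_iid_logprior(latent$lambda_iid, spec$icar, "lambda_iid")
  lp_u <- 0
  for (d in seq_len(D)) {
    lp_u <- lp_u +
      .structure_logprior(latent$u_struct[, d], spec$icar,
                          name = paste0("u_struct[, ", d, "]")) +
      .constrained_iid_logprior(latent$u_iid[, d], spec$icar,
                                paste0("u_iid[, ", d, "]"))
  }
  lp_phi <- .structure_logprior(latent$phi, spec$rw1, tau = h["tau_phi"],
                                name = "phi")
  lp_v <- 0
  for (d in seq_len(D)) {
    lp_v <- lp_v + .structure_logprior(latent$v[, d], spec$rw1,
                                       tau = h["tau_v"],
                                       name = paste0("v[, ", d, "]"))
  }
  lp_psi <- sum(stats::dnorm(latent$psi, 0, 1 / sqrt(h["tau_psi"]), log = TRUE))
  lp_alpha <- sum(stats::dnorm(fixed$alpha, 0, 1 / sqrt(h["tau_alpha"]),
                               log = TRUE))
  bp <- spec$priors$beta_prec
  lp_fixed <- sum(stats::dnorm(c(fixed$beta, fixed$mu), 0, 1 / sqrt(bp),
                               log = TRUE))

  pr <- spec$priors
  lp_hyper <-
    pc_prior_precision_logpdf(h["tau_lambda"], pr$tau_lambda$U, pr$tau_lambda$alpha) +
    pc_prior_precision_logpdf(h["tau_u"], pr$tau_u$U, pr$tau_u$alpha) +
    pc_prior_precision_logpdf(h["tau_phi"], pr$tau_phi$U, pr$tau_phi$alpha) +
    pc_prior_precision_logpdf(h["tau_v"], pr$tau_v$U, pr$tau_v$alpha) +
    pc_prior_precision_logpdf(h["tau_psi"], pr$tau_psi$U, pr$tau_psi$alpha) +
    pc_prior_precision_logpdf(h["tau_alpha"], pr$tau_alpha$U, pr$tau_alpha$alpha) +
    pc_prior_mixing_logpdf(h["rho_lambda"], spec$icar, pr$rho_lambda$U,
                           pr$rho_lambda$alpha) +
    pc_prior_mixing_logpdf(h["rho_u"], spec$icar, pr$rho_u$U, pr$rho_u$alpha)

  blocks <- c(loglik = ll$total, lambda = lp_lambda, u = lp_u, phi = lp_phi,
              v = lp_v, psi = lp_psi, alpha = lp_alpha, fixed = lp_fixed,
              hyper = unname(lp_hyper))
  list(total = sum(blocks), blocks = blocks, eta = eta)
}
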