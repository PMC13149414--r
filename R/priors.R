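#' Penalized-complexity prior on a precision
#'
#' The PC prior for a random-effect precision tau shrinks toward the base
#' model of no effect. On the standard-deviation scale sigma = tau^{-1/2} it
#' is Exponential(lambda) with lambda = -log(alpha)/U, calibrated so that
#' P(sigma > U) = alpha. Change of variables to tau gives
#' p(tau) = (lambda/2) tau^{-3/2} exp(-lambda tau^{-1/2}).
#'
#' @param tau precision (> 0); vectorized.
#' @param U threshold on the sd scale (> 0).
#' @param alpha tail probability in (0, 1).
#' @return log density at `tau`.
#' @export
pc_prior_precision_logpdf <- function(tau, U = 1, alpha = 0.01) {
  if (any(tau <= 0)) stop("tau must be positive")
  if (U <= 0) stop("U must be positive")
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  lambda <- -log(alpha) / U
  log(lambda / 2) - 1.5 * log(tau) - lambda / sqrt(tau)
}

#' Distance from the base model for the BYM2 mixing parameter
#'
#' For a scaled structure with positive eigenvalues gamma_k, the BYM2
#' covariance on the constrained subspace at mixing rho has eigenvalues
#' (1 - rho) + rho / gamma_k. The complexity distance from the base model
#' rho = 0 (pure iid) is d(rho) = sqrt(2 KLD(rho)) with
#' KLD = 0.5 * sum[(s_k - 1) - log s_k], s_k = 1 - rho + rho / gamma_k.
#'
#' @param rho mixing in [0, 1]; vectorized.
#' @param structure a scaled `structure_matrix`.
#' @return list with `d` and derivative `d_prime` (NA at rho where d = 0).
#' @keywords internal
.bym2_distance <- function(rho, structure) {
  g <- structure$values
  d <- d1 <- numeric(length(rho))
  for (j in seq_along(rho)) {
    s <- 1 - rho[j] + rho[j] / g
    kld <- 0.5 * sum(s - 1 - log(s))
    kld1 <- 0.5 * sum((1 / g - 1) * (1 - 1 / s))
    d[j] <- sqrt(2 * max(kld, 0))
    d1[j] <- if (d[j] > 0) kld1 / d[j] else NA_real_
  }
  list(d = d, d_prime = d1)
}

#' Penalized-complexity prior on the BYM2 mixing parameter
#'
#' PC prior for rho in (0, 1), built from the Kullback-Leibler complexity
#' distance d(rho) between the BYM2 model at rho and the iid base model
#' (rho = 0), computed from the eigenvalues of the scaled structure:
#' p(rho) = lambda exp(-lambda d(rho)) |d'(rho)| / (1 - exp(-lambda d(1))),
#' with lambda calibrated so that P(rho < U) = alpha.
#'
#' @param rho mixing value(s) in (0, 1).
#' @param structure a scaled `structure_matrix`.
#' @param U calibration threshold in (0, 1), default 0.5.
#' @param alpha calibration probability, default 2/3.
#' @return log density at `rho`.
#' @export
pc_prior_mixing_logpdf <- function(rho, structure, U = 0.5, alpha = 2 / 3) {
  stopifnot(inherits(structure, "structure_matrix"))
  if (!structure$scaled) stop("structure must be variance-scaled first")
  if (any(rho <= 0 | rho >= 1)) stop("rho must be in (0, 1)")
  lam <- .pc_mixing_lambda(structure, U, alpha)
  dist <- .bym2_distance(rho, structure)
  d1 <- .bym2_distance(1, structure)$d
  log(lam) - lam * dist$d + log(abs(dist$d_prime)) - log1p(-exp(-lam * d1))
}

# Solve the calibration P(rho < U) = alpha for the PC rate. Because d(rho)
# is increasing, the CDF has closed form
#   F(U) = (1 - exp(-lam d(U))) / (1 - exp(-lam d(1))).
.pc_mixing_lambda <- function(structure, U, alpha) {
  if (U <= 0 || U >= 1) stop("U must be in (0, 1)")
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  dU <- .bym2_distance(U, structure)$d
  d1 <- .bym2_distance(1 - 1e-12, structure)$d
  f <- function(lam) {
    (1 - exp(-lam * dU)) / (1 - exp(-lam * d1)) - alpha
  }
  # F(U) increases with lam from d(U)/d(1) (flat limit) to 1; bracket and
  # root-find. If even the flattest prior exceeds alpha below U, the
  # calibration is unattainable and the flat limit is returned.
  lo <- 1e-8; hi <- 1
  if (f(lo) >= 0) return(lo)
  while (f(hi) < 0 && hi < 1e8) hi <- hi * 10
  stats::uniroot(f, c(lo, hi), tol = 1e-12)$root
}

#' Cumulative distribution of the PC mixing prior
#' @inheritParams pc_prior_mixing_logpdf
#' @return P(mixing < rho).
#' @export
pc_prior_mixing_cdf <- function(rho, structure, U = 0.5, alpha = 2 / 3) {
  lam <- .pc_mixing_lambda(structure, U, alpha)
  d <- .bym2_distance(rho, structure)$d
  d1 <- .bym2_distance(1 - 1e-12, structure)$d
  (1 - exp(-lam * d)) / (1 - exp(-lam * d1))
}

#' Combine structured and unstructured parts into a BYM2 effect
#'
#' b = (1/sqrt(tau)) (sqrt(rho) u* + sqrt(1 - rho) v), where u* is drawn
#' under the variance-scaled structure (sum-to-zero) and v is a standard
#' normal vector. The generalized marginal variance of b is 1/tau for every
#' rho, which is what makes tau interpretable.
#'
#' @param rho mixing in [0, 1].
#' @param tau precision (> 0).
#' @param u_star structured (scaled ICAR) vector.
#' @param v_iid unstructured standard-normal vector, same length.
#' @return the combined spatial effect vector.
#' @export
bym2_combine <- function(rho, tau, u_star, v_iid) {
  if (length(u_star) != length(v_iid)) stop("u_star and v_iid lengths differ")
  if (rho < 0 || rho > 1) stop("rho must be in [0, 1]")
  if (tau <= 0) stop("tau must be positive")
  (sqrt(rho) * u_star + sqrt(1 - rho) * v_iid) / sqrt(tau)
}

#' Condition a Gaussian vector on linear constraints (kriging)
#'
#' Given x ~ N(mu, Sigma) and constraints A x = e, the conditioned vector is
#' x - Sigma A' (A Sigma A')^{-1} (A x - e): the standard
#' conditioning-by-kriging correction used to impose sum-to-zero constraints
#' on intrinsic fields after unconstrained sampling.
#'
#' @param x unconstrained draw (or mean) vector.
#' @param Sigma covariance (or generalized covariance) matrix of x.
#' @param A constraint matrix (k x n), rows are constraint directions.
#' @param e constraint values, default zero.
#' @return the corrected vector satisfying A x = e.
#' @export
krige_constrain <- function(x, Sigma, A, e = rep(0, nrow(A))) {
  A <- matrix(A, ncol = length(x))
  V <- A %*% Sigma %*% t(A)
  x - drop(Sigma %*% t(A) %*% solve(V, drop(A %*% x) - e))
}

#' Sample a zero-mean Gaussian under linear constraints
#'
#' Draws from N(0, Sigma) restricted to {x : A x = 0} by unconstrained
#' sampling followed by the kriging correction.
#'
#' @param n number of draws.
#' @param Sigma covariance matrix (may be a generalized inverse of an
#'   intrinsic precision).
#' @param A constraint matrix; NULL for unconstrained sampling.
#' @return n x dim matrix of draws.
#' @export
sample_constrained_gaussian <- function(n, Sigma, A = NULL) {
  p <- nrow(Sigma)
  eg <- eigen(Sigma, symmetric = TRUE)
  pos <- eg$values > max(eg$values, 0) * 1e-12
  half <- eg$vectors[, pos, drop = FALSE] %*%
    diag(sqrt(eg$values[pos]), sum(pos))
  Z <- matrix(stats::rnorm(n * sum(pos)), n, sum(pos))
  X <- Z %*% t(half)
  if (!is.null(A)) {
    X <- t(apply(X, 1L, krige_constrain, Sigma = Sigma, A = A))
    if (p == 1L) X <- t(X)
  }
  X
}

#' Draw one realization of an intrinsic (scaled) structure prior
#'
#' Samples u ~ N(0, (tau Q*)^+) subject to sum-to-zero within each connected
#' component, using the spectral representation of the scaled structure
#' (equivalent to kriging-corrected sampling from the generalized inverse).
#'
#' @param structure a scaled `structure_matrix`.
#' @param tau precision multiplier.
#' @return numeric vector of length `structure$n`.
#' @export
sample_structure_prior <- function(structure, tau = 1) {
  stopifnot(inherits(structure, "structure_matrix"))
  z <- stats::rnorm(structure$rank, sd = 1 / sqrt(structure$values * tau))
  drop(structure$vectors %*% z)
}
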