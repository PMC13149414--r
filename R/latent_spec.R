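#' Default hyperprior settings
#'
#' Penalized-complexity priors for every random-effect precision
#' (P(sigma > U) = alpha with U = 1, alpha = 0.01) and for the BYM2 mixing
#' parameters (P(rho < 0.5) = 2/3): the conventional defaults of these model
#' classes. All are configurable per component.
#'
#' @return nested list: one `(U, alpha)` pair per precision
#'   (lambda, u, phi, v, psi, alpha) and per mixing (rho_lambda, rho_u),
#'   plus `beta_prec`, the fixed-effect Gaussian prior precision.
#' @export
default_hyperpriors <- function() {
  pc <- list(U = 1, alpha = 0.01)
  list(tau_lambda = pc, tau_u = pc, tau_phi = pc, tau_v = pc,
       tau_psi = pc, tau_alpha = pc,
       rho_lambda = list(U = 0.5, alpha = 2 / 3),
       rho_u = list(U = 0.5, alpha = 2 / 3),
       beta_prec = 0.001)
}

#' Names and order of the model hyperparameters
#' @return character vector of the eight hyperparameter names.
#' @export
hyper_names <- function() {
  c("tau_lambda", "tau_u", "tau_phi", "tau_v", "tau_psi", "tau_alpha",
    "rho_lambda", "rho_u")
}

.check_hyper <- function(hyper) {
  hyper <- unlist(hyper)[hyper_names()]
  if (anyNA(hyper)) stop("hyper must contain: ", paste(hyper_names(), collapse = ", "))
  if (any(hyper[1:6] <= 0)) stop("precisions must be positive")
  if (any(hyper[7:8] < 0 | hyper[7:8] > 1)) stop("mixing parameters must be in [0, 1]")
  hyper
}

#' Build the latent-component specification
#'
#' Assembles everything the joint model needs about its seven predictor
#' components: the variance-scaled ICAR and RW1 structures, the
#' per-component kinds/dimensions/grouping, sum-to-zero constraint sets, and
#' the spectral bases on which inference parameterizes the improper priors.
#'
#' Components of the log relative risk, in panel row order
#' (disease-major, country, year):
#' \itemize{
#'  \item alpha_d: iid disease intercepts (plus a global level with a weak
#'    Gaussian prior),
#'  \item x'beta: fixed effects, common across diseases,
#'  \item lambda_i: shared BYM2 spatial effect,
#'  \item u_id: disease-specific BYM2 spatial effects (one tau/rho for all
#'    diseases),
#'  \item phi_t: shared RW1 temporal effect,
#'  \item v_td: disease-specific RW1 temporal effects,
#'  \item psi_itd: iid space-time interaction grouped by disease (one common
#'    precision).
#' }
#'
#' @param graph a `country_graph`.
#' @param years integer vector of consecutive years.
#' @param diseases character vector of disease labels.
#' @param covariates character vector of covariate names.
#' @param priors hyperprior settings, see [default_hyperpriors()].
#' @return a `latent_spec` list.
#' @export
build_latent_spec <- function(graph, years, diseases, covariates,
                              priors = default_hyperpriors()) {
  stopifnot(inherits(graph, "country_graph"))
  years <- sort(as.integer(years))
  if (length(years) < 2L || !all(diff(years) == 1L)) {
    stop("years must be >= 2 consecutive integers")
  }
  icar <- scale_structure(build_icar_structure(graph))
  rw1 <- scale_structure(build_rw1_structure(length(years)))
  I <- length(graph$nodes); D <- length(diseases); Tn <- length(years)
  components <- list(
    alpha  = list(kind = "iid",  dim = D,      grouping = "none"),
    beta   = list(kind = "fixed", dim = length(covariates), grouping = "none"),
    lambda = list(kind = "bym2", dim = I,      grouping = "none"),
    u      = list(kind = "bym2", dim = I * D,  grouping = "by-disease"),
    phi    = list(kind = "rw1",  dim = Tn,     grouping = "none"),
    v      = list(kind = "rw1",  dim = Tn * D, grouping = "by-disease"),
    psi    = list(kind = "iid",  dim = I * Tn * D, grouping = "by-disease")
  )
  spec <- structure(list(
    graph = graph, icar = icar, rw1 = rw1,
    countries = graph$nodes, years = years, diseases = sort(diseases),
    covariates = covariates,
    I = I, D = D, T = Tn, n = I * Tn * D,
    components = components, priors = priors
  ), class = "latent_spec")
  spec$constraints <- build_constraints(spec)
  spec
}

#' @export
print.latent_spec <- function(x, ...) {
  cat(sprintf("latent_spec: I=%d countries, D=%d diseases, T=%d years, %d covariates\n",
              x$I, x$D, x$T, length(x$covariates)))
  cat(sprintf("  ICAR rank %d (scaling %.4g), RW1 rank %d (scaling %.4g)\n",
              x$icar$rank, x$icar$scaling, x$rw1$rank, x$rw1$scaling))
  invisible(x)
}

#' Identifiability constraints of the latent components
#'
#' Sum-to-zero over countries for the shared spatial effect (per connected
#' component), over countries within each disease for the disease-specific
#' spatial effects, over years for the shared temporal effect, and over
#' years within each disease for the disease-specific temporal effects.
#' Disease intercepts are iid (not sum-to-zero constrained); the overall
#' level is identified by the weakly-penalized global intercept.
#'
#' @param spec a `latent_spec` (or list with icar/rw1 structures and I, D, T).
#' @return named list of constraint matrices (rows = constraint directions).
#' @export
build_constraints <- function(spec) {
  I <- spec$I; D <- spec$D; Tn <- spec$T
  # per-connected-component sum-to-zero for ICAR pieces
  A_sp <- t(spec$icar$null_basis)
  A_ti <- matrix(1, 1L, Tn)
  per_disease <- function(A, size) {
    k <- nrow(A)
    out <- matrix(0, k * D, size * D)
    for (d in seq_len(D)) {
      out[(d - 1L) * k + seq_len(k), (d - 1L) * size + seq_len(size)] <- A
    }
    out
  }
  cons <- list(lambda = A_sp, u = per_disease(A_sp, I),
               phi = A_ti, v = per_disease(A_ti, Tn),
               alpha = NULL, psi = NULL, beta = NULL)
  # every constraint direction must be in the corresponding null space
  for (nmc in c("lambda", "phi")) {
    st <- if (nmc == "lambda") spec$icar else spec$rw1
    A <- cons[[nmc]]
    proj <- A %*% st$vectors
    if (max(abs(proj)) > 1e-8) {
      stop("constraint directions for ", nmc, " not in the structure null space")
    }
  }
  cons
}

# ---- internal: spectral layout used by inference -------------------------
#
# The latent field is parameterized by standardized coordinates z with a
# proper diagonal Gaussian prior. Improper ICAR/RW1 components are expressed
# on the eigenbasis of their scaled structure restricted to the positive
# eigenvalues (which spans exactly the constraint-orthogonal subspace), so
# every sum-to-zero constraint holds by construction; BYM2 unstructured
# halves use the same basis (a standard normal restricted to sum-to-zero).
# Hyperparameters enter only as per-block scale multipliers on the design.
.spec_layout <- function(spec, p) {
  rs <- spec$icar$rank; rt <- spec$rw1$rank; D <- spec$D
  blocks <- list(
    beta = p, mu = 1L, a_alpha = D,
    s_lambda = rs, w_lambda = rs,
    s_u = rs * D, w_u = rs * D,
    s_phi = rt, s_v = rt * D)
  sizes <- unlist(blocks)
  ends <- cumsum(sizes); starts <- ends - sizes + 1L
  idx <- Map(function(s, e) seq.int(s, e), starts, ends)
  names(idx) <- names(blocks)
  q0 <- c(rep(spec$priors$beta_prec, p + 1L), rep(1, D),
          spec$icar$values, rep(1, rs),
          rep(spec$icar$values, D), rep(1, rs * D),
          spec$rw1$values, rep(spec$rw1$values, D))
  list(idx = idx, m = sum(sizes), q0 = q0)
}

# Per-coordinate design multipliers implied by a hyperparameter setting.
.spec_coefs <- function(spec, layout, hyper) {
  h <- .check_hyper(hyper)
  cf <- numeric(layout$m)
  idx <- layout$idx
  cf[idx$beta] <- 1; cf[idx$mu] <- 1
  cf[idx$a_alpha] <- 1 / sqrt(h["tau_alpha"])
  cf[idx$s_lambda] <- sqrt(h["rho_lambda"] / h["tau_lambda"])
  cf[idx$w_lambda] <- sqrt((1 - h["rho_lambda"]) / h["tau_lambda"])
  cf[idx$s_u] <- sqrt(h["rho_u"] / h["tau_u"])
  cf[idx$w_u] <- sqrt((1 - h["rho_u"]) / h["tau_u"])
  cf[idx$s_phi] <- 1 / sqrt(h["tau_phi"])
  cf[idx$s_v] <- 1 / sqrt(h["tau_v"])
  cf
}
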