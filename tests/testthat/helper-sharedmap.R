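# Small in-code fixtures shared across the suite.

# deterministic balanced panel: I countries x D diseases x T years
make_raw_panel <- function(I = 3L, D = 2L, T_len = 4L, year0 = 2001L) {
  countries <- paste0("C", seq_len(I))
  diseases <- paste0("dis", seq_len(D))
  years <- seq.int(year0, length.out = T_len)
  g <- expand.grid(year = years, country_id = countries, disease = diseases,
                   stringsAsFactors = FALSE)
  i <- match(g$country_id, countries); t <- g$year - year0 + 1L
  g$population <- 1e6 * i
  g$asmr <- 50 + 10 * match(g$disease, diseases)
  g$deaths <- as.integer(round(g$population * g$asmr / 1e5 * 0.9))
  g$x1 <- i + 0.1 * t
  g$x2 <- sin(i) + 0.05 * t^2
  g[, c("country_id", "year", "disease", "deaths", "population", "asmr",
        "x1", "x2")]
}

# path graph on n labeled nodes
make_path_graph <- function(n = 3L, labels = paste0("C", seq_len(n))) {
  country_graph(labels, cbind(labels[-n], labels[-1L]))
}

# random connected graph (spanning tree + extra edges), deterministic per seed
make_random_connected_graph <- function(n, seed, extra = n) {
  set.seed(seed)
  labels <- sprintf("N%02d", seq_len(n))
  tree <- cbind(labels[2:n],
                labels[vapply(2:n, function(i) sample.int(i - 1L, 1L), 1L)])
  more <- t(replicate(extra, sample(labels, 2L)))
  edges <- rbind(tree, more[more[, 1L] != more[, 2L], , drop = FALSE])
  # drop duplicate undirected edges
  key <- apply(edges, 1L, function(e) paste(sort(e), collapse = "-"))
  country_graph(labels, edges[!duplicated(key), , drop = FALSE])
}

# tiny fitted spec for model-level tests
make_tiny_spec <- function(I = 3L, D = 2L, T_len = 3L, covs = c("x1", "x2")) {
  build_latent_spec(make_path_graph(I), seq.int(2001L, length.out = T_len),
                    paste0("dis", seq_len(D)), covs)
}

# random natural-scale latent state satisfying all constraints
random_latent_state <- function(spec, hyper, seed = 1L) {
  set.seed(seed)
  draw_ci <- function(st) drop(st$vectors %*% rnorm(st$rank))
  D <- spec$D
  lambda_struct <- sample_structure_prior(spec$icar, 1)
  lambda_iid <- draw_ci(spec$icar)
  u_struct <- u_iid <- matrix(0, spec$I, D)
  v <- matrix(0, spec$T, D)
  for (d in seq_len(D)) {
    u_struct[, d] <- sample_structure_prior(spec$icar, 1)
    u_iid[, d] <- draw_ci(spec$icar)
    v[, d] <- sample_structure_prior(spec$rw1, hyper[["tau_v"]])
  }
  list(lambda_struct = lambda_struct, lambda_iid = lambda_iid,
       u_struct = u_struct, u_iid = u_iid,
       phi = sample_structure_prior(spec$rw1, hyper[["tau_phi"]]),
       v = v,
       psi = rnorm(spec$n, 0, 1 / sqrt(hyper[["tau_psi"]])))
}

# quadrature oracle for a single Poisson count with a Gaussian prior on eta
quad_posterior_1d <- function(y, E, m0, s0) {
  lpost <- function(eta) dpois(y, E * exp(eta), log = TRUE) +
    dnorm(eta, m0, s0, log = TRUE)
  mode <- optimize(lpost, c(m0 - 12 * s0, m0 + 12 * s0),
                   maximum = TRUE)$maximum
  width <- 1 / sqrt(y + 1 / s0^2)            # local curvature scale
  lo <- mode - 12 * width; hi <- mode + 12 * width
  post <- function(eta) exp(lpost(eta) - lpost(mode))
  Z <- integrate(post, lo, hi, rel.tol = 1e-12)$value
  m1 <- integrate(function(e) e * post(e), lo, hi, rel.tol = 1e-12)$value / Z
  m2 <- integrate(function(e) e^2 * post(e), lo, hi, rel.tol = 1e-12)$value / Z
  list(mean = m1, sd = sqrt(m2 - m1^2))
}

default_true_hyper <- function() {
  c(tau_lambda = 10, tau_u = 25, tau_phi = 10, tau_v = 25, tau_psi = 100,
    tau_alpha = 4, rho_lambda = 0.6, rho_u = 0.6)
}
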