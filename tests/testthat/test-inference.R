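test_that("the 1-D Laplace approximation matches adaptive quadrature", {
  m0 <- 0; s0 <- 1.5; E <- 1
  fit <- poisson_laplace(25, E, B = matrix(s0), q0 = 1, offset = m0)
  lm_ <- laplace_marginals(fit)
  lap_mean <- m0 + s0 * lm_$mean
  lap_sd <- s0 * lm_$sd
  truth <- quad_posterior_1d(25, E, m0, s0)
  expect_lt(abs(lap_mean - truth$mean) / abs(truth$mean), 0.02)
  expect_lt(abs(lap_sd - truth$sd) / truth$sd, 0.05)
  # increasing the count tightens the posterior, Laplace and quadrature alike
  sds <- vapply(c(5, 25, 100, 400), function(y) {
    f <- poisson_laplace(y, E, B = matrix(s0), q0 = 1, offset = m0)
    s0 * laplace_marginals(f)$sd
  }, numeric(1))
  expect_true(all(diff(sds) < 0))
  qsds <- vapply(c(5, 25, 100, 400), function(y) quad_posterior_1d(y, E, m0, s0)$sd,
                 numeric(1))
  expect_true(all(diff(qsds) < 0))
  expect_equal(sds, qsds, tolerance = 0.05)
})

test_that("Gaussian draws from the Laplace fit reproduce its marginals", {
  set.seed(21)
  panel <- validate_panel(make_raw_panel(3, 2, 4))
  model <- build_model(panel, make_path_graph(3))
  h <- default_true_hyper()
  fit <- laplace_latent(h, model)
  expect_true(all(diff(fit$trace) >= -1e-9))    # monotone Newton ascent
  dr <- draw_laplace(fit, 4000)
  lm_ <- laplace_marginals(fit)
  expect_equal(colMeans(dr$z), fit$z, tolerance = 0.05)
  se <- lm_$sd / sqrt(4000)
  expect_lt(max(abs(colMeans(dr$z) - fit$z) / pmax(lm_$sd, 1e-6)), 0.1)
  expect_equal(apply(dr$z, 2, sd), lm_$sd, tolerance = 0.1)
  # interaction coordinates recentre on the mode too
  expect_lt(max(abs(colMeans(dr$psi) - fit$psi)), 0.15)
})

test_that("hyperparameter sampling is bit-reproducible under a fixed seed", {
  panel <- validate_panel(make_raw_panel(3, 2, 4))
  model <- build_model(panel, make_path_graph(3))
  ctrl <- fit_control(n_iter = 300, burnin = 100, thin = 2, seed = 77)
  p1 <- sample_hyperparameters(model, ctrl)
  p2 <- sample_hyperparameters(model, ctrl)
  expect_identical(p1$hyper, p2$hyper)
  expect_identical(p1$beta, p2$beta)
  expect_identical(p1$eta, p2$eta)
  expect_identical(summarize_draws(p1$lambda), summarize_draws(p2$lambda))
})

test_that("the Metropolis chain reproduces its own 1-D marginal target (grid oracle)", {
  panel <- validate_panel(make_raw_panel(3, 2, 4))
  model <- build_model(panel, make_path_graph(3))
  h0 <- default_true_hyper()
  free <- "tau_psi"
  ctrl <- fit_control(n_iter = 9000, burnin = 1500, thin = 12, seed = 5)
  post <- sample_hyperparameters(model, ctrl, hyper_init = h0,
                                 fix = setdiff(hyper_names(), free))
  draws <- log(post$hyper[, free])
  # grid evaluation of the same target: Laplace evidence + PC prior + Jacobian
  grid <- seq(min(draws) - 1.5, max(draws) + 1.5, length.out = 200)
  pr <- model$spec$priors$tau_psi
  lp <- vapply(grid, function(th) {
    hh <- h0; hh[free] <- exp(th)
    laplace_latent(hh, model)$log_evidence +
      pc_prior_precision_logpdf(exp(th), pr$U, pr$alpha) + th
  }, numeric(1))
  w <- exp(lp - max(lp)); cdf <- cumsum(w) / sum(w)
  F_grid <- approxfun(grid, cdf, yleft = 0, yright = 1)
  probs <- seq(0.1, 0.9, by = 0.1)
  gap <- max(abs(F_grid(quantile(draws, probs)) - probs))
  expect_lt(gap, 0.05)
})

test_that("the GLM limit recovers IRLS coefficients", {
  glm_hyper <- c(tau_lambda = 1e6, tau_u = 1e6, tau_phi = 1e6, tau_v = 1e6,
                 tau_psi = 1e6, tau_alpha = 1e6, rho_lambda = 0.5, rho_u = 0.5)
  cfg <- simulation_config(seed = 31, hyper = glm_hyper)
  sim <- simulate_panel(cfg)
  model <- build_model(sim$panel, cfg$graph)
  fit <- laplace_latent(glm_hyper, model)
  lm_ <- laplace_marginals(fit)
  bidx <- model$layout$idx$beta
  beta_hat <- lm_$mean[bidx]; beta_sd <- lm_$sd[bidx]
  # IRLS oracle
  df <- as.data.frame(model$panel)
  Xs <- as.matrix(df[, attr(model$panel, "covariates")])
  or <- glm(model$y ~ Xs + offset(log(model$E)), family = poisson())
  expect_lt(max(abs(beta_hat - unname(coef(or)[-1])) / beta_sd), 3)
  expect_equal(beta_hat, unname(coef(or)[-1]), tolerance = 1e-2)
})

test_that("relabeling countries permutes the spatial-effect estimates exactly", {
  raw <- make_raw_panel(3, 2, 4)
  set.seed(4)
  raw$deaths <- rpois(nrow(raw), raw$population * raw$asmr / 1e5 *
                        exp(0.2 * (match(raw$country_id, c("C1", "C2", "C3")) - 2)))
  g <- make_path_graph(3)
  m1 <- build_model(validate_panel(raw), g)
  h <- default_true_hyper()
  s1 <- latent_state_from_coords(m1, h, laplace_latent(h, m1)$z,
                                 laplace_latent(h, m1)$psi)
  # relabel C1 -> Q3, C2 -> Q1, C3 -> Q2 (changes the alphabetical order)
  map <- c(C1 = "Q3", C2 = "Q1", C3 = "Q2")
  raw2 <- raw; raw2$country_id <- unname(map[raw$country_id])
  g2 <- country_graph(unname(map), cbind(map[c("C1", "C2")], map[c("C2", "C3")]))
  m2 <- build_model(validate_panel(raw2), g2)
  f2 <- laplace_latent(h, m2)
  s2 <- latent_state_from_coords(m2, h, f2$z, f2$psi)
  lam1 <- setNames(s1$lambda, m1$spec$countries)
  lam2 <- setNames(s2$lambda, m2$spec$countries)
  expect_equal(unname(lam2[map[c("C1", "C2", "C3")]]),
               unname(lam1[c("C1", "C2", "C3")]), tolerance = 1e-7)
})

test_that("posterior summaries have the documented shape and behavior", {
  expect_error(summarize_draws(matrix(rnorm(50), 50)), "at least 100")
  s <- summarize_draws(matrix(3.5, 200, 1), names = "c")
  expect_equal(s$mean, 3.5); expect_equal(s$sd, 0)
  expect_equal(s$median, 3.5); expect_equal(s$mode, 3.5)
  set.seed(6)
  z <- matrix(rnorm(1e5), ncol = 1)
  s2 <- summarize_draws(z, names = "z")
  expect_equal(s2$q2.5, -1.96, tolerance = 0.02)
  expect_equal(s2$q97.5, 1.96, tolerance = 0.02)
  expect_equal(s2$median, 0, tolerance = 0.02)
  expect_equal(s2$mode, 0, tolerance = 0.12)
  # quantile equivariance under the exp transform
  s3 <- summarize_draws(exp(z), names = "ez")
  expect_equal(s3$q2.5, exp(s2$q2.5), tolerance = 1e-6)
  expect_equal(s3$median, exp(s2$median), tolerance = 1e-6)
})

test_that("replicated-component precisions are recovered within a factor of two", {
  # tau_u, tau_v (one realization per disease) and tau_psi (one per row) are
  # the precisions the 7 x 4 x 20 design informs; the shared spatial and
  # intercept precisions rest on 6 and 4 effective observations and remain
  # prior-dominated at this size.
  n_rep <- 8
  ratios <- matrix(NA, n_rep, 3,
                   dimnames = list(NULL, c("tau_u", "tau_v", "tau_psi")))
  for (r in seq_len(n_rep)) {
    cfg <- simulation_config(seed = 3000 + r)
    sim <- simulate_panel(cfg)
    model <- build_model(sim$panel, cfg$graph)
    post <- suppressWarnings(sample_hyperparameters(
      model, fit_control(n_iter = 500, burnin = 200, thin = 2,
                         seed = 3100 + r)))
    pm <- colMeans(post$hyper)
    ratios[r, ] <- pm[colnames(ratios)] / cfg$hyper[colnames(ratios)]
  }
  hit <- colMeans(ratios > 0.5 & ratios < 2)
  expect_true(all(hit >= 0.75))
})

test_that("fixed-effect bias shrinks as the panel lengthens", {
  err <- function(T_len, seed) {
    g <- make_path_graph(4)
    cfg <- simulation_config(I = 4, T_len = T_len, graph = g, seed = seed)
    sim <- simulate_panel(cfg)
    model <- build_model(sim$panel, g)
    fit <- laplace_latent(cfg$hyper, model)
    mean(abs(fit$z[model$layout$idx$beta] - unname(cfg$beta)))
  }
  e20 <- mean(vapply(1:4, function(s) err(20L, 400 + s), numeric(1)))
  e80 <- mean(vapply(1:4, function(s) err(80L, 500 + s), numeric(1)))
  expect_lt(e80, e20)
})
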