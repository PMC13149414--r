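test_that("the default simulation reproduces the study dimensions", {
  cfg <- simulation_config(seed = 1)
  sim <- simulate_panel(cfg)
  expect_equal(nrow(sim$panel), 560)            # 7 x 4 x 20
  expect_length(attr(sim$panel, "countries"), 7)
  expect_length(attr(sim$panel, "diseases"), 4)
  expect_length(attr(sim$panel, "years"), 20)
  expect_equal(attr(sim$panel, "years"), 2000:2019)
  # generated panels pass validation by construction (re-validate explicitly)
  expect_silent(validate_panel(as.data.frame(sim$panel)))
  # ground truth reassembles eta exactly
  eta2 <- assemble_predictor(sim$truth$fixed, sim$truth$latent,
                             sim$truth$spec, X = sim$truth$Xstd)
  expect_identical(eta2, sim$truth$eta)
  expect_error(simulation_config(), "seed")
})

test_that("simulation is bit-reproducible under a fixed seed", {
  cfg <- simulation_config(seed = 33)
  s1 <- simulate_panel(cfg)
  s2 <- simulate_panel(cfg)
  expect_identical(as.data.frame(s1$panel), as.data.frame(s2$panel))
  expect_identical(s1$truth$latent, s2$truth$latent)
  s3 <- simulate_panel(simulation_config(seed = 34))
  expect_false(identical(s1$panel$deaths, s3$panel$deaths))
})

test_that("simulated covariates have the configured temporal autocorrelation", {
  g <- make_path_graph(2)
  lag1 <- function(ar, seed) {
    cfg <- simulation_config(I = 2, T_len = 3000, graph = g, seed = seed,
                             ar_coef = ar)
    cv <- simulate_covariates(cfg)
    x <- cv$ndvi[cv$country_id == "C1"]
    cor(x[-1], x[-length(x)])
  }
  expect_lt(abs(lag1(0, 41)), 0.1)              # white-noise limit
  expect_equal(lag1(0.9, 42), 0.9, tolerance = 0.1)
  expect_error(simulation_config(seed = 1, ar_coef = 1.2), "AR coefficient")
  # determinism
  cfg <- simulation_config(seed = 7)
  expect_identical(simulate_covariates(cfg), simulate_covariates(cfg))
  # covariates constant across diseases within (country, year) cells
  sim <- simulate_panel(cfg)
  cc <- covariate_cells(sim$panel)
  expect_equal(nrow(cc$X), 7 * 20)
})

test_that("the null model yields counts at the expected level", {
  tiny <- c(tau_lambda = 1e8, tau_u = 1e8, tau_phi = 1e8, tau_v = 1e8,
            tau_psi = 1e8, tau_alpha = 1e8, rho_lambda = 0.5, rho_u = 0.5)
  cfg <- simulation_config(seed = 19, hyper = tiny,
                           beta = setNames(rep(0, 8),
                                           names(simulation_config(seed = 1)$beta)))
  sim <- simulate_panel(cfg)
  ratio <- sim$panel$deaths / sim$panel$expected_deaths
  # mean(Y/E) = 1 within 3 Monte-Carlo standard errors
  mc_se <- sd(ratio) / sqrt(length(ratio))
  expect_lt(abs(mean(ratio) - 1), 3 * mc_se + 1e-4)
})

test_that("country-level risk tracks the planted spatial effect at inflated exposure", {
  cfg <- simulation_config(seed = 23, e_scale = 100)
  sim <- simulate_panel(cfg)
  ix <- panel_index_map(sim$truth$spec)
  log_ratio <- log(sim$panel$deaths / sim$panel$expected_deaths)
  other <- sim$truth$eta - sim$truth$latent$lambda[ix$i]
  resid <- tapply(log_ratio - other, ix$i, mean)
  expect_gt(cor(resid, sim$truth$latent$lambda, method = "spearman"), 0.9)
})

test_that("simulated latent blocks match their prior marginal variances", {
  spec <- make_tiny_spec(I = 4, D = 2, T_len = 6)
  h <- default_true_hyper()
  n_rep <- 1000
  set.seed(55)
  phi_draws <- t(replicate(n_rep, sample_structure_prior(spec$rw1,
                                                         h[["tau_phi"]])))
  target <- structure_marginal_variances(spec$rw1) / h[["tau_phi"]]
  emp <- apply(phi_draws, 2, var)
  mc_se <- target * sqrt(2 / n_rep)
  expect_true(all(abs(emp - target) < 3.5 * mc_se))
  lam_draws <- t(replicate(n_rep, {
    bym2_combine(h[["rho_lambda"]], h[["tau_lambda"]],
                 sample_structure_prior(spec$icar, 1),
                 drop(spec$icar$vectors %*% rnorm(spec$icar$rank)))
  }))
  tgt_lam <- (h[["rho_lambda"]] * structure_marginal_variances(spec$icar) +
                (1 - h[["rho_lambda"]]) *
                rowSums(spec$icar$vectors^2)) / h[["tau_lambda"]]
  expect_true(all(abs(apply(lam_draws, 2, var) - tgt_lam) <
                    3.5 * tgt_lam * sqrt(2 / n_rep)))
})

test_that("overflowing count scales are rejected with a config hint", {
  cfg <- simulation_config(seed = 3, e_scale = 1e6)
  expect_error(simulate_panel(cfg), "overflow.*e_scale")
})

test_that("ground truth serializes to a flat CSV", {
  sim <- simulate_panel(simulation_config(seed = 2))
  path <- tempfile(fileext = ".csv")
  write_truth_csv(sim$truth, path)
  tr <- read.csv(path)
  expect_setequal(unique(tr$component),
                  c("beta", "alpha", "lambda", "u", "phi", "v", "hyper"))
  expect_equal(tr$value[tr$component == "lambda"],
               unname(sim$truth$latent$lambda), tolerance = 1e-12)
  unlink(path)
})
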