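test_that("the null predictor is the expected level and shared effects broadcast", {
  spec <- make_tiny_spec()
  eta0 <- assemble_predictor(list(alpha = rep(0, 2)),
                             list(lambda = rep(0, 3)), spec)
  expect_equal(eta0, rep(0, spec$n))
  expect_equal(exp(eta0), rep(1, spec$n))       # theta = 1 everywhere
  # a single nonzero shared spatial effect hits that country's rows exactly,
  # across all diseases and years
  lam <- c(0, 0.3, 0)
  eta <- assemble_predictor(list(), list(lambda = lam), spec)
  ix <- panel_index_map(spec)
  expect_equal(eta, ifelse(ix$i == 2, 0.3, 0))
})

test_that("predictor assembly matches a hand-looped oracle and is linear", {
  g <- make_path_graph(2, c("A", "B"))
  spec <- build_latent_spec(g, 2001:2002, c("d1", "d2"), c("x1"))
  set.seed(5)
  I <- 2; D <- 2; Tn <- 2; n <- 8
  fx <- list(beta = rnorm(1), alpha = rnorm(D), mu = rnorm(1))
  lt <- list(lambda = rnorm(I), u = matrix(rnorm(I * D), I),
             phi = rnorm(Tn), v = matrix(rnorm(Tn * D), Tn),
             psi = rnorm(n))
  X <- matrix(rnorm(n), n, 1)
  eta <- assemble_predictor(fx, lt, spec, X = X)
  # brute-force loop over the canonical (disease, country, year) order
  oracle <- numeric(n); r <- 0
  for (d in 1:D) for (i in 1:I) for (t in 1:Tn) {
    r <- r + 1
    oracle[r] <- fx$mu + fx$alpha[d] + X[r, 1] * fx$beta + lt$lambda[i] +
      lt$u[i, d] + lt$phi[t] + lt$v[t, d] + lt$psi[r]
  }
  expect_equal(eta, oracle, tolerance = 1e-14)
  # linearity: assembling the sum of two states = sum of assembled predictors
  fx2 <- list(beta = rnorm(1), alpha = rnorm(D), mu = rnorm(1))
  lt2 <- list(lambda = rnorm(I), u = matrix(rnorm(I * D), I),
              phi = rnorm(Tn), v = matrix(rnorm(Tn * D), Tn), psi = rnorm(n))
  both_fx <- Map(`+`, fx, fx2)
  both_lt <- Map(`+`, lt, lt2)
  expect_equal(assemble_predictor(both_fx, both_lt, spec, X = X),
               eta + assemble_predictor(fx2, lt2, spec, X = X),
               tolerance = 1e-12)
  # dimension errors name the offending component
  expect_error(assemble_predictor(list(), list(lambda = rnorm(5)), spec),
               "lambda")
})

test_that("Poisson log-likelihood matches the pmf and its gradient matches finite differences", {
  expect_equal(poisson_loglik(0, 1, 0)$total, -1)
  # independent pmf oracle
  expect_equal(poisson_loglik(3, 2, log(1.5))$total, dpois(3, 3, log = TRUE),
               tolerance = 1e-12)
  set.seed(8)
  y <- rpois(25, 12); E <- runif(25, 0.5, 4); eta <- rnorm(25, 0, 0.8)
  ll <- poisson_loglik(y, E, eta)
  expect_equal(ll$total, sum(dpois(y, E * exp(eta), log = TRUE)),
               tolerance = 1e-12)
  expect_equal(ll$rows, dpois(y, E * exp(eta), log = TRUE), tolerance = 1e-12)
  # central finite differences on the gradient
  hstep <- 1e-6
  fd <- vapply(seq_along(eta), function(r) {
    ep <- eta; em <- eta
    ep[r] <- ep[r] + hstep; em[r] <- em[r] - hstep
    (poisson_loglik(y, E, ep)$total - poisson_loglik(y, E, em)$total) /
      (2 * hstep)
  }, numeric(1))
  expect_equal(ll$grad_eta, fd, tolerance = 1e-6)
  # overflow guard: guarded -Inf, not overflow
  expect_identical(poisson_loglik(1, 1, 40)$total, -Inf)
  expect_error(poisson_loglik(1, -1, 0), "positive")
})

test_that("the joint log posterior decomposes additively into its blocks", {
  spec <- make_tiny_spec()
  h <- default_true_hyper()
  lt <- random_latent_state(spec, h, seed = 2)
  set.seed(3)
  fx <- list(beta = rnorm(2, 0, 0.1), alpha = rnorm(2, 0, 0.3), mu = 0.1)
  n <- spec$n
  X <- matrix(rnorm(2 * n), n, 2)
  y <- rpois(n, 20); E <- rep(18, n)
  lp <- log_posterior(fx, lt, h, y, E, spec, X = X)
  expect_equal(lp$total, sum(lp$blocks), tolerance = 1e-12)
  # doubling tau_psi changes only the psi block and the hyperprior block
  h2 <- h; h2["tau_psi"] <- 2 * h["tau_psi"]
  lp2 <- log_posterior(fx, lt, h2, y, E, spec, X = X)
  same <- setdiff(names(lp$blocks), c("psi", "hyper"))
  expect_equal(lp2$blocks[same], lp$blocks[same], tolerance = 1e-12)
  expect_false(isTRUE(all.equal(lp2$blocks[["psi"]], lp$blocks[["psi"]])))
  # the likelihood block is the Poisson log likelihood of the assembled eta
  expect_equal(lp$blocks[["loglik"]], poisson_loglik(y, E, lp$eta)$total)
  # violated sum-to-zero constraints are an error, not a silent projection
  bad <- lt; bad$phi <- bad$phi + 0.5
  expect_error(log_posterior(fx, bad, h, y, E, spec, X = X), "sum-to-zero")
})

test_that("the latent-field gradient matches central finite differences", {
  # 2 countries x 2 years x 2 diseases toy
  g <- make_path_graph(2)
  raw <- make_raw_panel(2, 2, 2)
  panel <- validate_panel(raw)
  model <- build_model(panel, g)
  h <- default_true_hyper()
  set.seed(11)
  z <- rnorm(model$layout$m, 0, 0.2)
  psi <- rnorm(model$spec$n, 0, 0.5)
  obj <- latent_objective(model, h, z, psi)
  hstep <- 1e-5
  fd_z <- vapply(seq_along(z), function(j) {
    zp <- z; zm <- z
    zp[j] <- zp[j] + hstep; zm[j] <- zm[j] - hstep
    (latent_objective(model, h, zp, psi)$value -
       latent_objective(model, h, zm, psi)$value) / (2 * hstep)
  }, numeric(1))
  fd_psi <- vapply(seq_along(psi), function(j) {
    pp <- psi; pm <- psi
    pp[j] <- pp[j] + hstep; pm[j] <- pm[j] - hstep
    (latent_objective(model, h, z, pp)$value -
       latent_objective(model, h, z, pm)$value) / (2 * hstep)
  }, numeric(1))
  scale <- max(1, max(abs(obj$grad_z)), max(abs(obj$grad_psi)))
  expect_lt(max(abs(obj$grad_z - fd_z)) / scale, 1e-6)
  expect_lt(max(abs(obj$grad_psi - fd_psi)) / scale, 1e-6)
})
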