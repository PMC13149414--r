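test_that("DIC reduces to the deviance for a degenerate posterior and matches brute force", {
  dev <- rep(123.4, 150)
  r <- compute_dic(dev, 123.4)
  expect_equal(r$p_d, 0)
  expect_equal(r$dic, 123.4)
  # brute-force recomputation from a stored per-row log-likelihood matrix
  set.seed(12)
  L <- matrix(rnorm(200 * 6, -3, 0.4), 200)
  eta_mean_dev <- -2 * (sum(colMeans(L)) + 0.7)  # any reference deviance
  r2 <- compute_dic(-2 * rowSums(L), eta_mean_dev)
  dbar <- mean(-2 * rowSums(L))
  expect_equal(r2$dic, dbar + (dbar - eta_mean_dev), tolerance = 1e-12)
  expect_error(compute_dic(c(dev, NaN), 1), "non-finite")
})

test_that("DIC effective parameters match the Normal-Normal closed form", {
  # y_i ~ N(theta, s2) with conjugate prior: p_D -> n * v_post / s2
  set.seed(13)
  n <- 40; s2 <- 4; v0 <- 9
  y <- rnorm(n, 1.5, sqrt(s2))
  v_post <- 1 / (n / s2 + 1 / v0)
  m_post <- v_post * sum(y) / s2
  theta <- rnorm(20000, m_post, sqrt(v_post))
  dev <- vapply(theta, function(th) -2 * sum(dnorm(y, th, sqrt(s2), log = TRUE)),
                numeric(1))
  dev_at_mean <- -2 * sum(dnorm(y, m_post, sqrt(s2), log = TRUE))
  r <- compute_dic(dev, dev_at_mean)
  expect_equal(r$p_d, n * v_post / s2, tolerance = 0.05)
})

test_that("WAIC matches a direct-summation oracle and shifts correctly", {
  set.seed(14)
  L <- matrix(rnorm(5 * 400, -2, 0.3), 400, 5)   # 5-row toy, safe exp range
  r <- compute_waic(L)
  lppd_direct <- sum(log(colMeans(exp(L))))
  p_direct <- sum(apply(L, 2, var))
  expect_equal(r$lppd, lppd_direct, tolerance = 1e-10)
  expect_equal(r$p_waic, p_direct, tolerance = 1e-12)
  expect_equal(r$waic, -2 * (lppd_direct - p_direct), tolerance = 1e-8)
  # single draw: no variance term
  r1 <- compute_waic(L[1, , drop = FALSE])
  expect_equal(r1$p_waic, 0)
  expect_equal(r1$waic, -2 * sum(L[1, ]))
  # adding a constant to every draw of one row shifts lppd by that constant
  # and leaves p_WAIC unchanged
  L2 <- L; L2[, 3] <- L2[, 3] + 1.7
  r2 <- compute_waic(L2)
  expect_equal(r2$lppd, r$lppd + 1.7, tolerance = 1e-9)
  expect_equal(r2$p_waic, r$p_waic, tolerance = 1e-12)
})

test_that("CPO is the harmonic mean with closed-form small cases and LOO oracle", {
  # constant likelihood across draws -> CPO equals it exactly
  Lc <- matrix(log(0.37), 300, 2)
  rc <- compute_cpo(Lc)
  expect_equal(rc$cpo, c(0.37, 0.37), tolerance = 1e-12)
  expect_equal(rc$n_failures, 0)
  # two draws {a, b} -> 2ab/(a+b)
  a <- 0.2; b <- 0.6
  r2 <- compute_cpo(matrix(log(c(a, b)), 2, 1))
  expect_equal(r2$cpo, 2 * a * b / (a + b), tolerance = 1e-12)
  # conjugate Poisson-Gamma leave-one-out predictive oracle
  set.seed(15)
  n <- 8; a0 <- 2; b0 <- 1
  y <- rpois(n, 3)
  theta <- rgamma(200000, a0 + sum(y), b0 + n)
  L <- sapply(seq_len(n), function(i) dpois(y[i], theta, log = TRUE))
  r <- compute_cpo(L)
  loo_exact <- vapply(seq_len(n), function(i) {
    sh <- a0 + sum(y[-i]); rt <- b0 + n - 1
    dnbinom(y[i], size = sh, prob = rt / (rt + 1))
  }, numeric(1))
  expect_equal(r$cpo, loo_exact, tolerance = 0.02)
  expect_equal(r$lcpo, sum(log(r$cpo)))
  expect_equal(r$lcpo_mean, mean(log(r$cpo)))
  # a zero-likelihood draw marks the row as a failure
  Lbad <- matrix(rnorm(100, -2, 0.1), 100, 1); Lbad[5] <- -Inf
  expect_gte(compute_cpo(Lbad)$n_failures, 1)
})

test_that("LCPO never exceeds lppd (harmonic vs arithmetic predictive mean)", {
  for (s in 1:5) {
    set.seed(s)
    L <- matrix(rnorm(150 * 10, -3, runif(1, 0.1, 1)), 150)
    expect_lte(compute_cpo(L)$lcpo, compute_waic(L)$lppd + 1e-10)
  }
})

test_that("mid-PIT has the documented boundary and symmetry behavior", {
  mu <- matrix(rep(10, 200), 200, 1)
  expect_gt(compute_pit(60, mu), 0.999999)       # far above the predictive
  expect_lt(compute_pit(0, mu), 0.001)
  # y at the median of a near-symmetric predictive: exact discrete mid-PIT
  expect_equal(compute_pit(10, mu), ppois(9, 10) + 0.5 * dpois(10, 10),
               tolerance = 1e-12)
  expect_equal(compute_pit(10, mu), 0.5, tolerance = 0.05)
  expect_error(compute_pit(3, matrix(numeric(0), 0, 0)), "non-empty")
})

test_that("observed-vs-fitted reproduces the offset under the null model", {
  E <- c(5, 50, 500)
  mu <- matrix(rep(E, each = 300), 300)          # theta = 1 draws
  y <- c(5, 52, 480)
  r <- observed_vs_fitted(y, mu)
  expect_equal(r$table$fitted, E, tolerance = 1e-9)
  expect_true(all(r$table$lo <= r$table$fitted & r$table$fitted <= r$table$hi))
  expect_equal(unname(r$table$lo), qpois(0.025, E))
  expect_equal(unname(r$table$hi), qpois(0.975, E))
  expect_equal(r$coverage, 1)
})

test_that("the full diagnostics report is internally consistent on a fitted model", {
  panel <- validate_panel(make_raw_panel(3, 2, 4))
  model <- build_model(panel, make_path_graph(3))
  post <- sample_hyperparameters(model,
                                 fit_control(n_iter = 450, burnin = 150,
                                             thin = 2, seed = 9))
  dg <- model_diagnostics(post)
  # identities against brute-force recomputation from the stored matrix
  L <- post$loglik
  expect_equal(dg$waic, -2 * (sum(log(colMeans(exp(L)))) -
                                sum(apply(L, 2, var))), tolerance = 1e-6)
  dbar <- mean(-2 * rowSums(L))
  dev_mean <- -2 * poisson_loglik(model$y, model$E, colMeans(post$eta))$total
  expect_equal(dg$dic, 2 * dbar - dev_mean, tolerance = 1e-8)
  expect_lte(dg$lcpo, dg$lppd)
  expect_gte(dg$p_waic, 0)
  expect_true(all(dg$pit >= 0 & dg$pit <= 1))
  expect_equal(nrow(dg$observed_vs_fitted), model$spec$n)
})
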