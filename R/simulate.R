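#' Configuration of the synthetic-panel generator
#'
#' Defaults emulate the study design the model targets: seven East African
#' Community countries on their land-border contiguity graph, four
#' non-communicable-disease groups, twenty years (2000-2019), eight
#' environmental/socioeconomic covariates that are autocorrelated in time
#' (AR(1)) and correlated across neighboring countries, latent effects drawn
#' from the model's own constrained priors, and Poisson counts around
#' expected deaths built from national-scale populations and baseline
#' age-standardized rates.
#'
#' @param I,D,T_len panel dimensions (defaults 7 countries, 4 diseases,
#'   20 years starting at `year0`).
#' @param graph `"eac"` for the default EAC graph (requires I = 7) or a
#'   `country_graph`.
#' @param year0 first year label.
#' @param beta true standardized-scale fixed effects (length 8 by default).
#' @param hyper true hyperparameters, see [hyper_names()].
#' @param ar_coef temporal AR(1) coefficient of the covariates, in (-1, 1).
#' @param spatial_weight neighbor-smoothing weight of the covariate country
#'   means, in [0, 1].
#' @param noise_sd stationary sd of the covariate AR(1) noise around the
#'   country mean (on the standardized latent scale).
#' @param pop_range population range (log-uniform per country), persons.
#' @param rate_range baseline disease-rate range (uniform per disease),
#'   deaths per 100,000.
#' @param e_scale multiplier applied to expected deaths (1 = realistic
#'   national scale; larger values sharpen the likelihood for
#'   law-of-large-numbers checks).
#' @param seed mandatory RNG seed.
#' @return a `simulation_config` list.
#' @export
simulation_config <- function(I = 7L, D = 4L, T_len = 20L, graph = "eac",
                              year0 = 2000L,
                              beta = c(ndvi = 0.10, temperature = -0.05,
                                       precipitation = 0.08, gdp_pc = 0.15,
                                       health_exp = -0.12, urban = -0.10,
                                       pop_density = -0.06, pm25 = 0.05),
                              hyper = c(tau_lambda = 10, tau_u = 25,
                                        tau_phi = 10, tau_v = 25,
                                        tau_psi = 100, tau_alpha = 4,
                                        rho_lambda = 0.6, rho_u = 0.6),
                              ar_coef = 0.8, spatial_weight = 0.5,
                              noise_sd = 0.6,
                              pop_range = c(1e6, 1e8),
                              rate_range = c(20, 300),
                              e_scale = 1, seed = NULL) {
  if (is.null(seed)) stop("a seed is mandatory")
  if (abs(ar_coef) >= 1) stop("AR coefficient must be in (-1, 1)")
  if (identical(graph, "eac")) {
    if (I != 7L) stop("the EAC graph has 7 countries; set I = 7 or pass a graph")
    graph <- build_eac_graph()
  }
  stopifnot(inherits(graph, "country_graph"), length(graph$nodes) == I)
  diseases <- c("Cardiovascular diseases", "Diabetes mellitus",
                "Malignant neoplasms", "Respiratory diseases")
  if (D != 4L) diseases <- paste0("Disease ", LETTERS[seq_len(D)])
  list(I = I, D = D, T_len = as.integer(T_len), graph = graph,
       years = seq.int(year0, length.out = T_len),
       diseases = diseases, beta = beta, hyper = .check_hyper(hyper),
       ar_coef = ar_coef, spatial_weight = spatial_weight,
       noise_sd = noise_sd, pop_range = pop_range, rate_range = rate_range,
       e_scale = e_scale, seed = as.integer(seed))
}

# natural-scale location/spread of each simulated covariate
.covariate_scales <- function() {
  data.frame(
    name = c("ndvi", "temperature", "precipitation", "gdp_pc",
             "health_exp", "urban", "pop_density", "pm25"),
    center = c(0.5, 22, 1100, 900, 40, 25, 90, 30),
    spread = c(0.08, 2.5, 250, 300, 12, 8, 40, 8),
    stringsAsFactors = FALSE)
}

#' Simulate spatially and temporally correlated covariates
#'
#' Each covariate follows, on a latent standardized scale, a stationary
#' AR(1) in time around a country-level mean; country means are iid normals
#' smoothed once over the adjacency graph (weight `spatial_weight` on the
#' neighbor average), which induces the neighbor correlation the spatial
#' model assumes. Values are then shifted/scaled to plausible natural units
#' and emitted unstandardized.
#'
#' @param config a `simulation_config`.
#' @return data.frame: country_id, year, and one column per covariate,
#'   ordered country-major then year.
#' @export
simulate_covariates <- function(config) {
  set.seed(config$seed + 1L)
  g <- config$graph
  I <- config$I; Tn <- config$T_len
  W <- g$W
  deg <- pmax(rowSums(W), 1)
  sc <- .covariate_scales()
  nms <- names(config$beta)
  if (is.null(nms)) nms <- sc$name[seq_along(config$beta)]
  out <- data.frame(
    country_id = rep(g$nodes, each = Tn),
    year = rep(config$years, times = I), stringsAsFactors = FALSE)
  a <- config$ar_coef
  innov_sd <- config$noise_sd * sqrt(1 - a^2)   # stationary sd = noise_sd
  for (j in seq_along(nms)) {
    m0 <- stats::rnorm(I)
    m <- (1 - config$spatial_weight) * m0 +
      config$spatial_weight * drop(W %*% m0) / deg
    x <- matrix(0, I, Tn)
    x[, 1L] <- stats::rnorm(I, 0, config$noise_sd)
    for (t in seq_len(Tn - 1L)) {
      x[, t + 1L] <- a * x[, t] + stats::rnorm(I, 0, innov_sd)
    }
    row <- match(nms[j], sc$name)
    center <- if (is.na(row)) 0 else sc$center[row]
    spread <- if (is.na(row)) 1 else sc$spread[row]
    out[[nms[j]]] <- center + spread * as.vector(t(x + m))
  }
  out
}

#' Simulate a mortality panel from the generative model
#'
#' Draws populations and per-disease baseline rates, builds expected deaths,
#' simulates every latent component from its constrained prior at the true
#' hyperparameters, assembles the log relative risk, and draws Poisson
#' counts. The returned panel passes [validate_panel()] and carries the full
#' ground truth needed to recompute eta exactly.
#'
#' @param config a `simulation_config`.
#' @return list: `panel` (a `mortality_panel`), `truth` (fixed effects,
#'   latent state, hyperparameters, eta, and the standardized design).
#' @export
simulate_panel <- function(config) {
  g <- config$graph
  I <- config$I; D <- config$D; Tn <- config$T_len
  covs <- simulate_covariates(config)
  set.seed(config$seed + 2L)
  spec <- build_latent_spec(g, config$years, config$diseases,
                            names(config$beta))
  h <- config$hyper

  pop <- exp(stats::runif(I, log(config$pop_range[1]), log(config$pop_range[2])))
  names(pop) <- g$nodes
  rate <- stats::runif(D, config$rate_range[1], config$rate_range[2])
  names(rate) <- spec$diseases

  draw_constrained_iid <- function(st) drop(st$vectors %*% stats::rnorm(st$rank))
  lambda_struct <- sample_structure_prior(spec$icar, 1)
  lambda_iid <- draw_constrained_iid(spec$icar)
  lambda <- bym2_combine(h["rho_lambda"], h["tau_lambda"], lambda_struct,
                         lambda_iid)
  u_struct <- u_iid <- u <- matrix(0, I, D)
  v <- matrix(0, Tn, D)
  for (d in seq_len(D)) {
    u_struct[, d] <- sample_structure_prior(spec$icar, 1)
    u_iid[, d] <- draw_constrained_iid(spec$icar)
    u[, d] <- bym2_combine(h["rho_u"], h["tau_u"], u_struct[, d], u_iid[, d])
    v[, d] <- sample_structure_prior(spec$rw1, h["tau_v"])
  }
  phi <- sample_structure_prior(spec$rw1, h["tau_phi"])
  psi <- stats::rnorm(spec$n, 0, 1 / sqrt(h["tau_psi"]))
  alpha <- stats::rnorm(D, 0, 1 / sqrt(h["tau_alpha"]))

  ix <- panel_index_map(spec)
  df <- data.frame(
    country_id = spec$countries[ix$i],
    year = spec$years[ix$t],
    disease = spec$diseases[ix$d],
    population = unname(pop[ix$i]),
    asmr = unname(rate[ix$d]),
    stringsAsFactors = FALSE)
  # covariates vary over (country, year) only
  ckey <- paste(covs$country_id, covs$year)
  rkey <- paste(df$country_id, df$year)
  for (nm in names(config$beta)) df[[nm]] <- covs[[nm]][match(rkey, ckey)]

  # standardized design for the linear predictor (moments over (i, t) cells)
  Xc <- as.matrix(covs[, names(config$beta), drop = FALSE])
  mu_x <- colMeans(Xc); sd_x <- apply(Xc, 2L, stats::sd)
  Xstd <- sweep(sweep(as.matrix(df[, names(config$beta)]), 2L, mu_x), 2L,
                sd_x, `/`)

  fixed <- list(beta = unname(config$beta), alpha = alpha, mu = 0)
  latent <- list(lambda = lambda, lambda_struct = lambda_struct,
                 lambda_iid = lambda_iid, u = u, u_struct = u_struct,
                 u_iid = u_iid, phi = phi, v = v, psi = psi)
  eta <- assemble_predictor(fixed, latent, spec, X = Xstd)
  E <- compute_expected_deaths(df$population, df$asmr) * config$e_scale
  mu_pois <- E * exp(eta)
  if (any(mu_pois > 1e9)) {
    stop("Poisson mean overflow (max ", format(max(mu_pois), digits = 3),
         "); reduce e_scale, pop_range or latent variances in the config")
  }
  df$deaths <- stats::rpois(spec$n, mu_pois)
  df$population <- df$population * config$e_scale
  panel <- validate_panel(df)
  truth <- list(fixed = fixed, latent = latent, hyper = h, eta = eta,
                Xstd = Xstd, spec = spec, config = config)
  list(panel = panel, truth = truth)
}

#' Write a simulated ground truth to CSV
#'
#' Flat (component, index, value) table sufficient to reconstruct eta.
#' @param truth the `truth` element of [simulate_panel()].
#' @param path output CSV path.
#' @export
write_truth_csv <- function(truth, path) {
  spec <- truth$spec
  rows <- rbind(
    data.frame(component = "beta", index = names(truth$config$beta),
               value = truth$fixed$beta),
    data.frame(component = "alpha", index = spec$diseases,
               value = truth$fixed$alpha),
    data.frame(component = "lambda", index = spec$countries,
               value = truth$latent$lambda),
    data.frame(component = "u",
               index = paste(rep(spec$countries, spec$D),
                             rep(spec$diseases, each = spec$I), sep = ":"),
               value = as.vector(truth$latent$u)),
    data.frame(component = "phi", index = as.character(spec$years),
               value = truth$latent$phi),
    data.frame(component = "v",
               index = paste(rep(spec$years, spec$D),
                             rep(spec$diseases, each = spec$T), sep = ":"),
               value = as.vector(truth$latent$v)),
    data.frame(component = "hyper", index = hyper_names(),
               value = unname(truth$hyper[hyper_names()])))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}
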