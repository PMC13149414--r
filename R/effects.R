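#' Extract a posterior effect surface
#'
#' Per-cell posterior mean and central 95 percent interval of a fitted
#' component on its natural (log-risk) scale, or of the relative risk
#' theta = exp(eta) per (country, year, disease) cell.
#'
#' @param posterior a `posterior_result`.
#' @param component one of `"lambda"` (shared spatial), `"u"`
#'   (disease-specific spatial), `"phi"` (shared temporal), `"v"`
#'   (disease-specific temporal), `"psi"` (interaction), `"alpha"`,
#'   `"beta"`, `"eta"`, `"rr"`.
#' @return an `effect_surface` data.frame: index label columns, `mean`,
#'   `lo`, `median`, `hi`.
#' @export
extract_effect <- function(posterior, component) {
  stopifnot(inherits(posterior, "posterior_result"))
  spec <- posterior$model$spec
  ix <- panel_index_map(spec)
  cell_labels <- data.frame(
    country = spec$countries[ix$i], year = spec$years[ix$t],
    disease = spec$diseases[ix$d], stringsAsFactors = FALSE)
  known <- c("lambda", "u", "phi", "v", "psi", "alpha", "beta", "eta", "rr")
  if (!component %in% known) {
    stop("unknown component '", component, "'; available: ",
         paste(known, collapse = ", "))
  }
  draws <- switch(component,
    rr = exp(posterior$eta),
    eta = posterior$eta,
    posterior[[component]])
  labels <- switch(component,
    lambda = data.frame(country = spec$countries, stringsAsFactors = FALSE),
    u = data.frame(country = rep(spec$countries, times = spec$D),
                   disease = rep(spec$diseases, each = spec$I),
                   stringsAsFactors = FALSE),
    phi = data.frame(year = spec$years),
    v = data.frame(year = rep(spec$years, times = spec$D),
                   disease = rep(spec$diseases, each = spec$T),
                   stringsAsFactors = FALSE),
    alpha = data.frame(disease = spec$diseases, stringsAsFactors = FALSE),
    beta = data.frame(covariate = spec$covariates, stringsAsFactors = FALSE),
    cell_labels)
  qs <- t(apply(draws, 2L, stats::quantile, probs = c(0.025, 0.5, 0.975)))
  out <- cbind(labels,
               data.frame(mean = colMeans(draws), lo = qs[, 1L],
                          median = qs[, 2L], hi = qs[, 3L]))
  rownames(out) <- NULL
  structure(out, component = component,
            class = c("effect_surface", "data.frame"))
}

#' Write / read an effect surface CSV
#'
#' Round-trip preserving the index labels, summaries, and component name
#' (stored in a `# component:` header comment line).
#' @param surface an `effect_surface`.
#' @param path file path.
#' @export
write_effect_csv <- function(surface, path) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste0("# component: ", attr(surface, "component")), con)
  utils::write.csv(as.data.frame(surface), con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_effect_csv
#' @export
read_effect_csv <- function(path) {
  first <- readLines(path, n = 1L)
  comp <- sub("^# component: ", "", first)
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  structure(df, component = comp, class = c("effect_surface", "data.frame"))
}

#' Relative-risk surface export
#'
#' CSV with columns country, year, disease, theta_mean, theta_lo2.5,
#' theta_median, theta_hi97.5.
#' @param posterior a `posterior_result`.
#' @param path file path.
#' @export
write_rr_csv <- function(posterior, path) {
  s <- extract_effect(posterior, "rr")
  out <- data.frame(country = s$country, year = s$year, disease = s$disease,
                    theta_mean = s$mean, theta_lo2.5 = s$lo,
                    theta_median = s$median, theta_hi97.5 = s$hi)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
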