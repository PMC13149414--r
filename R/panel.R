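#' Expected deaths from population and age-standardized rate
#'
#' Expected deaths for a country-year-disease cell are the deaths implied by
#' the cell's age-standardized mortality rate applied to its population:
#' \deqn{E = P \times R / 100{,}000} where \eqn{P} is person-years of exposure
#' and \eqn{R} is the age-standardized rate per 100,000. \eqn{E} is the offset
#' against which relative mortality risk is measured (risk 1 = mortality at
#' the standardized expectation).
#'
#' @param population positive numeric vector, person-years \eqn{P}.
#' @param asmr non-negative numeric vector, rate per 100,000 \eqn{R}.
#' @return numeric vector of expected deaths, zero only where the rate is zero.
#' @export
compute_expected_deaths <- function(population, asmr) {
  if (length(population) != length(asmr)) {
    stop("population and asmr must have equal length")
  }
  bad_p <- which(!is.finite(population) | population <= 0)
  if (length(bad_p)) {
    stop("non-positive or non-finite population at row(s): ",
         paste(utils::head(bad_p, 5L), collapse = ", "))
  }
  bad_r <- which(!is.finite(asmr) | asmr < 0)
  if (length(bad_r)) {
    stop("negative or non-finite asmr at row(s): ",
         paste(utils::head(bad_r, 5L), collapse = ", "))
  }
  population * asmr / 1e5
}

#' Core panel column names (everything else is treated as a covariate)
#' @keywords internal
.panel_core_cols <- c("country_id", "year", "disease", "deaths",
                      "population", "asmr", "expected_deaths")

#' Validate a long-format mortality panel
#'
#' Checks that a raw long table is a balanced country x year x disease panel:
#' exactly one row per combination, non-negative integer death counts,
#' positive populations, non-negative rates, and covariates constant across
#' the disease replicates of each (country, year) cell. Rows are sorted into
#' the canonical order (disease-major, then country, then year) on which all
#' latent-vector indexing in the model relies. Expected deaths are computed
#' (or checked) from population and asmr.
#'
#' @param df data.frame with columns country_id, year, disease, deaths,
#'   population, asmr, plus one column per covariate.
#' @return a `mortality_panel`: the canonical-order data.frame with attributes
#'   `countries`, `years`, `diseases`, `covariates`.
#' @export
validate_panel <- function(df) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  need <- c("country_id", "year", "disease", "deaths", "population", "asmr")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("panel is missing column(s): ", paste(miss, collapse = ", "))

  problems <- character(0)
  countries <- sort(unique(as.character(df$country_id)))
  diseases  <- sort(unique(as.character(df$disease)))
  years     <- sort(unique(as.integer(df$year)))
  I <- length(countries); D <- length(diseases); Tn <- length(years)

  if (Tn > 1L && !all(diff(years) == 1L)) {
    problems <- c(problems, "years are not consecutive")
  }

  key <- paste(df$disease, df$country_id, df$year, sep = "\r")
  dup <- unique(key[duplicated(key)])
  if (length(dup)) {
    problems <- c(problems, paste0("duplicate rows for cell(s): ",
      paste(gsub("\r", "/", utils::head(dup, 5L)), collapse = "; ")))
  }
  full <- as.vector(outer(
    as.vector(outer(diseases, countries, paste, sep = "\r")),
    years, paste, sep = "\r"))
  missing_cells <- setdiff(full, key)
  if (length(missing_cells)) {
    problems <- c(problems, paste0("missing (disease/country/year) cell(s): ",
      paste(gsub("\r", "/", utils::head(missing_cells, 5L)), collapse = "; ")))
  }

  if (any(!is.finite(df$deaths) | df$deaths < 0 | df$deaths != round(df$deaths))) {
    bad <- which(!is.finite(df$deaths) | df$deaths < 0 | df$deaths != round(df$deaths))
    problems <- c(problems, paste0("deaths not a non-negative integer at row(s): ",
      paste(utils::head(bad, 5L), collapse = ", ")))
  }
  if (any(!is.finite(df$population) | df$population <= 0)) {
    problems <- c(problems, "non-positive population")
  }
  if (any(!is.finite(df$asmr) | df$asmr < 0)) {
    problems <- c(problems, "negative asmr")
  }

  covs <- setdiff(names(df), .panel_core_cols)
  for (cv in covs) {
    if (!is.numeric(df[[cv]])) {
      problems <- c(problems, paste0("covariate '", cv, "' is not numeric"))
      next
    }
    spread <- tapply(df[[cv]], paste(df$country_id, df$year, sep = "\r"),
                     function(x) diff(range(x)))
    off <- names(spread)[which(spread > 1e-8 * (1 + max(abs(df[[cv]]))))]
    if (length(off)) {
      problems <- c(problems, paste0("covariate '", cv,
        "' differs across diseases within (country, year) cell(s): ",
        paste(gsub("\r", "/", utils::head(off, 3L)), collapse = "; ")))
    }
  }

  if (length(problems)) {
    stop("panel validation failed:\n  - ", paste(problems, collapse = "\n  - "))
  }

  df$country_id <- as.character(df$country_id)
  df$disease <- as.character(df$disease)
  df$year <- as.integer(df$year)
  ord <- order(match(df$disease, diseases), match(df$country_id, countries), df$year)
  df <- df[ord, , drop = FALSE]
  rownames(df) <- NULL

  E <- compute_expected_deaths(df$population, df$asmr)
  if (!is.null(df$expected_deaths)) {
    if (max(abs(df$expected_deaths - E)) > 1e-6 * (1 + max(E))) {
      stop("panel validation failed:\n  - expected_deaths column inconsistent ",
           "with population * asmr / 1e5")
    }
  }
  df$expected_deaths <- E

  structure(df,
            countries = countries, years = years, diseases = diseases,
            covariates = covs,
            class = c("mortality_panel", "data.frame"))
}

#' @export
print.mortality_panel <- function(x, ...) {
  cat(sprintf("mortality_panel: %d countries x %d diseases x %d years = %d rows\n",
              length(attr(x, "countries")), length(attr(x, "diseases")),
              length(attr(x, "years")), nrow(x)))
  cat("covariates:", paste(attr(x, "covariates"), collapse = ", "), "\n")
  print(utils::head(as.data.frame(x)), ...)
  invisible(x)
}

#' Unique (country, year) covariate matrix of a panel
#'
#' Covariates vary over (country, year) only; this extracts the deduplicated
#' I x T cell matrix used for standardization and VIF screening.
#' @param panel a `mortality_panel`.
#' @return list with `cells` (data.frame country_id, year) and `X` (matrix).
#' @export
covariate_cells <- function(panel) {
  stopifnot(inherits(panel, "mortality_panel"))
  covs <- attr(panel, "covariates")
  first_disease <- attr(panel, "diseases")[1L]
  sub <- panel[panel$disease == first_disease, , drop = FALSE]
  X <- as.matrix(as.data.frame(sub)[, covs, drop = FALSE])
  rownames(X) <- NULL
  list(cells = data.frame(country_id = sub$country_id, year = sub$year,
                          stringsAsFactors = FALSE),
       X = X)
}

#' Z-score the panel covariates
#'
#' Centers and scales each covariate to mean 0, sd 1, with moments computed
#' over the unique (country, year) cells (not over the replicated disease
#' rows, which would merely reweight every cell equally anyway for a balanced
#' panel but is conceptually wrong for an unbalanced one). Sample sd
#' (denominator n - 1). Coefficients fitted on the standardized scale can be
#' mapped back with the returned record: beta_raw = beta_std / sd.
#'
#' @param panel a `mortality_panel`.
#' @return list with `panel` (covariates replaced by z-scores) and `record`
#'   (data.frame: covariate, mean, sd).
#' @export
standardize_covariates <- function(panel) {
  stopifnot(inherits(panel, "mortality_panel"))
  covs <- attr(panel, "covariates")
  cc <- covariate_cells(panel)
  mu <- colMeans(cc$X)
  sd_ <- apply(cc$X, 2L, stats::sd)
  zero <- names(sd_)[sd_ <= 0 | !is.finite(sd_)]
  if (length(zero)) {
    stop("zero-variance covariate(s): ", paste(zero, collapse = ", "))
  }
  for (cv in covs) panel[[cv]] <- (panel[[cv]] - mu[[cv]]) / sd_[[cv]]
  record <- data.frame(covariate = covs, mean = unname(mu[covs]),
                       sd = unname(sd_[covs]), stringsAsFactors = FALSE)
  list(panel = panel, record = record)
}

#' Variance inflation factors
#'
#' VIF_j = 1 / (1 - R^2_j), with R^2_j the coefficient of determination from
#' regressing covariate j on all the others (with intercept). Values at or
#' above the threshold are flagged; a perfectly collinear column yields an
#' infinite VIF and a flag, not an error.
#'
#' @param X numeric matrix (rows = unique (country, year) cells), >= 2 columns.
#' @param threshold flag level, default 5 (the conventional screen).
#' @return data.frame: covariate, vif, flagged.
#' @export
compute_vif <- function(X, threshold = 5) {
  X <- as.matrix(X)
  if (ncol(X) < 2L) stop("VIF needs at least 2 covariates")
  if (nrow(X) <= ncol(X)) stop("need more rows than covariates")
  nm <- colnames(X)
  if (is.null(nm)) nm <- paste0("x", seq_len(ncol(X)))
  vif <- vapply(seq_len(ncol(X)), function(j) {
    fit <- stats::lm.fit(cbind(1, X[, -j, drop = FALSE]), X[, j])
    rss <- sum(fit$residuals^2)
    tss <- sum((X[, j] - mean(X[, j]))^2)
    r2 <- 1 - rss / tss
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))
  data.frame(covariate = nm, vif = vif,
             flagged = !is.finite(vif) | vif >= threshold,
             stringsAsFactors = FALSE)
}

#' Read / write the panel CSV schema
#'
#' CSV with header country_id, year, disease, deaths, population, asmr plus
#' one column per covariate; UTF-8, '.' decimal separator.
#' @param path file path.
#' @return `read_panel_csv`: a validated `mortality_panel`.
#' @export
read_panel_csv <- function(path) {
  validate_panel(utils::read.csv(path, stringsAsFactors = FALSE,
                                 fileEncoding = "UTF-8"))
}

#' @rdname read_panel_csv
#' @param panel a `mortality_panel`.
#' @export
write_panel_csv <- function(panel, path) {
  utils::write.csv(as.data.frame(panel), path, row.names = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}
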