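#' Read a per-country richness table
#'
#' Expected header: `country,species,land_area_km2,population,percent_tropical`.
#' Only countries with at least one described species are admitted; rows
#' with zero species are dropped with a message.
#'
#' @param path CSV path.
#' @return a tibble of country records.
#' @export
read_country_table <- function(path) {
  if (!file.exists(path)) stop("country file not found: ", path,
                               call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("country", "species", "land_area_km2", "population",
              "percent_tropical")
  missing_cols <- setdiff(needed, names(raw))
  if (length(missing_cols) > 0L) {
    stop("country header lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  raw <- tibble::as_tibble(raw[, needed])
  drop <- raw$species < 1
  if (any(drop)) {
    message("dropping ", sum(drop),
            " country/ies with no described species")
    raw <- raw[!drop, ]
  }
  if (any(raw$land_area_km2 <= 0)) {
    stop("non-positive land area", call. = FALSE)
  }
  classify_tropical(raw$percent_tropical)  # validates the range
  raw
}

#' Classify a country as tropical or nontropical
#'
#' A country is tropical when at least half of its land area lies between
#' the tropics; the 50% boundary is inclusive.
#'
#' @param percent_tropical percentage of land area in the tropics (0-100);
#'   vectorised.
#' @return `"tropical"` or `"nontropical"` per element.
#' @export
classify_tropical <- function(percent_tropical) {
  if (any(is.na(percent_tropical)) || any(percent_tropical < 0) ||
        any(percent_tropical > 100)) {
    stop("percent_tropical must lie in [0, 100]", call. = FALSE)
  }
  ifelse(percent_tropical >= 50, "tropical", "nontropical")
}

#' Regress country richness on land area or population
#'
#' Ordinary least squares of the number of species described from each
#' country on its land area or human population, optionally within the
#' tropical or nontropical stratum and optionally excluding named
#' outliers (e.g. the population outliers India and China).  Predictors
#' are untransformed by default; `log_predictor = TRUE` uses the natural
#' log.
#'
#' @param dataset a country tibble ([read_country_table()] or
#'   [simulate_geography()]).
#' @param predictor `"land_area"` or `"population"`.
#' @param stratum `"all"`, `"tropical"` or `"nontropical"`.
#' @param exclude country names to drop; every name must be present in
#'   the dataset (misspelled exclusions are an error, never silently
#'   ignored).
#' @param log_predictor regress on `log(predictor)` instead.
#' @param log_response regress `log(species)` instead of raw counts
#'   (log-log fits recover a power-law richness-area relationship as a
#'   straight line).
#' @return a `country_fit` with `slope`, `intercept`, `r_squared`,
#'   `p_value`, `n_points`, `excluded_countries`.
#' @export
richness_regression <- function(dataset,
                                predictor = c("land_area", "population"),
                                stratum = c("all", "tropical",
                                            "nontropical"),
                                exclude = character(),
                                log_predictor = FALSE,
                                log_response = FALSE) {
  predictor <- match.arg(predictor)
  stratum <- match.arg(stratum)
  missing_excl <- setdiff(exclude, dataset$country)
  if (length(missing_excl) > 0L) {
    stop("exclusion(s) not present in the dataset: ",
         paste(missing_excl, collapse = ", "), call. = FALSE)
  }
  dat <- dataset[!dataset$country %in% exclude, ]
  if (stratum != "all") {
    dat <- dat[classify_tropical(dat$percent_tropical) == stratum, ]
  }
  if (nrow(dat) < 3L) stop("fewer than 3 countries after filtering",
                           call. = FALSE)
  x <- if (predictor == "land_area") dat$land_area_km2 else dat$population
  if (log_predictor) x <- log(x)
  if (stats::var(x) == 0) {
    stop("predictor has zero variance; regression undefined", call. = FALSE)
  }
  y <- if (log_response) log(dat$species) else dat$species
  fit <- stats::lm(y ~ x)
  sm <- summary(fit)
  structure(list(predictor = predictor, stratum = stratum,
                 log_predictor = log_predictor,
                 log_response = log_response,
                 slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = sm$r.squared,
                 p_value = sm$coefficients[2, 4],
                 n_points = nrow(dat),
                 excluded_countries = exclude),
            class = "country_fit")
}

#' @export
print.country_fit <- function(x, ...) {
  cat(sprintf("species ~ %s%s [%s]: r^2 = %.4f, p = %.4g, n = %d\n",
              if (x$log_predictor) "log " else "", x$predictor, x$stratum,
              x$r_squared, x$p_value, x$n_points))
  if (length(x$excluded_countries)) {
    cat("  excluded:", paste(x$excluded_countries, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Compare tropical and nontropical description effort
#'
#' Splits the admitted countries at the 50%-tropical-land rule, compares
#' mean per-country richness with a Welch unequal-variance two-sample
#' t-test, and reports each stratum's species total, land-area total and
#' species described per square kilometre.
#'
#' @param dataset a country tibble.
#' @return a `tropical_comparison`: `summary` tibble (one row per
#'   stratum: `n_countries`, `species_total`, `mean_species`,
#'   `land_area_total`, `species_per_km2`) plus Welch `t`, `df`,
#'   `p_value`.
#' @export
tropical_comparison <- function(dataset) {
  stratum <- classify_tropical(dataset$percent_tropical)
  if (length(unique(stratum)) < 2L) {
    stop("both tropical and nontropical strata must be non-empty",
         call. = FALSE)
  }
  levs <- c("tropical", "nontropical")
  summ <- do.call(rbind, lapply(levs, function(s) {
    d <- dataset[stratum == s, ]
    tibble::tibble(stratum = s, n_countries = nrow(d),
                   species_total = sum(d$species),
                   mean_species = mean(d$species),
                   land_area_total = sum(d$land_area_km2),
                   species_per_km2 = sum(d$species) / sum(d$land_area_km2))
  }))
  tt <- stats::t.test(dataset$species[stratum == "tropical"],
                      dataset$species[stratum == "nontropical"],
                      var.equal = FALSE)
  structure(list(summary = summ, t = unname(tt$statistic),
                 df = unname(tt$parameter), p_value = tt$p.value),
            class = "tropical_comparison")
}

#' @export
print.tropical_comparison <- function(x, ...) {
  print(x$summary)
  cat(sprintf("Welch t = %.4f, df = %.1f, p = %.4f\n", x$t, x$df,
              x$p_value))
  invisible(x)
}
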