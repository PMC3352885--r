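#' Seeded generators for synthetic catalogs, histories and country tables
#'
#' The generators in this file produce data with the statistical structure
#' the analysis modules assume — strongly imbalanced species-to-genus
#' allocation, sigmoid discovery histories with era-varying effort, and
#' country richness scaling with log land area plus a tropical effect — so
#' that every stage of the pipeline can be exercised with known truth.
#' All are bit-reproducible given their config and seed.
#'
#' @name synthetic
NULL

# Two-parameter (concentration + discount) preferential allocation: item i
# joins an existing block of size n_k with weight n_k - discount, or opens
# a new block with weight concentration + discount * k.  The discount
# fattens the tail: it yields many tiny blocks alongside a few huge ones,
# which a single-parameter scheme cannot do while holding the mean block
# size moderate.
preferential_allocation <- function(n, concentration, discount) {
  stopifnot(n >= 1, concentration > 0, discount >= 0, discount < 1)
  z <- integer(n)
  counts <- numeric(n)
  k <- 0L
  for (i in seq_len(n)) {
    if (k == 0L) {
      k <- 1L
      counts[1L] <- 1
      z[i] <- 1L
      next
    }
    w_new <- concentration + discount * k
    j <- sample.int(k + 1L, 1L,
                    prob = c(counts[seq_len(k)] - discount, w_new))
    if (j > k) {
      k <- k + 1L
      counts[k] <- 1
    } else {
      counts[j] <- counts[j] + 1
    }
    z[i] <- j
  }
  z
}

#' Simulate a Linnean catalog with imbalanced allocation
#'
#' Species are allocated to genera, genera to families and families to
#' orders by a seeded two-parameter preferential-allocation scheme (see
#' the concentration/discount weights in the package vignette).  The
#' default species-to-genus parameters (concentration 5, discount 0.6)
#' reproduce the hallmark of piecemeal invertebrate taxonomy: roughly
#' two-thirds of genera end up with one or two species.
#'
#' @param n_species total species to generate.
#' @param genus_concentration,genus_discount allocation parameters for
#'   species into genera.
#' @param family_concentration,family_discount for genera into families.
#' @param order_concentration,order_discount for families into orders.
#' @param prob_unplaced fraction of species left without a family
#'   assignment (to exercise placeholder handling).
#' @param year_midpoint,year_scale logistic location/scale of description
#'   years, truncated to `year_range`.
#' @param year_range inclusive span of description years.
#' @param n_countries_pool size of the country-code pool sampled for each
#'   species (0-3 codes per species).
#' @param seed integer seed.
#' @return a [taxo_catalog()] with attribute `allocation`: realised
#'   `fraction_small_genera` and `species_per_genus`.
#' @export
simulate_classification <- function(n_species,
                                    genus_concentration = 5,
                                    genus_discount = 0.6,
                                    family_concentration = 3,
                                    family_discount = 0.45,
                                    order_concentration = 1,
                                    order_discount = 0.25,
                                    prob_unplaced = 0,
                                    year_midpoint = 1900,
                                    year_scale = 30,
                                    year_range = c(1758, 2007),
                                    n_countries_pool = 30,
                                    seed = 1) {
  stopifnot(n_species >= 1)
  withr::with_seed(seed, {
    genus_of <- preferential_allocation(n_species, genus_concentration,
                                        genus_discount)
    n_gen <- max(genus_of)
    family_of_genus <- preferential_allocation(n_gen, family_concentration,
                                               family_discount)
    n_fam <- max(family_of_genus)
    order_of_family <- preferential_allocation(n_fam, order_concentration,
                                               order_discount)
    fam <- family_of_genus[genus_of]
    ord <- order_of_family[fam]
    years <- pmin(pmax(floor(stats::rlogis(n_species, year_midpoint,
                                           year_scale)),
                       year_range[1]), year_range[2])
    pool <- sprintf("C%02d", seq_len(n_countries_pool))
    countries <- lapply(stats::rpois(n_species, 1.2), function(k) {
      sort(sample(pool, min(k, n_countries_pool)))
    })
    family_names <- sprintf("Family%04d", fam)
    if (prob_unplaced > 0) {
      family_names[stats::runif(n_species) < prob_unplaced] <- ""
    }
    records <- tibble::tibble(
      order = sprintf("Order%02d", ord),
      family = family_names,
      genus = sprintf("Genus%04d", genus_of),
      species = sprintf("sp%05d", seq_len(n_species)),
      year = years,
      countries = countries)
  })
  out <- taxo_catalog(records, class_name = "Simulata",
                      source = sprintf("simulate_classification(seed=%d)",
                                       seed))
  per_genus <- table(out$genus)
  attr(out, "allocation") <- list(
    fraction_small_genera = mean(per_genus <= 2L),
    species_per_genus = n_species / length(per_genus))
  out
}

#' Simulate a species-description history with known truth
#'
#' Each of `n_true` species receives a latent description year drawn from
#' a logistic distribution (midpoint `midpoint`, scale `scale`).  A
#' species whose latent year falls inside `years` is described with
#' probability equal to the era's effort factor (the thinning); dropped
#' or out-of-range species remain latent.  The true total is returned
#' alongside the series so estimator error is exact, not approximate.
#'
#' @param n_true true total species richness.
#' @param midpoint,scale logistic discovery-curve parameters (years).
#' @param years inclusive observation span.
#' @param effort `NULL` (constant effort 1), a function `year -> factor`,
#'   or a data frame with columns `start`, `end`, `factor` (factors in
#'   `[0, 1]`; unlisted years get effort 1).
#' @param seed integer seed.
#' @return a list: `series` (a `description_series`) and `truth`
#'   (`n_true`, `n_described`, `n_latent`, `midpoint`, `scale`).
#' @export
simulate_description_history <- function(n_true, midpoint, scale,
                                         years = c(1758, 2007),
                                         effort = NULL, seed = 1) {
  stopifnot(n_true >= 1, scale > 0, years[1] <= years[2])
  effort_fn <- make_effort_fn(effort)
  described_years <- withr::with_seed(seed, {
    latent <- floor(stats::rlogis(n_true, midpoint, scale))
    in_range <- latent >= years[1] & latent <= years[2]
    eff <- numeric(n_true)
    eff[in_range] <- effort_fn(latent[in_range])
    if (any(eff < 0 | eff > 1)) stop("effort factors must lie in [0, 1]",
                                     call. = FALSE)
    keep <- in_range & stats::runif(n_true) < eff
    latent[keep]
  })
  series <- new_description_series(tabulate_years(described_years,
                                                  years[1], years[2]))
  list(series = series,
       truth = list(n_true = n_true, n_described = length(described_years),
                    n_latent = n_true - length(described_years),
                    midpoint = midpoint, scale = scale))
}

make_effort_fn <- function(effort) {
  if (is.null(effort)) return(function(year) rep(1, length(year)))
  if (is.function(effort)) return(effort)
  stopifnot(is.data.frame(effort),
            all(c("start", "end", "factor") %in% names(effort)))
  function(year) {
    out <- rep(1, length(year))
    for (i in seq_len(nrow(effort))) {
      hit <- year >= effort$start[i] & year <= effort$end[i]
      out[hit] <- effort$factor[i]
    }
    out
  }
}

#' Simulate a per-country richness table
#'
#' Land areas and populations are log-normal; expected richness follows a
#' log link on log land area plus a tropical effect and (optionally)
#' log-normal noise.  Counts are Poisson draws around that expectation by
#' default; `count_model = "deterministic"` rounds the expectation
#' instead, which makes richness an exact monotone function of area when
#' the noise and tropical effect are switched off.  Countries with zero
#' species are dropped, matching the admission rule of the analysis.
#'
#' @param n_countries countries to draw (before the zero-species drop).
#' @param log_area_mean,log_area_sd log-normal parameters of land area
#'   (km2).
#' @param log_pop_mean,log_pop_sd log-normal parameters of population.
#' @param p_tropical probability a country is tropical.
#' @param intercept,log_area_slope,tropical_effect,noise_sd richness
#'   model coefficients on the log scale.
#' @param count_model `"poisson"` or `"deterministic"`.
#' @param seed integer seed.
#' @return a country tibble in the [read_country_table()] layout.
#' @export
simulate_geography <- function(n_countries = 60,
                               log_area_mean = 11.5, log_area_sd = 1.6,
                               log_pop_mean = 15.5, log_pop_sd = 1.8,
                               p_tropical = 0.45,
                               intercept = -1.5, log_area_slope = 0.5,
                               tropical_effect = 0.5, noise_sd = 0.6,
                               count_model = c("poisson", "deterministic"),
                               seed = 1) {
  stopifnot(n_countries >= 2, log_area_sd >= 0, noise_sd >= 0)
  count_model <- match.arg(count_model)
  withr::with_seed(seed, {
    area <- exp(stats::rnorm(n_countries, log_area_mean, log_area_sd))
    pop <- exp(stats::rnorm(n_countries, log_pop_mean, log_pop_sd))
    tropical <- stats::runif(n_countries) < p_tropical
    pct <- ifelse(tropical, stats::runif(n_countries, 50, 100),
                  stats::runif(n_countries, 0, 50))
    eta <- intercept + log_area_slope * log(area) +
      tropical_effect * tropical +
      if (noise_sd > 0) stats::rnorm(n_countries, 0, noise_sd) else 0
    lambda <- exp(eta)
    species <- if (count_model == "poisson") stats::rpois(n_countries,
                                                          lambda)
    else round(lambda)
  })
  out <- tibble::tibble(country = sprintf("Country%03d",
                                          seq_len(n_countries)),
                        species = as.numeric(species),
                        land_area_km2 = area, population = pop,
                        percent_tropical = pct)
  out[out$species >= 1, ]
}

#' Write a deterministic bundle of small test fixtures
#'
#' Generates a catalog, a description history and a country table with
#' one seed, writes them as CSV in the dialects of the consuming readers,
#' and records the generator truth as JSON.  The same seed always yields
#' byte-identical files.
#'
#' @param seed integer seed.
#' @param dir output directory (created if needed).
#' @return a list: `paths` (catalog/series/countries/truth), plus the
#'   in-memory `catalog`, `history` (series + truth) and `countries`.
#' @export
make_fixture_suite <- function(seed = 1, dir = tempfile("fixtures")) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  catalog <- simulate_classification(250, prob_unplaced = 0.1,
                                     seed = seed + 101L)
  history <- simulate_description_history(
    2000, midpoint = 1920, scale = 25, years = c(1758, 2007),
    effort = data.frame(start = 1914, end = 1918, factor = 0.2),
    seed = seed + 202L)
  countries <- simulate_geography(40, seed = seed + 303L)
  paths <- list(catalog = file.path(dir, "catalog.csv"),
                series = file.path(dir, "series.csv"),
                countries = file.path(dir, "countries.csv"),
                truth = file.path(dir, "truth.json"))
  write_catalog(catalog, paths$catalog)
  write_description_series(history$series, paths$series)
  utils::write.csv(countries, paths$countries, row.names = FALSE,
                   quote = FALSE)
  truth <- list(seed = seed,
                catalog = attr(catalog, "allocation"),
                history = history$truth,
                countries = list(n_countries = nrow(countries)))
  jsonlite::write_json(truth, paths$truth, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  list(paths = paths, catalog = catalog, history = history,
       countries = countries)
}
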