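#' Pipeline runners with file outputs
#'
#' `run_distinctness()`, `run_richness()` and `run_geography()` wrap the
#' corresponding analysis stages behind a uniform interface: read an
#' input file, run the stage, and write plain-text TSV/JSON results plus
#' a `manifest.json` recording the input path, every parameter and the
#' seed, so any run can be reproduced exactly from its output directory.
#'
#' @name runners
NULL

write_manifest <- function(out_dir, stage, input, params, outputs) {
  manifest <- list(stage = stage,
                   input = normalizePath(input, mustWork = FALSE),
                   params = params, outputs = outputs,
                   package_version = as.character(
                     utils::packageVersion("taxocat")))
  path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  path
}

fit_to_list <- function(fit) {
  fit$model <- NULL
  unclass(fit)
}

#' @rdname runners
#' @param input path to a catalog CSV (`input_type = "catalog"`) or a
#'   pre-aggregated groups CSV `group,s,delta_plus`
#'   (`input_type = "groups"`).
#' @param out_dir output directory, created if needed.
#' @param input_type how to interpret `input`.
#' @param min_species smallest group admitted to the regression.
#' @param max_path distinctness scale maximum.
#' @param overlay_input optional second groups CSV overlaid on the fit
#'   without refitting.
#' @param on_tolerance "on the line" band for overlay signs.
#' @return (invisibly) a list of result objects and output paths.
#' @export
run_distinctness <- function(input, out_dir,
                             input_type = c("catalog", "groups"),
                             min_species = 4, max_path = 100,
                             overlay_input = NULL, on_tolerance = 0.5) {
  input_type <- match.arg(input_type)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (input_type == "catalog") {
    catalog <- assign_placeholders(read_catalog(input))
    tree <- build_classification_tree(catalog, max_path = max_path)
    results <- distinctness_table(tree)
  } else {
    results <- read_distinctness_groups(input)
  }
  fit <- distinctness_regression(results, min_species = min_species)
  tsv <- file.path(out_dir, "distinctness.tsv")
  utils::write.table(results, tsv, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  fit_json <- file.path(out_dir, "fit.json")
  jsonlite::write_json(fit_to_list(fit), fit_json, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  outputs <- list(distinctness = tsv, fit = fit_json)
  overlay <- NULL
  if (!is.null(overlay_input)) {
    extra <- read_distinctness_groups(overlay_input)
    overlay <- overlay_groups(fit, extra[extra$s >= 2, ],
                              on_tolerance = on_tolerance)
    outputs$overlay <- file.path(out_dir, "overlay.tsv")
    utils::write.table(overlay, outputs$overlay, sep = "\t",
                       row.names = FALSE, quote = FALSE)
  }
  write_manifest(out_dir, "distinctness", input,
                 list(input_type = input_type, min_species = min_species,
                      max_path = max_path, on_tolerance = on_tolerance),
                 outputs)
  invisible(list(results = results, fit = fit, overlay = overlay,
                 outputs = outputs))
}

#' @rdname runners
#' @param method richness estimator to run.
#' @param start_year productivity fitting-window start (`"auto"` or a
#'   calendar year).
#' @param n_boot bootstrap replicates (productivity method).
#' @param horizon_year forecast horizon(s) (bayes method).
#' @param config an [nhpp_config()] (bayes method).
#' @param ref_global,ref_region,target_region counts for the ratio
#'   method.
#' @param seed integer seed for every stochastic step.
#' @export
run_richness <- function(input, out_dir,
                         method = c("productivity", "bayes", "ratio"),
                         start_year = "auto", n_boot = 2000,
                         horizon_year = c(2050, 2100),
                         config = nhpp_config(),
                         ref_global = NULL, ref_region = NULL,
                         target_region = NULL, seed = 1) {
  method <- match.arg(method)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  series <- if (method != "ratio") read_description_series(input)
  result <- switch(method,
    productivity = estimate_richness_productivity(
      series, start_year = start_year, n_boot = n_boot, seed = seed),
    bayes = {
      posterior <- fit_nhpp_bayes(series, config = config, seed = seed)
      fc <- forecast_descriptions(posterior, horizon_year, seed = seed)
      if (inherits(fc, "richness_estimate")) fc <- list(fc)
      list(posterior = posterior, forecasts = fc)
    },
    ratio = extrapolate_from_reference(ref_global, ref_region,
                                       target_region))
  est_json <- file.path(out_dir, "estimate.json")
  payload <- if (method == "bayes") {
    list(no_finite_estimate = result$posterior$no_finite_estimate,
         rhat = as.list(result$posterior$rhat),
         forecasts = lapply(result$forecasts, unclass))
  } else {
    unclass(result)
  }
  jsonlite::write_json(payload, est_json, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  outputs <- list(estimate = est_json)
  if (method == "bayes") {
    outputs$trace <- file.path(out_dir, "trace.csv")
    utils::write.csv(result$posterior$draws, outputs$trace,
                     row.names = FALSE, quote = FALSE)
  }
  write_manifest(out_dir, paste0("richness_", method),
                 if (method == "ratio") "(counts)" else input,
                 list(method = method, start_year = start_year,
                      n_boot = n_boot, horizon_year = horizon_year,
                      seed = seed),
                 outputs)
  invisible(list(result = result, outputs = outputs))
}

#' @rdname runners
#' @param exclude country names excluded from the regressions (each must
#'   exist in the table).
#' @export
run_geography <- function(input, out_dir, exclude = character()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  countries <- read_country_table(input)
  missing_excl <- setdiff(exclude, countries$country)
  if (length(missing_excl) > 0L) {
    stop("exclusion(s) not present in the dataset: ",
         paste(missing_excl, collapse = ", "), call. = FALSE)
  }
  fits <- list()
  for (pred in c("land_area", "population")) {
    for (strat in c("all", "tropical", "nontropical")) {
      key <- paste(pred, strat, sep = "_")
      fits[[key]] <- tryCatch(
        fit_to_list(richness_regression(countries, predictor = pred,
                                        stratum = strat)),
        error = function(e) list(error = conditionMessage(e)))
      if (length(exclude)) {
        fits[[paste0(key, "_excl")]] <- tryCatch(
          fit_to_list(richness_regression(countries, predictor = pred,
                                          stratum = strat,
                                          exclude = exclude)),
          error = function(e) list(error = conditionMessage(e)))
      }
    }
  }
  comparison <- tropical_comparison(countries)
  tsv <- file.path(out_dir, "tropical_comparison.tsv")
  utils::write.table(comparison$summary, tsv, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  fits_json <- file.path(out_dir, "fits.json")
  jsonlite::write_json(
    c(fits, list(welch = list(t = comparison$t, df = comparison$df,
                              p_value = comparison$p_value))),
    fits_json, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  outputs <- list(comparison = tsv, fits = fits_json)
  write_manifest(out_dir, "geography", input,
                 list(exclude = exclude, n_excluded = length(exclude)),
                 outputs)
  invisible(list(fits = fits, comparison = comparison, outputs = outputs))
}
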