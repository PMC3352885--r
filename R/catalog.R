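#' Construct a taxonomic catalog
#'
#' A taxonomic catalog holds one row per nominal species with its Linnean
#' placement (order, family, genus, species epithet), the year in which it
#' was described, and the countries from which it has been recorded.  Only
#' the four classical ranks below the class are kept; finer ranks
#' (subgenera, tribes, subfamilies, ...) are deliberately unsupported
#' because their use is too inconsistent across groups to carry signal.
#'
#' @param records data frame with columns `order`, `family`, `genus`,
#'   `species`, `year` and `countries` (a character vector of
#'   `;`-separated codes, or a list column of character vectors).
#' @param class_name name of the class the catalog covers.
#' @param source free-text provenance note stored in the catalog metadata.
#' @return A `taxo_catalog`: a tibble with one row per species and
#'   attributes `class_name` and `metadata` (source and realised year span).
#' @examples
#' cat <- taxo_catalog(data.frame(
#'   order = "Julida", family = "Julidae", genus = "Julus",
#'   species = c("scandinavius", "terrestris"), year = c(1798, 1758),
#'   countries = c("SE;NO", "GB")))
#' summarize_ranks(cat)
#' @export
taxo_catalog <- function(records, class_name = "Diplopoda", source = "in-memory") {
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  needed <- c("order", "family", "genus", "species", "year", "countries")
  missing_cols <- setdiff(needed, names(records))
  if ("year" %in% missing_cols) records$year <- NA_integer_
  if ("countries" %in% missing_cols) records$countries <- list(character())
  missing_cols <- setdiff(c("order", "family", "genus", "species"), names(records))
  if (length(missing_cols) > 0L) {
    stop("catalog records lack required columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (!is.list(records$countries)) {
    records$countries <- strsplit(ifelse(is.na(records$countries), "",
                                         as.character(records$countries)), ";",
                                  fixed = TRUE)
  }
  records$countries <- lapply(records$countries,
                              function(x) x[nzchar(trimws(x))])
  for (col in c("order", "family", "genus", "species")) {
    records[[col]] <- trimws(as.character(records[[col]]))
    records[[col]][is.na(records[[col]])] <- ""
  }
  records$year <- suppressWarnings(as.integer(records$year))
  out <- tibble::as_tibble(records[, needed])
  validate_catalog(out)
  yrs <- out$year[!is.na(out$year)]
  structure(out,
            class = c("taxo_catalog", class(out)),
            class_name = class_name,
            metadata = list(source = source,
                            year_span = if (length(yrs)) range(yrs) else NULL))
}

validate_catalog <- function(records) {
  bad <- which(!nzchar(records$genus) | !nzchar(records$species) |
                 !nzchar(records$order))
  if (length(bad) > 0L) {
    stop("invalid catalog record(s) at row ", paste(bad, collapse = ", "),
         ": order, genus and species epithet must be non-empty", call. = FALSE)
  }
  early <- which(!is.na(records$year) & records$year < 1758)
  if (length(early) > 0L) {
    stop("description year precedes 1758 at row ",
         paste(early, collapse = ", "), call. = FALSE)
  }
  path <- paste(records$order, records$family, records$genus, records$species)
  dup <- unique(path[duplicated(path)])
  if (length(dup) > 0L) {
    stop("duplicate species path(s): ", paste(dup, collapse = "; "),
         call. = FALSE)
  }
  invisible(records)
}

#' @export
print.taxo_catalog <- function(x, ...) {
  cat("<taxo_catalog> class ", attr(x, "class_name"), ": ",
      nrow(x), " species, ", length(unique(x$genus)), " genera, ",
      length(unique(x$order)), " orders\n", sep = "")
  NextMethod()
}

# Columns accepted in a catalog CSV.  Any finer Linnean rank in the header is
# rejected rather than silently dropped.
.catalog_cols <- c("class", "order", "family", "genus", "species", "year",
                   "countries")
.subrank_cols <- c("subclass", "superorder", "suborder", "superfamily",
                   "subfamily", "tribe", "subtribe", "subgenus", "subspecies")

#' Read a taxonomic catalog from CSV
#'
#' The expected header is `class,order,family,genus,species,year,countries`.
#' An empty `family` field marks a species not yet assigned to a family
#' (see [assign_placeholders()]); `countries` is a `;`-separated list and
#' may be empty; `year` may be empty for species whose description date is
#' unknown.  Rows with an empty genus or epithet, duplicate species paths,
#' and headers containing sub-rank columns are all rejected with an
#' informative error.
#'
#' @param path path to a UTF-8 CSV file.
#' @param countries_sep delimiter inside the `countries` field.
#' @return a [taxo_catalog()].
#' @export
read_catalog <- function(path, countries_sep = ";") {
  if (!file.exists(path)) stop("catalog file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, colClasses = "character", check.names = FALSE,
                         na.strings = character(), fileEncoding = "UTF-8")
  hdr <- tolower(names(raw))
  subs <- intersect(hdr, .subrank_cols)
  if (length(subs) > 0L) {
    stop("catalog header contains unsupported sub-rank column(s): ",
         paste(subs, collapse = ", "),
         " (only class/order/family/genus/species are analysed)",
         call. = FALSE)
  }
  missing_cols <- setdiff(c("order", "family", "genus", "species"), hdr)
  if (length(missing_cols) > 0L) {
    stop("catalog header lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  names(raw) <- hdr
  cl <- if ("class" %in% hdr && nrow(raw) > 0L) raw$class[1] else "unknown"
  if (!"year" %in% hdr) raw$year <- ""
  if (!"countries" %in% hdr) raw$countries <- ""
  raw$countries <- gsub(countries_sep, ";", raw$countries, fixed = TRUE)
  bad <- which(!nzchar(trimws(raw$genus)) | !nzchar(trimws(raw$species)) |
                 !nzchar(trimws(raw$order)))
  if (length(bad) > 0L) {
    # +1 for the header line so the message points at the file line
    stop("malformed catalog row at line ", paste(bad + 1L, collapse = ", "),
         " of ", path, ": empty order, genus or species field", call. = FALSE)
  }
  raw$year[!nzchar(trimws(raw$year))] <- NA
  taxo_catalog(raw[, c("order", "family", "genus", "species", "year",
                       "countries")],
               class_name = cl, source = path)
}

#' Write a taxonomic catalog to CSV
#'
#' Inverse of [read_catalog()]: the written file round-trips to an
#' identical catalog.
#'
#' @param catalog a [taxo_catalog()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_catalog <- function(catalog, path) {
  stopifnot(inherits(catalog, "taxo_catalog"))
  out <- data.frame(class = attr(catalog, "class_name"),
                    order = catalog$order, family = catalog$family,
                    genus = catalog$genus, species = catalog$species,
                    year = ifelse(is.na(catalog$year), "",
                                  as.character(catalog$year)),
                    countries = vapply(catalog$countries, paste,
                                       character(1), collapse = ";"))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Assign placeholder families to unplaced species
#'
#' Species not currently assigned to any described family are collected in
#' a single artificial (incertae sedis) family per order, named
#' `INCERTAE_SEDIS_<ORDER>`.  Pooling all of an order's unplaced species
#' into one family deliberately deflates between-species distances: the
#' alternative (one pseudo-family per species) would inflate the number of
#' higher taxa with units that carry no information.
#'
#' @param catalog a [taxo_catalog()].
#' @return the catalog with every `family` field non-empty.
#' @export
assign_placeholders <- function(catalog) {
  stopifnot(inherits(catalog, "taxo_catalog"))
  unplaced <- !nzchar(catalog$family)
  if (any(unplaced)) {
    catalog$family[unplaced] <-
      paste0("INCERTAE_SEDIS_", toupper(catalog$order[unplaced]))
  }
  catalog
}

#' Summarise taxon counts and allocation ratios
#'
#' Counts the distinct names at each rank and the species-to-genus and
#' species-to-family ratios, together with the fraction of genera holding
#' at most two species — the signature of piecemeal single-species
#' taxonomy.  Placeholder families count as families.
#'
#' @param catalog a [taxo_catalog()].
#' @return a list of class `rank_summary` with elements `n_species`,
#'   `n_genera`, `n_families`, `n_orders`, `species_per_genus`,
#'   `species_per_family` and `fraction_small_genera`.  Ratios are exact;
#'   use `print()` for the conventional 2-decimal display.
#' @export
summarize_ranks <- function(catalog) {
  stopifnot(inherits(catalog, "taxo_catalog"))
  if (nrow(catalog) == 0L) stop("catalog is empty", call. = FALSE)
  per_genus <- table(catalog$genus)
  out <- list(n_species = nrow(catalog),
              n_genera = length(unique(catalog$genus)),
              n_families = length(unique(catalog$family[nzchar(catalog$family)])),
              n_orders = length(unique(catalog$order)))
  out$species_per_genus <- out$n_species / out$n_genera
  out$species_per_family <- if (out$n_families > 0)
    out$n_species / out$n_families else NA_real_
  out$fraction_small_genera <- mean(per_genus <= 2L)
  structure(out, class = "rank_summary")
}

#' @export
print.rank_summary <- function(x, ...) {
  cat(sprintf(paste0("Rank summary: %d species | %d genera | %d families",
                     " | %d orders\n"),
              x$n_species, x$n_genera, x$n_families, x$n_orders))
  cat(sprintf("  species/genus %.2f, species/family %.2f\n",
              x$species_per_genus, x$species_per_family))
  cat(sprintf("  %.0f%% of genera hold <= 2 species\n",
              100 * x$fraction_small_genera))
  invisible(x)
}

#' Yearly species-description counts
#'
#' Tabulates new descriptions per calendar year over a closed span,
#' including explicit zero years.  Records without a description year are
#' excluded and their number is reported as an attribute; they remain
#' usable for distinctness analysis, which does not need dates.
#'
#' @param catalog a [taxo_catalog()].
#' @param start_year,end_year inclusive year span; defaults to the
#'   catalog's own span.
#' @return a `description_series` tibble with columns `year`, `count` and
#'   `cumulative`, and attribute `n_missing_year`.
#' @export
description_series <- function(catalog, start_year = NULL, end_year = NULL) {
  stopifnot(inherits(catalog, "taxo_catalog"))
  yrs <- catalog$year
  n_missing <- sum(is.na(yrs))
  yrs <- yrs[!is.na(yrs)]
  if (is.null(start_year)) start_year <- if (length(yrs)) min(yrs) else 1758L
  if (is.null(end_year)) end_year <- if (length(yrs)) max(yrs) else start_year
  if (start_year > end_year) stop("start_year must not exceed end_year",
                                  call. = FALSE)
  new_description_series(
    tabulate_years(yrs, start_year, end_year),
    n_missing_year = n_missing)
}

tabulate_years <- function(years, start_year, end_year) {
  grid <- seq.int(start_year, end_year)
  counts <- as.integer(table(factor(years[years >= start_year &
                                            years <= end_year],
                                    levels = grid)))
  tibble::tibble(year = grid, count = counts)
}

new_description_series <- function(df, n_missing_year = 0L) {
  stopifnot(all(c("year", "count") %in% names(df)))
  if (any(df$count < 0)) stop("negative description count", call. = FALSE)
  if (any(diff(df$year) != 1L)) stop("years must be consecutive",
                                     call. = FALSE)
  df$cumulative <- cumsum(df$count)
  structure(tibble::as_tibble(df[, c("year", "count", "cumulative")]),
            class = c("description_series", class(tibble::tibble())),
            n_missing_year = n_missing_year)
}

#' Read a description series from CSV (`year,count`)
#'
#' @param path CSV with header `year,count`; years need not be consecutive
#'   (gaps are filled with zeros).
#' @return a `description_series` tibble (`year`, `count`, `cumulative`).
#' @export
read_description_series <- function(path) {
  if (!file.exists(path)) stop("series file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path)
  if (!all(c("year", "count") %in% names(raw))) {
    stop("series header must name `year` and `count` columns", call. = FALSE)
  }
  full <- tabulate_years(rep(raw$year, raw$count), min(raw$year),
                         max(raw$year))
  new_description_series(full)
}

#' @rdname read_description_series
#' @param series a `description_series`.
#' @export
write_description_series <- function(series, path) {
  utils::write.csv(series[, c("year", "count")], path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}
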