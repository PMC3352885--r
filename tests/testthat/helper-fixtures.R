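# Small in-code fixtures and independent oracles shared across tests.

toy_catalog <- function(orders, families, genera, epithets, years = 1900,
                        countries = "") {
  taxo_catalog(data.frame(order = orders, family = families,
                          genus = genera, species = epithets,
                          year = years, countries = countries))
}

# 3 species, 2 genera, 1 family, 1 order
small_catalog <- function() {
  toy_catalog("Ord1", "Fam1", c("Gen1", "Gen1", "Gen2"),
              c("alpha", "beta", "gamma"))
}

groups_csv_path <- function() {
  system.file("extdata", "ordinal_distinctness.csv", package = "taxocat")
}

# Brute-force Delta+: explicit double loop over all leaf pairs.  Kept
# deliberately naive and independent of the pair-counting implementation.
brute_delta_plus <- function(tree, group) {
  labels <- tree$leaves$label[tree$leaves$order == group |
                                tree$leaves$family == group |
                                tree$leaves$genus == group]
  s <- length(labels)
  if (s <= 1) return(0)
  total <- 0
  for (i in seq_len(s - 1)) {
    for (j in seq(i + 1, s)) {
      total <- total + pairwise_distance(tree, labels[i], labels[j])
    }
  }
  total / (s * (s - 1) / 2)
}

# The record columns of a catalog, without provenance attributes, for
# content comparisons across write/read round trips.
catalog_records <- function(x) {
  tibble::tibble(order = x$order, family = x$family, genus = x$genus,
                 species = x$species, year = x$year,
                 countries = x$countries)
}

# A description series tibble from raw counts (bypasses the catalog).
series_from_counts <- function(counts, start_year = 1900) {
  tibble::tibble(year = seq(start_year, by = 1,
                            length.out = length(counts)),
                 count = counts, cumulative = cumsum(counts))
}
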