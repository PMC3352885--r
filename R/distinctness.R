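#' Translate a Linnean classification into a tree
#'
#' Each species becomes a leaf under its genus, family and order, all
#' rooted at the class.  Pairwise distance between two species (the
#' distinctness weight, omega) is the scaled height of their lowest shared
#' taxon.  With the default equal-step convention the four inter-rank
#' steps are equal and the longest possible leaf-to-leaf path is scaled to
#' `max_path`, so at `max_path = 100` congeners are 25 apart, confamilial
#' species 50, con-ordinal species 75 and species in different orders 100.
#'
#' With `variable_steps = TRUE` step lengths are instead proportional to
#' the relative drop in the number of distinct taxa between adjacent
#' ranks (ranks that discriminate little contribute little path length),
#' still scaled to `max_path` overall.
#'
#' @param catalog a [taxo_catalog()] with every family assigned (run
#'   [assign_placeholders()] first).
#' @param max_path scaled maximum leaf-to-leaf distance (default 100).
#' @param variable_steps use taxon-count-proportional step lengths.
#' @return a `classification_tree` object with the leaf table, the four
#'   step lengths (species->genus, genus->family, family->order,
#'   order->class) and the node count.
#' @export
build_classification_tree <- function(catalog, max_path = 100,
                                      variable_steps = FALSE) {
  stopifnot(inherits(catalog, "taxo_catalog"))
  if (nrow(catalog) == 0L) stop("catalog is empty", call. = FALSE)
  if (any(!nzchar(catalog$family))) {
    stop("catalog contains species with no family; run assign_placeholders()",
         call. = FALSE)
  }
  leaves <- tibble::tibble(order = catalog$order, family = catalog$family,
                           genus = catalog$genus, species = catalog$species,
                           label = paste(catalog$genus, catalog$species))
  if (anyDuplicated(leaves$label)) {
    stop("ambiguous binomials: ",
         paste(unique(leaves$label[duplicated(leaves$label)]),
               collapse = "; "), call. = FALSE)
  }
  n_at <- c(species = nrow(leaves),
            genus = length(unique(leaves$genus)),
            family = length(unique(leaves$family)),
            order = length(unique(leaves$order)),
            class = 1L)
  if (variable_steps) {
    # step from rank r to its parent shrinks when the parent rank barely
    # aggregates (mirrors the varstep convention of classic Delta+ software)
    steps <- -diff(log(pmax(n_at, 1L)))
    if (all(steps == 0)) steps <- rep(1, 4)
    steps[steps == 0] <- min(steps[steps > 0]) / 2
  } else {
    steps <- rep(1, 4)
  }
  heights <- cumsum(steps) / sum(steps)  # lowest-shared-taxon height, 0..1
  structure(list(leaves = leaves,
                 step_heights = stats::setNames(max_path * heights,
                                                c("genus", "family", "order",
                                                  "class")),
                 max_path = max_path,
                 n_nodes = 1L + n_at[["order"]] + n_at[["family"]] +
                   n_at[["genus"]] + n_at[["species"]]),
            class = "classification_tree")
}

#' @export
print.classification_tree <- function(x, ...) {
  cat("<classification_tree> ", nrow(x$leaves), " species, ",
      x$n_nodes, " nodes, max path ", x$max_path, "\n", sep = "")
  cat("  step heights:",
      paste(names(x$step_heights), round(x$step_heights, 2), sep = "=",
            collapse = " "), "\n")
  invisible(x)
}

#' Distinctness weight between two species
#'
#' The pairwise distance omega is the scaled height of the lowest Linnean
#' taxon shared by the two species; `0` for a species against itself.
#'
#' @param tree a [build_classification_tree()] result.
#' @param species_a,species_b leaf labels (`"Genus epithet"`).
#' @return a single distance on the `0..max_path` scale.
#' @export
pairwise_distance <- function(tree, species_a, species_b) {
  stopifnot(inherits(tree, "classification_tree"))
  ia <- match(species_a, tree$leaves$label)
  ib <- match(species_b, tree$leaves$label)
  if (is.na(ia)) stop("unknown species: ", species_a, call. = FALSE)
  if (is.na(ib)) stop("unknown species: ", species_b, call. = FALSE)
  if (ia == ib) return(0)
  lv <- tree$leaves
  shared <- if (lv$genus[ia] == lv$genus[ib]) "genus"
  else if (lv$family[ia] == lv$family[ib]) "family"
  else if (lv$order[ia] == lv$order[ib]) "order"
  else "class"
  unname(tree$step_heights[shared])
}

#' Average taxonomic distinctness of a group
#'
#' Delta+ is the mean distinctness weight over all unordered pairs of
#' species in the group: `sum_{i<j} omega_ij / (s (s - 1) / 2)`.  A group
#' with a single species has no pairs and is assigned 0 by convention.
#' Rather than looping over the s(s-1)/2 pairs, pairs are counted per
#' shared rank (pairs sharing a genus, a family but not a genus, ...),
#' which is exact and linear in the number of species.
#'
#' @param tree a [build_classification_tree()] result.
#' @param group name of an order, family or genus in the tree, or `NULL`
#'   for the whole class.
#' @return a one-row tibble with `group`, `s`, `delta_plus`, `log10_s`.
#' @seealso [distinctness_table()] for all orders at once.
#' @export
taxonomic_distinctness <- function(tree, group = NULL) {
  stopifnot(inherits(tree, "classification_tree"))
  lv <- tree$leaves
  if (is.null(group)) {
    sub <- lv
    group <- "(all)"
  } else {
    sub <- lv[lv$order == group | lv$family == group | lv$genus == group, ]
    if (nrow(sub) == 0L) stop("unknown group: ", group, call. = FALSE)
  }
  tibble::tibble(group = group, s = nrow(sub),
                 delta_plus = delta_plus_pairs(sub, tree$step_heights),
                 log10_s = log10(nrow(sub)))
}

# Exact Delta+ by counting pairs at each shared rank.
delta_plus_pairs <- function(sub, heights) {
  s <- nrow(sub)
  if (s <= 1L) return(0)
  npairs <- function(counts) sum(choose(counts, 2))
  p_tot <- choose(s, 2)
  p_gen <- npairs(table(sub$genus))
  p_fam <- npairs(table(sub$family))
  p_ord <- npairs(table(sub$order))
  w <- heights[["genus"]] * p_gen +
    heights[["family"]] * (p_fam - p_gen) +
    heights[["order"]] * (p_ord - p_fam) +
    heights[["class"]] * (p_tot - p_ord)
  w / p_tot
}

#' Delta+ for every order in a tree
#'
#' @inheritParams taxonomic_distinctness
#' @return a tibble with one row per order, sorted by name.
#' @export
distinctness_table <- function(tree) {
  stopifnot(inherits(tree, "classification_tree"))
  orders <- sort(unique(tree$leaves$order))
  do.call(rbind, lapply(orders, function(o) taxonomic_distinctness(tree, o)))
}

#' Regress Delta+ on log10 species richness
#'
#' Ordinary least squares of group distinctness on the log10 of group
#' species count.  Groups below `min_species` are excluded (very small
#' groups have degenerate Delta+ fixed by one or two pairs); the default 4
#' drops groups of two or three species.
#'
#' @param results data frame with columns `group`, `s`, `delta_plus`
#'   (e.g. from [distinctness_table()] or [read_distinctness_groups()]).
#' @param min_species smallest group size admitted to the fit.
#' @return a `distinctness_fit` with `slope`, `intercept`, `r_squared`,
#'   two-sided slope `p_value`, `n_points` and `excluded_groups`.
#' @export
distinctness_regression <- function(results, min_species = 4) {
  stopifnot(all(c("group", "s", "delta_plus") %in% names(results)))
  keep <- results$s >= min_species
  excluded <- results$group[!keep]
  used <- results[keep, ]
  if (nrow(used) < 3L) {
    stop("need at least 3 groups with s >= ", min_species,
         " for a regression (have ", nrow(used), ")", call. = FALSE)
  }
  fit <- stats::lm(delta_plus ~ log10(s), data = used)
  sm <- summary(fit)
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = sm$r.squared,
                 p_value = sm$coefficients[2, 4],
                 n_points = nrow(used),
                 excluded_groups = as.character(excluded),
                 model = fit),
            class = "distinctness_fit")
}

#' @export
print.distinctness_fit <- function(x, ...) {
  cat(sprintf("Delta+ ~ log10(s): slope %.3f, intercept %.3f\n",
              x$slope, x$intercept))
  cat(sprintf("  r^2 = %.4f, p = %.4g, n = %d\n", x$r_squared, x$p_value,
              x$n_points))
  if (length(x$excluded_groups)) {
    cat("  excluded (too few species):",
        paste(x$excluded_groups, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Overlay external groups on a fitted Delta+ regression
#'
#' Comparison groups (e.g. orders of a related class) are placed against
#' an existing fit without refitting: each receives its predicted Delta+,
#' the residual (observed minus predicted) and a sign classification.
#' Residuals within `on_tolerance` of zero are classed `"on"` the line so
#' that a qualitative above/below reading is not driven by numeric noise.
#'
#' @param fit a [distinctness_regression()] result.
#' @param extra data frame of overlay groups (`group`, `s`, `delta_plus`).
#' @param on_tolerance half-width of the "on the line" band, in Delta+
#'   units.
#' @return a tibble with `group`, `s`, `delta_plus`, `predicted`,
#'   `residual`, `position` (`"above"`, `"on"`, `"below"`).
#' @export
overlay_groups <- function(fit, extra, on_tolerance = 0.5) {
  stopifnot(inherits(fit, "distinctness_fit"),
            all(c("group", "s", "delta_plus") %in% names(extra)))
  predicted <- fit$intercept + fit$slope * log10(extra$s)
  residual <- extra$delta_plus - predicted
  position <- ifelse(abs(residual) <= on_tolerance, "on",
                     ifelse(residual > 0, "above", "below"))
  tibble::tibble(group = extra$group, s = extra$s,
                 delta_plus = extra$delta_plus,
                 predicted = predicted, residual = residual,
                 position = position)
}

#' Read a pre-aggregated distinctness table
#'
#' For regression-only analyses the per-group numbers can be supplied
#' directly as a CSV with header `group,s,delta_plus` (extra annotation
#' columns such as a taxon-set label are carried through).
#'
#' @param path CSV path.
#' @return a tibble.
#' @export
read_distinctness_groups <- function(path) {
  if (!file.exists(path)) stop("groups file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("group", "s", "delta_plus") %in% names(raw))) {
    stop("groups header must name `group`, `s` and `delta_plus`",
         call. = FALSE)
  }
  tibble::as_tibble(raw)
}
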