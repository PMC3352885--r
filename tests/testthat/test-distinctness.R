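test_that("classification trees have the expected structure", {
  tree <- build_classification_tree(small_catalog())
  expect_equal(tree$n_nodes, 8L)  # root + 1 order + 1 family + 2 gen + 3 sp
  expect_equal(unname(tree$step_heights), c(25, 50, 75, 100))

  chain <- build_classification_tree(toy_catalog("O", "F", "G", "solus"))
  expect_equal(chain$n_nodes, 5L)  # species-genus-family-order-class chain

  unplaced <- toy_catalog("O", "", "G", "x")
  expect_error(build_classification_tree(unplaced), "assign_placeholders")
})

test_that("pairwise distances follow the lowest shared rank", {
  cat6 <- toy_catalog(c("O1", "O1", "O1", "O1", "O2"),
                      c("F1", "F1", "F1", "F2", "F3"),
                      c("G1", "G1", "G2", "G3", "G4"),
                      c("a", "b", "c", "d", "e"))
  tree <- build_classification_tree(cat6)
  expect_equal(pairwise_distance(tree, "G1 a", "G1 b"), 25)  # congeners
  expect_equal(pairwise_distance(tree, "G1 a", "G2 c"), 50)  # confamilial
  expect_equal(pairwise_distance(tree, "G1 a", "G3 d"), 75)  # con-ordinal
  expect_equal(pairwise_distance(tree, "G1 a", "G4 e"), 100) # cross-order
  expect_equal(pairwise_distance(tree, "G1 a", "G1 a"), 0)
  expect_error(pairwise_distance(tree, "G1 a", "G9 z"), "unknown species")
})

test_that("Delta+ matches direct pair averages on constructed groups", {
  # two congeners: the single pair has omega 25
  two <- build_classification_tree(toy_catalog("O", "F", "G",
                                               c("a", "b")))
  expect_equal(taxonomic_distinctness(two, "O")$delta_plus, 25)

  # a singleton group is 0 by convention
  one <- build_classification_tree(toy_catalog("O", "F", "G", "a"))
  expect_equal(taxonomic_distinctness(one, "O")$delta_plus, 0)

  # realizable 3-species triples: {25, 50, 50} and {25, 75, 75}
  t355 <- build_classification_tree(
    toy_catalog("O1", "F1", c("G1", "G1", "G2"), c("a", "b", "c")))
  expect_equal(taxonomic_distinctness(t355, "O1")$delta_plus,
               mean(c(25, 50, 50)))
  t377 <- build_classification_tree(
    toy_catalog("O1", c("F1", "F1", "F2"), c("G1", "G1", "G2"),
                c("a", "b", "c")))
  expect_equal(taxonomic_distinctness(t377, "O1")$delta_plus,
               mean(c(25, 75, 75)))

  tree <- build_classification_tree(small_catalog())
  expect_error(taxonomic_distinctness(tree, "Nowhere"), "unknown group")
})

test_that("Delta+ equals the brute-force pairwise oracle", {
  for (seed in 1:10) {
    cat_s <- simulate_classification(sample(20:150, 1), seed = seed)
    tree <- build_classification_tree(cat_s)
    for (ord in unique(tree$leaves$order)) {
      expect_equal(taxonomic_distinctness(tree, ord)$delta_plus,
                   brute_delta_plus(tree, ord), tolerance = 1e-12)
    }
  }
})

test_that("Delta+ respects bounds, scaling and genus-merging monotonicity", {
  cat_s <- simulate_classification(150, seed = 42)
  tree <- build_classification_tree(cat_s)
  tab <- distinctness_table(tree)
  expect_true(all(tab$delta_plus >= 0 & tab$delta_plus <= 100))
  expect_true(all(tab$delta_plus[tab$s >= 2] >= 25))

  # doubling max_path doubles omega and Delta+
  tree2 <- build_classification_tree(cat_s, max_path = 200)
  tab2 <- distinctness_table(tree2)
  expect_equal(tab2$delta_plus, 2 * tab$delta_plus)
  l1 <- tree$leaves$label[1:2]
  expect_equal(pairwise_distance(tree2, l1[1], l1[2]),
               2 * pairwise_distance(tree, l1[1], l1[2]))

  # relabeling one genus as a confamilial genus never increases Delta+
  for (seed in 1:5) {
    cat_m <- simulate_classification(80, seed = seed)
    fam_tab <- table(unique(cat_m[, c("family", "genus")])$family)
    fam <- names(fam_tab)[fam_tab >= 2][1]
    if (is.na(fam)) next
    gens <- unique(cat_m$genus[cat_m$family == fam])
    merged <- cat_m
    idx <- merged$genus == gens[2]
    merged$genus[idx] <- gens[1]
    merged$species[idx] <- paste0(merged$species[idx], "_m")
    ord <- merged$order[merged$family == fam][1]
    d_before <- taxonomic_distinctness(build_classification_tree(cat_m),
                                       ord)$delta_plus
    d_after <- taxonomic_distinctness(build_classification_tree(merged),
                                      ord)$delta_plus
    expect_lte(d_after, d_before + 1e-12)
  }
})

test_that("Delta+ agrees with the community-ecology reference implementation", {
  cat_s <- simulate_classification(120, seed = 9)
  tree <- build_classification_tree(cat_s)
  ranks <- data.frame(species = tree$leaves$label, genus = cat_s$genus,
                      family = cat_s$family, order = cat_s$order,
                      row.names = tree$leaves$label)
  dis <- vegan::taxa2dist(ranks, varstep = FALSE, check = FALSE)
  orders <- unique(cat_s$order)
  comm <- t(sapply(orders, function(o) as.integer(cat_s$order == o)))
  colnames(comm) <- tree$leaves$label
  dd <- vegan::taxondive(comm, dis)
  ours <- vapply(orders, function(o)
    taxonomic_distinctness(tree, o)$delta_plus, numeric(1))
  multi <- table(cat_s$order)[orders] >= 2  # singleton conventions differ
  expect_equal(unname(ours[multi]), unname(dd$Dplus[multi]),
               tolerance = 1e-10)
})

test_that("the Delta+ regression reports OLS diagnostics and exclusions", {
  # hand-computed oracle: r^2 = Sxy^2 / (Sxx Syy) = 225/233.33 = 0.9643
  toy <- data.frame(group = c("a", "b", "c"), s = c(10, 100, 1000),
                    delta_plus = c(10, 20, 25))
  fit <- distinctness_regression(toy, min_species = 1)
  expect_equal(fit$r_squared, 225 / (2 * 350 / 3), tolerance = 1e-10)
  expect_equal(fit$n_points, 3L)

  collinear <- data.frame(group = letters[1:3], s = c(10, 100, 1000),
                          delta_plus = c(10, 20, 30))
  collinear_fit <- suppressWarnings(  # summary.lm flags the perfect fit
    distinctness_regression(collinear, min_species = 1))
  expect_equal(collinear_fit$r_squared, 1)

  # exclusion below min_species is listed, never silent
  toy4 <- rbind(toy, data.frame(group = "tiny", s = 2, delta_plus = 25))
  fit4 <- distinctness_regression(toy4, min_species = 4)
  expect_identical(fit4$excluded_groups, "tiny")
  expect_equal(fit4$n_points, 3L)

  expect_error(distinctness_regression(toy4, min_species = 50),
               "at least 3")

  # r^2 is invariant under affine transformation of the predictor:
  # scaling every s by a constant shifts log10(s) without changing fit
  scaled <- toy
  scaled$s <- scaled$s * 37
  expect_equal(distinctness_regression(scaled, min_species = 1)$r_squared,
               fit$r_squared, tolerance = 1e-12)
})

test_that("overlays classify residual signs without touching the fit", {
  fit <- suppressWarnings(distinctness_regression(
    data.frame(group = letters[1:4], s = c(10, 100, 1000, 10000),
               delta_plus = c(40, 60, 80, 100)), min_species = 1))
  extra <- data.frame(group = c("on", "above", "below"),
                      s = c(100, 100, 100),
                      delta_plus = c(60, 70, 45))
  ov <- overlay_groups(fit, extra, on_tolerance = 0.5)
  expect_equal(ov$position, c("on", "above", "below"))
  expect_equal(ov$residual, c(0, 10, -15), tolerance = 1e-12)
  # the fit itself is unchanged by overlaying
  expect_equal(fit$r_squared, 1)
})
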