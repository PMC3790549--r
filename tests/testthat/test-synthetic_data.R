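test_that("pure-birth trees are ultrametric, reproducible, and scale correctly", {
  tr <- simulate_tree(22, 1, seed = 101)
  expect_identical(length(tr$tip.label), 22L)
  expect_identical(tr$Nnode, 21L)
  depth <- ape::node.depth.edgelength(tr)[1:22]
  expect_lt(diff(range(depth)), 1e-12)

  expect_identical(write_tree(simulate_tree(22, 1, seed = 101)), write_tree(tr))
  expect_false(identical(write_tree(simulate_tree(22, 1, seed = 102)),
                         write_tree(tr)))

  # depth scales inversely with the birth rate and grows with n
  d1 <- vapply(1:150, function(i)
    max(ape::node.depth.edgelength(simulate_tree(20, 1, i))), 1)
  d2 <- vapply(1:150, function(i)
    max(ape::node.depth.edgelength(simulate_tree(20, 2, i))), 1)
  d3 <- vapply(1:150, function(i)
    max(ape::node.depth.edgelength(simulate_tree(80, 1, i))), 1)
  expect_equal(mean(d2) / mean(d1), 0.5, tolerance = 0.1)
  expect_gt(mean(d3), mean(d1))
})

test_that("Mk character simulation matches its limiting behavior", {
  tr <- simulate_tree(16, 1, seed = 7)
  slow <- simulate_mk_characters(tr, 20, c("C", "B", "N"), rate = 1e-9, seed = 1)
  expect_true(all(apply(slow, 2, function(col) length(unique(col)) == 1)))

  # near-stationary regime: states approach the uniform distribution
  fast <- simulate_mk_characters(tr, 500, c("C", "B", "N", "D"), rate = 50,
                                 seed = 2)
  tab <- table(factor(unclass(fast), c("C", "B", "N", "D")))
  expect_gt(suppressWarnings(chisq.test(tab)$p.value), 0.001)

  # step counts always respect the parsimony lower bound
  m <- simulate_mk_characters(tr, 30, c("C", "B", "N", "D", "L", "W"),
                              rate = 0.05, seed = 3)
  r <- unambiguous_changes(tr, m)
  expect_true(all(r$steps >= r$min_steps))
})

test_that("OU trait simulation matches its moments", {
  # BM: tip variance grows like sigma2 * depth (independent tips, star tree)
  star <- read_tree(text = "(A:2,B:2,C:2,D:2);")
  y <- vapply(1:400, function(i)
    simulate_ou_trait(star, alpha = 0, sigma2 = 1.5, z0 = 0, seed = i)[1], 1)
  expect_equal(var(y), 1.5 * 2, tolerance = 0.35)

  # strong attraction: means approach the regime optima
  p2 <- regime_painting(star, c("R1", "R1", "R2", "R2"), root_regime = "R1")
  sims <- t(vapply(1:200, function(i)
    simulate_ou_trait(star, p2, alpha = 10, sigma2 = 1,
                      theta = c(R1 = -4, R2 = 4), seed = i), numeric(4)))
  se <- sqrt(1 / (2 * 10)) / sqrt(200)
  expect_lt(abs(mean(sims[, "A"]) + 4), 3 * se + 1e-6)
  expect_lt(abs(mean(sims[, "D"]) - 4), 3 * se + 1e-6)
})

test_that("sequence simulation follows the Jukes-Cantor expectation", {
  two <- read_tree(text = "(A:1.5,B:1.5);")   # patristic distance 3
  aln <- simulate_sequences(two, c(g1 = 20000), rate = 0.05, seed = 5)
  p <- as.numeric(p_distance(aln["A", ], aln["B", ]))
  expected <- 0.75 * (1 - exp(-4 * 0.05 * 3 / 3))
  expect_lt(abs(p - expected), 3 * sqrt(expected * (1 - expected) / 20000))

  calm <- simulate_sequences(two, c(g1 = 500), rate = 1e-9, seed = 6)
  expect_equal(as.numeric(p_distance(calm["A", ], calm["B", ])), 0)

  # partitions cover the alignment
  b <- make_study_fixture(fixture_spec(seed = 2))
  parts <- attr(b$alignment, "partitions")
  expect_identical(sum(parts$end - parts$start + 1L), ncol(b$alignment))
})

test_that("fixtures regenerate byte-identically from (spec, seed)", {
  b1 <- make_study_fixture(fixture_spec(seed = 42))
  b2 <- make_study_fixture(fixture_spec(seed = 42))
  expect_identical(serialize(b1, NULL), serialize(b2, NULL))
  b3 <- make_study_fixture(fixture_spec(seed = 43))
  expect_false(identical(unclass(b1$male), unclass(b3$male)))
  expect_length(validate_bundle(b1), 0)

  # both regions and all four radiations represented
  expect_identical(sort(unique(b1$meta$regime2)), c("Australia", "NewGuinea"))
  expect_identical(length(unique(b1$meta$regime4)), 4L)
  # regime4 refines regime2
  expect_true(all(startsWith(b1$meta$regime4, b1$meta$regime2)))

  # the generating paintings satisfy the painting invariants
  expect_length(b1$painting2$edge_regimes, nrow(b1$tree$edge))
  expect_true(all(b1$painting2$edge_regimes %in% b1$painting2$regimes))
})

test_that("southern-regime bias raises dichromatism where latitude is high", {
  b <- make_study_fixture(fixture_spec(seed = 21))
  sc <- dichromatism_scores(b$male, b$female)
  sc <- merge(sc, b$meta, by = "taxon")
  expect_gt(mean(sc$D[sc$regime2 == "Australia"]),
            mean(sc$D[sc$regime2 == "NewGuinea"]))
  expect_gt(mean(sc$lat_south[sc$regime2 == "Australia"]),
            mean(sc$lat_south[sc$regime2 == "NewGuinea"]))
})

test_that("a zero-effect generator yields null-calibrated contrast slopes", {
  pvals <- vapply(1:60, function(s) {
    b <- make_study_fixture(fixture_spec(seed = s, female_bias = 0,
                                         female_noise = 0.1))
    res <- dichromatism_latitude_analysis(b$tree, b$male, b$female, b$meta,
                                          latitude = "midpoint")
    res$regression_midpoint$p
  }, 1)
  expect_lte(mean(pvals < 0.05), 0.15)   # ~5% nominal, binomial slack
})

test_that("the shipped frozen fixture matches regeneration from its seed", {
  dir <- system.file("extdata", "fixture_seed1", package = "plumevol")
  b <- make_study_fixture(fixture_spec(seed = 1))
  expect_identical(readLines(file.path(dir, "tree.nwk")), write_tree(b$tree))
  m <- read_character_matrix(file.path(dir, "male.csv"))
  expect_equal(unclass(m), unclass(b$male), ignore_attr = TRUE)
  f <- read_character_matrix(file.path(dir, "female.csv"))
  expect_equal(unclass(f), unclass(b$female), ignore_attr = TRUE)
  meta <- read_taxon_meta(file.path(dir, "meta.csv"))
  expect_equal(meta, b$meta, tolerance = 1e-12)
})

test_that("fixtures round-trip through the on-disk formats", {
  b <- make_study_fixture(fixture_spec(seed = 3))
  dir <- withr::local_tempdir()
  write_study_fixture(b, dir)
  b2 <- study_bundle(read_tree(file.path(dir, "tree.nwk")),
                     read_character_matrix(file.path(dir, "male.csv")),
                     read_character_matrix(file.path(dir, "female.csv")),
                     read_taxon_meta(file.path(dir, "meta.csv")),
                     read_alignment(file.path(dir, "alignment.fasta"),
                                    attr(b$alignment, "partitions")))
  expect_length(validate_bundle(b2), 0)
  expect_equal(unclass(b2$male), unclass(b$male), ignore_attr = TRUE)
  expect_true(ape::all.equal.phylo(b2$tree, b$tree, use.edge.length = TRUE))
  expect_identical(unclass(b2$alignment), unclass(b$alignment))
})
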