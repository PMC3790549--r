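test_that("principal-coordinate scores behave like classical MDS", {
  # three collinear points: axis 1 proportional to (-1, 0, 1)
  d <- matrix(c(0, 1, 2, 1, 0, 1, 2, 1, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  sc <- pcoa_trait(d)
  expect_equal(unname(sc$trait / sc$trait["C"]), c(-1, 0, 1), tolerance = 1e-10)
  expect_equal(sum(sc$trait), 0, tolerance = 1e-10)
  expect_gt(sc$trait[which.max(abs(sc$trait))], 0)   # sign convention

  expect_error(pcoa_trait(matrix(0, 3, 3)), "zero")

  b <- make_study_fixture(fixture_spec(seed = 4))
  s <- pcoa_trait(plumage_distance_matrix(b$male))
  ev <- s$eigenvalues
  expect_true(all(diff(ev) <= 1e-8))                 # non-increasing
})

test_that("BM likelihood matches closed forms and is scale-invariant", {
  star <- read_tree(text = "(A:1,B:1);")
  expect_equal(bm_loglik(star, c(A = 0, B = 0), 1, 0), -log(2 * pi),
               tolerance = 1e-12)

  tr <- ape::rtree(8)
  set.seed(2); y <- setNames(rnorm(8), tr$tip.label)
  l1 <- bm_loglik(tr, y, 0.7, 0.1)
  tr2 <- tr; tr2$edge.length <- tr$edge.length * 3
  expect_equal(bm_loglik(tr2, y, 0.7 / 3, 0.1), l1, tolerance = 1e-10)

  # ML root state equals the GLS mean
  fit <- fit_trait_model(tr, y, "BM")
  C <- ape::vcv.phylo(tr)
  Ci <- solve(C)
  one <- rep(1, 8)
  expect_equal(fit$z0,
               as.numeric((one %*% Ci %*% y[tr$tip.label]) / (one %*% Ci %*% one)),
               tolerance = 1e-8)
})

test_that("OU likelihood reduces to closed forms in limiting cases", {
  tr <- read_tree(text = "((A:1,B:1):1,C:2);")
  y <- c(A = 0.3, B = -0.1, C = 0.5)
  p1 <- single_regime_painting(tr)
  # BM limit
  expect_lt(abs(ou_loglik(tr, y, p1, 1e-8, 1, c(all = 0.2), z0 = 0.2) -
                  bm_loglik(tr, y, 1, 0.2)), 1e-4)
  expect_error(ou_loglik(tr, y, p1, 0, 1, c(all = 0)), "alpha")

  # independent tips on a star tree: product of univariate OU densities
  star <- read_tree(text = "(A:2,B:2);")
  ps <- single_regime_painting(star)
  a <- 0.9; s2 <- 1.3; th <- 1.1; z0 <- -0.4
  yv <- c(A = 0.8, B = 1.5)
  m <- z0 * exp(-a * 2) + th * (1 - exp(-a * 2))
  v <- s2 * (1 - exp(-2 * a * 2)) / (2 * a)
  expect_equal(ou_loglik(star, yv, ps, a, s2, c(all = th), z0 = z0),
               sum(dnorm(yv, m, sqrt(v), log = TRUE)), tolerance = 1e-10)

  # strong attraction: tip means converge to their own regime's optimum
  p2 <- regime_painting(star, c("R1", "R2"), root_regime = "R1")
  W <- plumevol:::ou_mean_weights(p2, 20)            # alpha * T = 40
  mu <- W %*% c(R1 = -3, R2 = 7)
  expect_equal(unname(mu[, 1]), c(-3, 7), tolerance = 1e-6)
})

test_that("OU likelihood matches a quadrature-based multivariate-normal oracle", {
  set.seed(31)
  for (rep in 1:8) {
    tr <- ape::rtree(sample(4:6, 1))
    regs <- c("A", "B")
    painting <- regime_painting(tr, sample(regs, nrow(tr$edge), replace = TRUE),
                                regimes = regs, root_regime = "A")
    y <- setNames(rnorm(length(tr$tip.label)), tr$tip.label)
    a <- runif(1, 0.2, 3); s2 <- runif(1, 0.5, 2)
    th <- c(A = rnorm(1), B = rnorm(1)); z0 <- rnorm(1)
    expect_equal(ou_loglik(tr, y, painting, a, s2, th, z0 = z0),
                 ou_oracle_loglik(tr, y, painting, a, s2, th, z0),
                 tolerance = 1e-8)
  }
})

test_that("model fits are nested and recover generating parameters", {
  set.seed(55)
  tr <- ape::rphylo(80, 1, 0)
  painting <- basal_split_painting(tr)
  y <- simulate_ou_trait(tr, painting, alpha = 2, sigma2 = 1,
                         theta = c(N = 0, S = 5), seed = 404)
  fits <- list(BM = fit_trait_model(tr, y, "BM"),
               OU1 = fit_trait_model(tr, y, "OU1"),
               OUM2 = suppressWarnings(fit_trait_model(tr, y, "OUM2",
                                                       painting = painting)))
  # nesting up to optimizer tolerance
  expect_gte(fits$OU1$lnL, fits$BM$lnL - 1e-6)
  expect_gte(fits$OUM2$lnL, fits$OU1$lnL - 1e-6)
  # recovery of the optima
  expect_lt(abs(fits$OUM2$theta["N"] - 0), 0.5)
  expect_lt(abs(fits$OUM2$theta["S"] - 5), 0.5)
  expect_identical(vapply(fits, `[[`, 1L, "k"), c(BM = 2L, OU1 = 3L, OUM2 = 4L))

  yb <- simulate_ou_trait(tr, alpha = 0, sigma2 = 1.5, z0 = 0, seed = 405)
  fb <- fit_trait_model(tr, yb, "BM")
  expect_lt(abs(fb$sigma2 - 1.5) / 1.5, 0.25)
})

test_that("the AICc table normalizes weights and flags decisive best models", {
  tab <- table1_check(c(-5, -5), k = c(2, 2), n = 20, models = c("m1", "m2"))
  expect_equal(tab$delta_AICc, c(0, 0))
  expect_equal(tab$weight, c(0.5, 0.5))
  expect_false(any(tab$best))

  one <- table1_check(-3, k = 2, n = 20, models = "only")
  expect_equal(one$delta_AICc, 0)
  expect_equal(one$weight, 1)

  expect_error(table1_check(c(0, 0), k = c(2, 6), n = 7), "AICc undefined")

  b <- make_study_fixture(fixture_spec(seed = 9))
  tr <- b$tree
  y <- b$traits$male
  fits <- list(fit_trait_model(tr, y, "BM"), fit_trait_model(tr, y, "OU1"))
  mt <- model_table(fits)
  expect_equal(sum(mt$weight), 1)
  expect_equal(min(mt$delta_AICc), 0)
  fits[[2]]$n <- 99L
  expect_error(model_table(fits), "different n")
})
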