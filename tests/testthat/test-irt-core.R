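# Characteristic curves, the loading conversion, and the Lord-Wingersky
# recursion against brute-force enumeration.

# Printed reference table: a, lambda, h2 (3 dp).
PRINTED <- data.frame(
  item = c("SC20", "SC21", "SC22", "SC23", "SC24", "SC25", "SC26", "SC29", "SC30"),
  a = c(1.791, 3.518, 4.641, 3.799, 1.752, 2.069, 2.280, 1.822, 2.048),
  lambda = c(0.725, 0.900, 0.939, 0.913, 0.717, 0.772, 0.801, 0.731, 0.769),
  h2 = c(0.525, 0.810, 0.881, 0.833, 0.514, 0.596, 0.642, 0.534, 0.591))

test_that("the 2PL ICC has its midpoint at b and the right asymptotes", {
  expect_equal(icc2pl(1.849, a = 1.752, b = 1.849), 0.5)
  expect_equal(icc2pl(1e6, a = 2, b = 0), 1)
  expect_equal(icc2pl(-1e6, a = 2, b = 0), 0)
  # direct evaluation of the logistic formula at theta = 0
  expect_equal(icc2pl(0, a = 1.752, b = 1.849), 1 / (1 + exp(1.752 * 1.849)),
               tolerance = 1e-12)
  expect_equal(round(icc2pl(0, a = 1.752, b = 1.849), 4), 0.0377)
})

test_that("the loading conversion reproduces all printed lambda/h2 pairs to 3 dp", {
  lam <- loadingFromDiscrimination(PRINTED$a)
  expect_equal(round(lam, 3), PRINTED$lambda)
  expect_equal(round(lam^2, 3), PRINTED$h2)
  expect_equal(loadingFromDiscrimination(0), 0)
  expect_equal(loadingFromDiscrimination(1.702), 1 / sqrt(2), tolerance = 1e-12)
  expect_error(loadingFromDiscrimination(-0.5), "non-negative")
  # accessors agree with the direct conversion
  expect_equal(unname(itemLoadings(TRUTH)), lam)
  expect_equal(unname(itemCommunalities(TRUTH)), lam^2)
})

test_that("the TCC is a strictly increasing sum of the item curves", {
  one <- TRUTH["SC25"]
  expect_equal(tcc(difficulty(one), one), 0.5)
  expect_equal(tcc(50, TRUTH), 9, tolerance = 1e-10)
  # term-by-term hand evaluation at theta = 0
  expect_equal(tcc(0, TRUTH),
               sum(1 / (1 + exp(-TRUTH@a * (0 - TRUTH@b)))), tolerance = 1e-12)
  grid <- seq(-4, 4, by = 0.25)
  expect_true(all(diff(tcc(grid, TRUTH)) > 0))
})

test_that("quadrature grids carry renormalised normal mass on increasing nodes", {
  g <- quadratureGrid(61L, c(-6, 6))
  expect_equal(sum(g@weights), 1, tolerance = 1e-12)
  expect_true(all(diff(g@nodes) > 0))
  expect_error(new("QuadratureGrid", nodes = c(0, 0), weights = c(0.5, 0.5)),
               "strictly increasing")
})

test_that("Lord-Wingersky equals the single-Bernoulli and binomial special cases", {
  one <- TRUTH["SC22"]
  p <- icc2pl(0.3, one@a, one@b)
  expect_equal(drop(lordWingersky(0.3, one)), c("0" = 1 - p, "1" = p))
  eq <- itemParameters(paste0("i", 1:6), a = rep(1.4, 6), b = rep(0.2, 6))
  pmf <- drop(lordWingersky(-0.5, eq))
  pj <- icc2pl(-0.5, 1.4, 0.2)
  expect_equal(unname(pmf), stats::dbinom(0:6, 6, pj), tolerance = 1e-12)
})

test_that("Lord-Wingersky matches exhaustive 512-pattern enumeration at 25 thetas", {
  thetas <- seq(-3, 3, length.out = 25)
  pmf <- lordWingersky(thetas, TRUTH)
  expect_equal(max(abs(rowSums(pmf) - 1)), 0, tolerance = 1e-12)
  worst <- max(vapply(seq_along(thetas), function(i)
    max(abs(pmf[i, ] - bruteSumScorePmf(thetas[i], TRUTH))), numeric(1L)))
  expect_lt(worst, 1e-12)
})

test_that("cut exceedance probabilities complement the pmf below the cut", {
  th <- c(-1, 0, 1)
  pmf <- lordWingersky(th, TRUTH)
  expect_equal(cutExceedanceProb(th, TRUTH, cut = 1), 1 - pmf[, "0"],
               tolerance = 1e-12)
  expect_equal(cutExceedanceProb(th, TRUTH, cut = 3),
               rowSums(pmf[, as.character(3:9)]), tolerance = 1e-12)
})
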