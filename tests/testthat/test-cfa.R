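# One-factor CFA: exact rank-one recovery, ordering invariance, agreement
# with the IRT route, and index behaviour.

test_that("an exactly rank-one matrix is fit perfectly", {
  lam <- c(0.85, 0.75, 0.65, 0.55, 0.45)
  R <- tcrossprod(lam); diag(R) <- 1
  fit <- fitOneFactor(R, n = 10000)
  expect_equal(unname(fit@loadings), lam, tolerance = 1e-6)
  expect_lt(fit@srmsr, 1e-7)
  expect_equal(fit@cfi, 1)
  expect_equal(fit@tli, 1)
  expect_lt(max(fit@itemRmsea), 1e-6)
})

test_that("permuting item order permutes loadings but leaves fit indices unchanged", {
  rm <- simulateResponses(simulationConfig(n = 5000, groups = "all", seed = 51))
  R <- tetrachoricMatrix(rm)@rho
  perm <- c(4, 9, 1, 7, 2, 6, 3, 8, 5)
  f1 <- fitOneFactor(R, n = 5000)
  f2 <- fitOneFactor(R[perm, perm], n = 5000)
  expect_equal(unname(f2@loadings), unname(f1@loadings[perm]), tolerance = 1e-5)
  expect_equal(f2@srmsr, f1@srmsr, tolerance = 1e-8)
  expect_equal(f2@rmsea, f1@rmsea, tolerance = 1e-8)
  expect_equal(f2@cfi, f1@cfi, tolerance = 1e-8)
  # deterministic: same input, same output
  expect_identical(fitOneFactor(R, n = 5000)@loadings, f1@loadings)
})

test_that("loadings recover the generating values on large simulated data", {
  # logistic ICCs vs the tetrachoric's normal ogive diverge for the most
  # extreme thresholds, so the bound is 0.02 for mid-range difficulties
  # and 0.06 overall (see the methods vignette)
  rm <- simulateResponses(simulationConfig(n = 50000, groups = "all", seed = 52))
  fit <- fitOneFactor(tetrachoricMatrix(rm), n = 50000)
  lam <- itemLoadings(TRUTH)
  mid <- abs(TRUTH@b) <= 1.2
  expect_lt(max(abs(fit@loadings - lam)[mid]), 0.02)
  expect_lt(max(abs(fit@loadings - lam)), 0.06)
  # two routes to the same quantity: CFA vs converted 2PL slopes
  irtRoute <- itemLoadings(itemParams(fit2pl(rm)))
  expect_lt(max(abs(fit@loadings - irtRoute)[mid]), 0.03)
  expect_lt(max(abs(fit@loadings - irtRoute)), 0.06)
})

test_that("SRMSR weakly decreases as a second factor's cross-loadings vanish", {
  lam <- rep(0.7, 6)
  srmsr <- vapply(c(0.3, 0), function(cross) {
    lam2 <- c(cross, cross, cross, 0, 0, 0)
    R <- tcrossprod(lam) + tcrossprod(lam2); diag(R) <- 1
    fitOneFactor(R, n = 5000)@srmsr
  }, numeric(1L))
  expect_lte(srmsr[2L], srmsr[1L])
})

test_that("non-PSD inputs error without smoothing and are repaired with it", {
  R <- diag(3); R[1, 2] <- R[2, 1] <- 0.9; R[1, 3] <- R[3, 1] <- 0.9
  R[2, 3] <- R[3, 2] <- -0.9   # violates PSD
  expect_error(fitOneFactor(R, n = 1000, smooth = FALSE), "positive semi-definite")
  fit <- fitOneFactor(R, n = 1000, smooth = TRUE)
  expect_true(all(is.finite(fit@loadings)))
})

test_that("the JSON report round-trips the fitted indices", {
  lam <- c(0.8, 0.7, 0.6, 0.5)
  R <- tcrossprod(lam); diag(R) <- 1
  dimnames(R) <- list(paste0("i", 1:4), paste0("i", 1:4))
  fit <- fitOneFactor(R, n = 2000)
  parsed <- jsonlite::fromJSON(cfaReport(fit))
  expect_equal(parsed$srmsr, fit@srmsr)
  expect_equal(unlist(parsed$loadings), fit@loadings, tolerance = 1e-6)
})
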