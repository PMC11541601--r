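# Constrained two-group estimation: constraint saturation, exhaustive
# likelihood oracle, identification and nesting.

test_that("a fully anchored model with fixed moments collapses to the pooled fit", {
  rm <- nullGroupData(4000, seed = 61)
  ctl <- list(tol = 1e-8)
  mg <- fitMultigroup(rm, anchored = itemNames(rm), estimateMoments = FALSE,
                      control = ctl)
  pooled <- fit2pl(responseMatrix(responses(rm)), control = ctl)
  expect_equal(mg@refParams@a, itemParams(pooled)@a, tolerance = 1e-6)
  expect_equal(mg@refParams@b, itemParams(pooled)@b, tolerance = 1e-6)
  expect_equal(mg@focalParams@a, mg@refParams@a)
  expect_equal(mg@fit@logLik, fitSummary(pooled)@logLik, tolerance = 1e-6)
})

test_that("the joint log-likelihood equals per-group exhaustive enumeration", {
  rm <- nullGroupData(2000, seed = 62)
  mg <- fitMultigroup(rm, anchored = itemNames(rm)[1:5])
  Y <- responses(rm); grp <- groupLabels(rm)
  grid <- quadratureGrid()
  bruteRef <- bruteMarginalLogLik(Y[grp == "ref", ], mg@refParams, grid)
  # focal group integrates against its estimated normal prior
  gridFoc <- new("QuadratureGrid", nodes = grid@nodes,
                 weights = {
                   w <- stats::dnorm(grid@nodes, mg@focalMean, sqrt(mg@focalVar))
                   w / sum(w)
                 })
  bruteFoc <- bruteMarginalLogLik(Y[grp == "foc", ], mg@focalParams, gridFoc)
  expect_equal(mg@fit@logLik, bruteRef + bruteFoc, tolerance = 1e-8)
})

test_that("latent moments cannot be freed without anchors, and groups need both categories", {
  rm <- nullGroupData(2000, seed = 63)
  expect_error(fitMultigroup(rm, anchored = character(),
                             estimateMoments = TRUE), "identification")
  Y <- responses(rm)
  Y[groupLabels(rm) == "foc", "SC24"] <- 0L
  expect_error(fitMultigroup(responseMatrix(Y, groupLabels(rm)),
                             anchored = colnames(Y)), "SC24.*foc|foc.*SC24")
  expect_error(fitMultigroup(rm, anchored = itemNames(rm),
                             control = list(minGroupN = 5000)), "floor")
})

test_that("freeing parameters never decreases the maximised log-likelihood", {
  rm <- nullGroupData(3000, seed = 64)
  items <- itemNames(rm)
  ctl <- list(tol = 1e-6)
  full <- fitMultigroup(rm, anchored = items, control = ctl)
  lls <- vapply(items[1:4], function(j)
    fitMultigroup(rm, anchored = setdiff(items, j), control = ctl)@fit@logLik,
    numeric(1L))
  expect_true(all(lls >= full@fit@logLik - 1e-6))
})

test_that("a true focal latent shift is absorbed by the moments, not the items", {
  cfg <- simulationConfig(n = 16000, focalMean = -0.4, seed = 65)
  rm <- simulateResponses(cfg)
  mg <- fitMultigroup(rm, anchored = itemNames(rm))
  expect_equal(mg@focalMean, -0.4, tolerance = 0.06)
  expect_equal(mg@focalVar, 1, tolerance = 0.08)
  expect_lt(max(abs(mg@refParams@b - TRUTH@b)), 0.12)
})

test_that("group parameter accessors resolve labels and roles", {
  rm <- nullGroupData(2000, seed = 66)
  mg <- fitMultigroup(rm, anchored = itemNames(rm))
  expect_identical(groupParameters(mg, "reference"), mg@refParams)
  expect_identical(groupParameters(mg, "foc"), mg@focalParams)
  expect_identical(anchorItems(mg), itemNames(rm))
})
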