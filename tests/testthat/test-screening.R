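# Latent cut-point mapping and classification accuracy under DIF-free and
# DIF measurement models.

test_that("a single-item test puts the midpoint latent cut at its difficulty", {
  one <- TRUTH["SC25"]
  cp <- latentCutpoint(one, cut = 1)
  expect_equal(cp@t, 0.5)
  expect_equal(cp@thetaStar, difficulty(one)[["SC25"]], tolerance = 1e-8)
})

test_that("bisection matches a brute-force fine grid search", {
  cp <- latentCutpoint(TRUTH, cut = 1)
  expect_lt(abs(tcc(cp@thetaStar, TRUTH) - 0.5), 1e-10)
  # localized 1e-6-step grid around the coarse bracket
  grid <- seq(cp@thetaStar - 0.002, cp@thetaStar + 0.002, by = 1e-6)
  best <- grid[which.min(abs(tcc(grid, TRUTH) - 0.5))]
  expect_lt(abs(cp@thetaStar - best), 1e-5)
})

test_that("higher cuts map to strictly higher latent cut-points, invalid cuts error", {
  c1 <- latentCutpoint(TRUTH, cut = 1)
  c2 <- latentCutpoint(TRUTH, cut = 2)
  expect_gt(c2@thetaStar, c1@thetaStar)
  s1 <- latentCutpoint(TRUTH, cut = 1, convention = "strict")
  expect_equal(s1@t, 1)
  expect_gt(s1@thetaStar, c1@thetaStar)
  expect_error(latentCutpoint(TRUTH, cut = 10), "validation")
  expect_error(latentCutpoint(TRUTH, cut = 9, convention = "strict"),
               "validation")
})

test_that("the cut-point ignores an added item that is never endorsed", {
  cp <- latentCutpoint(TRUTH, cut = 1)
  aug <- itemParameters(c(TRUTH@items, "null"),
                        a = c(TRUTH@a, 0.01), b = c(TRUTH@b, 3000))
  expect_equal(latentCutpoint(aug, cut = 1)@thetaStar, cp@thetaStar,
               tolerance = 1e-6)
})

test_that("zero-DIF models yield identical variants and exactly zero differences", {
  model <- makeGroupModel(TRUTH, TRUTH)
  cp <- latentCutpoint(TRUTH, cut = 1)
  for (v in c("expected", "probabilistic")) {
    ix <- classificationIndices(model, cp, mode = "integration", variant = v)
    cmp <- compareModels(ix, ix)
    expect_true(all(cmp$difference == 0))
    wide <- impactTable(cmp)
    expect_true(all(unlist(wide[, grep("difference", names(wide))]) == 0))
  }
})

test_that("near-deterministic items drive sensitivity and specificity to one", {
  # slopes steep enough that the summed-score transition zone carries
  # negligible mass; the grid must resolve the transition width ~4/a
  sharp <- itemParameters(TRUTH@items, a = rep(3000, 9), b = TRUTH@b)
  model <- makeGroupModel(sharp, sharp)
  cp <- latentCutpoint(sharp, cut = 1)
  ix <- classificationIndices(model, cp, mode = "integration",
                              variant = "probabilistic",
                              grid = quadratureGrid(10001L, c(-6, 6)))
  tab <- indicesTable(ix)
  expect_gt(min(tab$sensitivity), 1 - 1e-3)
  expect_gt(min(tab$specificity), 1 - 1e-3)
})

test_that("classification rate decomposes as sens*pi + spec*(1-pi)", {
  g <- groupItemParameters("sex")
  model <- makeGroupModel(g$reference, g$focal, groups = unname(g$labels),
                          mu = -0.15, v = 0.95)
  cp <- latentCutpoint(TRUTH, cut = 1)
  for (v in c("expected", "probabilistic")) {
    tab <- indicesTable(classificationIndices(model, cp, mode = "integration",
                                              variant = v))
    expect_equal(tab$classificationRate,
                 tab$sensitivity * tab$propAbove +
                   tab$specificity * (1 - tab$propAbove), tolerance = 1e-10)
  }
})

test_that("DIF-free indices are group-invariant under equal latent distributions", {
  model <- makeGroupModel(TRUTH, TRUTH)
  cp <- latentCutpoint(TRUTH, cut = 1)
  tab <- indicesTable(classificationIndices(model, cp, mode = "integration",
                                            variant = "probabilistic"))
  expect_equal(tab$sensitivity[1L], tab$sensitivity[2L], tolerance = 1e-10)
  expect_equal(tab$specificity[1L], tab$specificity[2L], tolerance = 1e-10)
})

test_that("Monte-Carlo draws reproduce the quadrature indices", {
  g <- groupItemParameters("sex")
  model <- makeGroupModel(g$reference, g$focal, groups = unname(g$labels),
                          mu = -0.2)
  cp <- latentCutpoint(TRUTH, cut = 1)
  grid <- quadratureGrid(401L, c(-9, 9))
  for (v in c("expected", "probabilistic")) {
    ix <- indicesTable(classificationIndices(model, cp, mode = "integration",
                                             variant = v, grid = grid))
    set.seed(81)
    mc <- indicesTable(classificationIndices(model, cp, mode = "montecarlo",
                                             variant = v, grid = grid,
                                             nMC = 1e5))
    cols <- c("sensitivity", "specificity", "classificationRate")
    expect_lt(max(abs(as.matrix(ix[cols]) - as.matrix(mc[cols]))), 0.01)
  }
})

test_that("strong uniform DIF moves focal specificity away from the no-DIF difference", {
  difFoc <- TRUTH
  shift <- difFoc@items %in% c("SC20", "SC21", "SC26")
  difFoc <- itemParameters(difFoc@items, difFoc@a,
                           difFoc@b + ifelse(shift, -1, 0))
  cp <- latentCutpoint(TRUTH, cut = 1)
  free <- classificationIndices(makeGroupModel(TRUTH, TRUTH), cp,
                                mode = "integration", variant = "probabilistic")
  dif <- classificationIndices(makeGroupModel(TRUTH, difFoc), cp,
                               mode = "integration", variant = "probabilistic")
  cmpNull <- compareModels(free, free)
  cmpDif <- compareModels(free, dif)
  focalSpec <- function(cmp) cmp$difference[cmp$index == "Spec"][2L]
  expect_gt(abs(focalSpec(cmpDif)), abs(focalSpec(cmpNull)))
  # arithmetic consistency: differences equal independent subtraction
  expect_equal(cmpDif$difference, cmpDif$ignoring - cmpDif$accounting)
})

test_that("empirical mode validates its inputs", {
  model <- makeGroupModel(TRUTH, TRUTH)
  cp <- latentCutpoint(TRUTH, cut = 1)
  expect_error(classificationIndices(model, cp, mode = "empirical"),
               "requires the response data")
  other <- makeGroupModel(TRUTH, TRUTH, groups = c("x", "y"))
  i1 <- classificationIndices(model, cp, mode = "integration")
  i2 <- classificationIndices(other, cp, mode = "integration")
  expect_error(compareModels(i1, i2), "different groups")
})
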