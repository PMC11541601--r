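# Anchor purification and formal DIF testing: null behaviour, power,
# the all-flagged fallback, BH adjustment and symmetry.

test_that("under the null the sweep flags at about the nominal rate and anchors stay large", {
  reps <- 8L
  out <- vapply(seq_len(reps), function(r) {
    pur <- purifyAnchors(nullGroupData(10000, seed = 700 + r))
    c(flags = sum(pur$sweep$flagged), anchors = length(pur$anchors))
  }, numeric(2L))
  # nine unadjusted tests at alpha = 0.05: ~0.45 expected flags/replicate
  expect_lt(mean(out["flags", ]), 2)
  expect_true(all(out["anchors", ] >= 3))
  expect_gt(mean(out["flags", ] == 0), 0.25)
})

test_that("an item with a strong difficulty offset is excluded from the anchors", {
  hits <- vapply(1:5, function(r) {
    cfg <- simulationConfig(n = 20000,
                            dif = data.frame(item = "SC23", parameter = "b",
                                             offset = 0.8), seed = 710 + r)
    pur <- purifyAnchors(simulateResponses(cfg))
    !"SC23" %in% pur$anchors
  }, logical(1L))
  expect_true(all(hits))
})

test_that("when every item flags, exactly the three smallest BIC differences anchor", {
  dif <- data.frame(item = TRUTH@items, parameter = "b",
                    offset = rep(c(0.5, -0.5), length.out = 9L))
  cfg <- simulationConfig(n = 20000, dif = dif, seed = 72)
  pur <- purifyAnchors(simulateResponses(cfg))
  expect_true(all(pur$sweep$flagged))
  expect_length(pur$anchors, 3L)
  ord <- order(pur$sweep$bicDiff)
  expect_setequal(pur$anchors, pur$sweep$item[ord[1:3]])
})

test_that("identical groups give zero LR statistics, unit p-values and no flags", {
  Y <- responses(simulateResponses(simulationConfig(n = 2500, groups = "all",
                                                    seed = 73)))
  dup <- responseMatrix(rbind(Y, Y), group = rep(c("g1", "g2"), each = 2500L))
  dt <- testDif(dup, anchors = c("SC20", "SC21", "SC26"),
                control = list(tol = 1e-6))
  expect_lt(max(difTable(dt)$lr), 1e-3)
  expect_gt(min(difTable(dt)$p), 0.999)
  expect_false(any(difTable(dt)$flag))
})

test_that("BH adjustment is the step-up rule and reduces to the raw p when m = 1", {
  p <- c(0.005, 0.01, 0.02, 0.03, 0.04, 0.20)
  # closed-form step-up: p_(i) * m / i, cumulative minimum from the top
  m <- length(p)
  byHand <- rev(cummin(rev(p * m / seq_len(m))))
  expect_equal(byHand, c(0.03, 0.03, 0.04, 0.045, 0.048, 0.20))
  expect_equal(stats::p.adjust(p, "BH"), byHand)
  expect_equal(stats::p.adjust(0.03, "BH"), 0.03)
  # a fitted result's adjusted column obeys the same rule
  rm <- nullGroupData(3000, seed = 74)
  dt <- testDif(rm, anchors = itemNames(rm)[1:3])
  tab <- difTable(dt)
  expect_equal(tab$p_bh, stats::p.adjust(tab$p, "BH"))
  expect_true(all(tab$p_bh >= tab$p - 1e-12))
})

test_that("LR statistics are invariant to swapping the group labels", {
  rm <- nullGroupData(4000, seed = 75)
  grp <- groupLabels(rm)
  swapped <- responseMatrix(responses(rm),
                            group = factor(grp, levels = rev(levels(grp))))
  ctl <- list(tol = 1e-6)
  d1 <- testDif(rm, anchors = itemNames(rm)[1:3], control = ctl)
  d2 <- testDif(swapped, anchors = itemNames(rm)[1:3], control = ctl)
  expect_lt(max(abs(difTable(d1)$lr - difTable(d2)$lr)), 0.02)
})

test_that("detection strength increases with the size of the difficulty offset", {
  lrFor <- function(off, seeds) vapply(seeds, function(s) {
    cfg <- simulationConfig(n = 6000,
                            dif = data.frame(item = "SC22", parameter = "b",
                                             offset = off), seed = s)
    dt <- testDif(simulateResponses(cfg), anchors = c("SC20", "SC21", "SC26"))
    difTable(dt)$lr[difTable(dt)$item == "SC22"]
  }, numeric(1L))
  expect_gt(mean(lrFor(0.8, 761:763)), mean(lrFor(0.3, 761:763)))
})

test_that("anchored items cannot be tested and follow-ups localise the parameter", {
  rm <- nullGroupData(2000, seed = 77)
  expect_error(testDif(rm, anchors = c("SC20", "nope")), "unknown anchor")
  expect_error(difFollowUp(rm, anchors = itemNames(rm)[1:3],
                           item = "SC20"), "non-anchor")
  cfg <- simulationConfig(n = 12000,
                          dif = data.frame(item = "SC22", parameter = "b",
                                           offset = 0.6), seed = 78)
  fu <- difFollowUp(simulateResponses(cfg),
                    anchors = c("SC20", "SC21", "SC26"), item = "SC22")
  expect_lt(fu$p[fu$parameter == "b"], 0.01)
  expect_gt(fu$lr[fu$parameter == "b"], fu$lr[fu$parameter == "a"])
})
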