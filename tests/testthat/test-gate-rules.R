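# The rule compiler: exhaustive truth tables, negative-answer handling and
# input validation.

CATS <- c("Yes", "No", "Don't know", "Refused")

# Hand-coded truth tables, written directly from the interview's screening
# logic as plain predicates over "is the answer Yes".
handCoded <- list(
  SC20 = function(y) y["SC20"] || y["SC20a"],
  SC21 = function(y) y[["SC21"]],
  SC22 = function(y) y[["SC22"]],
  SC23 = function(y) y[["SC23"]],
  SC24 = function(y) y[["SC24"]],
  SC25 = function(y) y["SC25"] && y["SC25a"],
  SC26 = function(y) y["SC26"] || y["SC26a"] || y["SC26b"],
  SC29 = function(y) (y["SC29"] || y["SC29a"]) &&
    (y["SC29.1"] || y["SC29.2"]) && y["SC29.3"],
  SC30 = function(y) y["SC30"] && (y["SC30.1"] || y["SC30.2"]) && y["SC30.3"]
)

ruleQuestions <- list(
  SC20 = c("SC20", "SC20a"), SC21 = "SC21", SC22 = "SC22", SC23 = "SC23",
  SC24 = "SC24", SC25 = c("SC25", "SC25a"),
  SC26 = c("SC26", "SC26a", "SC26b"),
  SC29 = c("SC29", "SC29a", "SC29.1", "SC29.2", "SC29.3"),
  SC30 = c("SC30", "SC30.1", "SC30.2", "SC30.3")
)

test_that("every rule matches its hand-coded truth table over exhaustive answer patterns", {
  for (rule in names(handCoded)) {
    qs <- ruleQuestions[[rule]]
    combos <- expand.grid(rep(list(CATS), length(qs)),
                          stringsAsFactors = FALSE)
    names(combos) <- qs
    raw <- rawRow("No")[rep(1L, nrow(combos)), , drop = FALSE]
    raw[qs] <- combos
    got <- responses(encodeScreeningRules(raw))[, rule]
    want <- vapply(seq_len(nrow(combos)), function(i) {
      y <- stats::setNames(rep(FALSE, 20L), gateQuestionNames())
      y[qs] <- unlist(combos[i, ]) == "Yes"
      as.integer(handCoded[[rule]](y))
    }, integer(1L))
    expect_identical(got, want, label = paste("rule", rule))
  }
})

test_that("screen-out clauses treat Don't know and Refused exactly as No", {
  raw <- rbind(
    rawRow("No"), rawRow("Don't know"), rawRow("Refused"),
    rawRow("No", SC25 = "Yes", SC25a = "Don't know"),
    rawRow("Refused", SC20 = "Don't know", SC20a = "Yes"),
    rawRow("No", SC21 = "Yes"))
  out <- responses(encodeScreeningRules(raw))
  expect_equal(unname(rowSums(out[1:3, ])), c(0, 0, 0))   # no positive gate
  expect_equal(unname(out[4, "SC25"]), 0L)                # both probes needed
  expect_equal(unname(out[5, "SC20"]), 1L)                # either panic question
  expect_equal(unname(out[6, ]), c(0L, 1L, 0L, 0L, 0L, 0L, 0L, 0L, 0L))
})

test_that("rule encoding is deterministic and total", {
  set.seed(42)
  raw <- rawRow("No")[rep(1L, 50L), ]
  for (q in gateQuestionNames())
    raw[[q]] <- sample(CATS, 50L, replace = TRUE)
  expect_identical(responses(encodeScreeningRules(raw)),
                   responses(encodeScreeningRules(raw)))
})

test_that("unknown questions and categories are rejected with informative errors", {
  raw <- rawRow("No")
  expect_error(encodeScreeningRules(raw[, -1L]), "missing gate question")
  bad <- rawRow("No"); bad$SC22 <- "Maybe"
  expect_error(encodeScreeningRules(bad), "SC22.*row 1")
  ruleset <- screeningRules()
  expect_error(new("ScreeningRuleSet",
                   rules = c(ruleset@rules[-1L], list(XX = quote(NOPE))),
                   questions = ruleset@questions),
               "undeclared")
})

test_that("simulated raw gate tables compile back to their generating rules", {
  cfg <- simulationConfig(n = 400, groups = "all", seed = 31)
  raw <- simulateRawGateResponses(cfg, dkRate = 0.1)
  expect_identical(responses(encodeScreeningRules(raw)),
                   responses(attr(raw, "rules")))
})
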