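# Shared fixtures and independent oracles for the test suite. Oracles are
# written as plain enumeration/integration code, independent of the
# package's internal computation paths.

# Published total-sample 2PL table used as simulation truth throughout.
TRUTH <- referenceItemParameters()

# All 2^J binary response patterns (rows).
enumPatterns <- function(J) as.matrix(expand.grid(rep(list(0:1), J)))

# Brute-force marginal log-likelihood of a response matrix under a 2PL
# parameter set: enumerate every pattern, integrate its probability over
# the quadrature grid, multiply by observed counts.
bruteMarginalLogLik <- function(Y, params, grid = quadratureGrid()) {
  J <- ncol(Y)
  pats <- enumPatterns(J)
  P <- sapply(seq_len(J), function(j)
    icc2pl(grid@nodes, params@a[j], params@b[j]))
  lik <- apply(pats, 1L, function(y) {
    cond <- rep(1, length(grid@nodes))
    for (j in seq_len(J)) cond <- cond * (if (y[j] == 1) P[, j] else 1 - P[, j])
    sum(grid@weights * cond)
  })
  key <- apply(Y, 1L, paste, collapse = "")
  pkey <- apply(pats, 1L, paste, collapse = "")
  cnt <- as.numeric(table(factor(key, levels = pkey)))
  sum(cnt * log(lik))
}

# Brute-force summed-score pmf at one theta by pattern enumeration.
bruteSumScorePmf <- function(theta, params) {
  J <- length(params@a)
  pats <- enumPatterns(J)
  p <- icc2pl(theta, params@a, params@b)
  prob <- apply(pats, 1L, function(y) prod(ifelse(y == 1, p, 1 - p)))
  vapply(0:J, function(s) sum(prob[rowSums(pats) == s]), numeric(1L))
}

# GroupModel built directly from known truth (no fitting).
makeGroupModel <- function(ref, focal, groups = c("reference", "focal"),
                           mu = 0, v = 1) {
  anchored <- stats::setNames(ref@a == focal@a & ref@b == focal@b, ref@items)
  new("GroupModel", groups = groups, refParams = ref, focalParams = focal,
      anchored = anchored, focalMean = mu, focalVar = v,
      momentsEstimated = any(anchored),
      fit = new("FitSummary", logLik = NA_real_, nParameters = 0L, n = 0L,
                converged = TRUE, nIterations = 0L, logLikTrace = numeric()))
}

# A raw gate-response row with every question set to `default`.
rawRow <- function(default = "No", ...) {
  row <- as.list(stats::setNames(rep(default, 20L), gateQuestionNames()))
  over <- list(...)
  row[names(over)] <- over
  as.data.frame(row, check.names = FALSE, stringsAsFactors = FALSE)
}

# Two-group no-DIF response data from the published truth.
nullGroupData <- function(n, seed, groups = c("ref", "foc"))
  simulateResponses(simulationConfig(n = n, groups = groups, seed = seed))
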