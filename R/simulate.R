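# Synthetic multigroup binary item responses with known 2PL truth and
# injectable DIF. All randomness is driven by an explicit seed held in the
# configuration; the global RNG state is saved and restored.

# Evaluate expr under a local RNG seeded with `seed`.
.withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' Build a simulation configuration
#'
#' Assembles and validates the truth for [simulateResponses()]. Defaults
#' reproduce the published study conditions: the total-sample item
#' parameters as the reference truth, an even two-group split, equal
#' standard-normal latent distributions, and no injected DIF.
#'
#' @param n number of respondents.
#' @param groups group labels, reference first; give a single label for
#'   single-group data.
#' @param proportions group proportions (summing to 1).
#' @param refParams reference-group [ItemParameters-class];
#'   [referenceItemParameters()] by default.
#' @param focalParams focal-group truth before `dif` offsets; defaults to
#'   `refParams` (no DIF).
#' @param focalMean,focalVar focal latent moments (reference is N(0, 1)).
#' @param dif injected DIF: data.frame with columns `item`,
#'   `parameter` ("a" or "b") and `offset`, added to the focal group's
#'   parameter.
#' @param seed integer seed; required for reproducibility.
#' @return A [SimulationConfig-class].
#' @examples
#' cfg <- simulationConfig(n = 1000, dif = data.frame(
#'   item = "SC21", parameter = "b", offset = 0.8), seed = 1)
#' cfg
#' @export
simulationConfig <- function(n, groups = c("reference", "focal"),
                             proportions = NULL,
                             refParams = referenceItemParameters(),
                             focalParams = refParams,
                             focalMean = 0, focalVar = 1,
                             dif = NULL, seed) {
  if (length(n) != 1L || !is.finite(n) || n < 1)
    stop("validation error: n must be a positive count")
  if (missing(seed)) stop("an explicit integer seed is required")
  if (is.null(proportions))
    proportions <- rep(1 / length(groups), length(groups))
  if (is.null(dif))
    dif <- data.frame(item = character(), parameter = character(),
                      offset = numeric())
  focal <- focalParams
  if (nrow(dif)) {
    a <- focal@a; b <- focal@b
    for (k in seq_len(nrow(dif))) {
      j <- match(dif$item[k], focal@items)
      if (is.na(j)) stop("dif offset names unknown item: ", dif$item[k])
      if (dif$parameter[k] == "a") a[j] <- a[j] + dif$offset[k]
      else b[j] <- b[j] + dif$offset[k]
    }
    focal <- itemParameters(focal@items, a, b, focal@D)
  }
  new("SimulationConfig", n = as.integer(n), groups = as.character(groups),
      proportions = as.numeric(proportions), refParams = refParams,
      focalParams = focal, focalMean = as.numeric(focalMean),
      focalVar = as.numeric(focalVar), dif = dif, seed = as.integer(seed))
}

#' Simulate binary item responses under the 2PL model
#'
#' Draws each respondent's latent trait from their group's normal
#' distribution and each item response as a Bernoulli with the group's
#' 2PL endorsement probability. Fully reproducible given the config seed.
#'
#' @param config a [SimulationConfig-class].
#' @param returnTheta also attach the true latent values as attribute
#'   `"theta"` (used by simulation diagnostics).
#' @return A [ResponseMatrix-class]; with a group factor when the config
#'   has two groups.
#' @examples
#' cfg <- simulationConfig(n = 200, seed = 42)
#' simulateResponses(cfg)
#' @export
simulateResponses <- function(config, returnTheta = FALSE) {
  stopifnot(is(config, "SimulationConfig"))
  .withSeed(config@seed, {
    n <- config@n
    twoGroup <- length(config@groups) == 2L
    if (twoGroup) {
      gi <- stats::rbinom(n, 1L, config@proportions[2L])  # 1 = focal
      theta <- ifelse(gi == 1L,
                      stats::rnorm(n, config@focalMean, sqrt(config@focalVar)),
                      stats::rnorm(n))
    } else {
      gi <- rep(0L, n)
      theta <- stats::rnorm(n)
    }
    J <- length(config@refParams@items)
    P <- matrix(0, n, J)
    refIdx <- gi == 0L
    for (j in seq_len(J)) {
      P[refIdx, j] <- icc2pl(theta[refIdx], config@refParams@a[j],
                             config@refParams@b[j])
      if (any(!refIdx))
        P[!refIdx, j] <- icc2pl(theta[!refIdx], config@focalParams@a[j],
                                config@focalParams@b[j])
    }
    Y <- matrix(as.integer(stats::runif(n * J) < P), n, J,
                dimnames = list(NULL, config@refParams@items))
    grp <- if (twoGroup)
      factor(config@groups[gi + 1L], levels = config@groups) else NULL
    out <- responseMatrix(Y, group = grp)
    if (returnTheta) attr(out, "theta") <- theta
    out
  })
}

#' Model-implied marginal endorsement rates
#'
#' Endorsement probability of each item after integrating the ICC against
#' a normal latent distribution (by quadrature). Useful as the analytic
#' counterpart of simulated endorsement rates.
#'
#' @param params an [ItemParameters-class].
#' @param mean,var latent moments.
#' @param grid a [QuadratureGrid-class].
#' @return Named vector of probabilities.
#' @export
marginalEndorsement <- function(params, mean = 0, var = 1,
                                grid = quadratureGrid(201L, c(-9, 9))) {
  w <- .normalWeights(grid@nodes, mean, var)
  p <- vapply(seq_along(params@items), function(j)
    sum(w * icc2pl(grid@nodes, params@a[j], params@b[j])), numeric(1L))
  stats::setNames(p, params@items)
}

#' Simulate raw gate-question answer tables
#'
#' Generates a categorical answer table consistent with a target pattern of
#' screening-rule outcomes: for each respondent a rule outcome is drawn
#' from the 2PL truth, then a raw answer pattern realising that outcome is
#' sampled uniformly from the patterns compatible with it. Intended for
#' exercising the rule compiler end to end; "Don't know"/"Refused" answers
#' are sprinkled among the negative answers at rate `dkRate`.
#'
#' @param config a [SimulationConfig-class] (single- or two-group).
#' @param dkRate probability that a negative answer is recorded as
#'   "Don't know" or "Refused" rather than "No".
#' @return data.frame of categorical answers, one column per gate question,
#'   with the generating [ResponseMatrix-class] attached as attribute
#'   `"rules"`.
#' @export
simulateRawGateResponses <- function(config, dkRate = 0.05) {
  rm <- simulateResponses(config)
  Y <- responses(rm)
  qn <- gateQuestionNames()
  .withSeed(config@seed + 1L, {
    n <- nrow(Y)
    raw <- as.data.frame(matrix("No", n, length(qn),
                                dimnames = list(NULL, qn)),
                         stringsAsFactors = FALSE)
    fillYes <- function(col, idx) { raw[idx, col] <<- "Yes"; invisible() }
    # single-question rules
    for (r in c("SC21", "SC22", "SC23", "SC24")) fillYes(r, Y[, r] == 1L)
    # SC20: either panic question; choose one (or both) at random
    i <- which(Y[, "SC20"] == 1L)
    pick <- sample(1:3, length(i), replace = TRUE)   # 1: SC20, 2: SC20a, 3: both
    fillYes("SC20", i[pick != 2L]); fillYes("SC20a", i[pick != 1L])
    # SC25: both probes required
    i <- which(Y[, "SC25"] == 1L)
    fillYes("SC25", i); fillYes("SC25a", i)
    # SC26: at least one of three probes
    i <- which(Y[, "SC26"] == 1L)
    for (k in seq_along(i)) {
      on <- sample(c(TRUE, FALSE, FALSE), 3L)
      if (!any(on)) on[1L] <- TRUE
      for (q in c("SC26", "SC26a", "SC26b")[on]) raw[i[k], q] <- "Yes"
    }
    # SC29 / SC30: fear question(s) + (upset or avoid) + excessive
    i <- which(Y[, "SC29"] == 1L)
    fillYes(sample(c("SC29", "SC29a"), 1L), i)
    fillYes(sample(c("SC29.1", "SC29.2"), 1L), i)
    fillYes("SC29.3", i)
    i <- which(Y[, "SC30"] == 1L)
    fillYes("SC30", i)
    fillYes(sample(c("SC30.1", "SC30.2"), 1L), i)
    fillYes("SC30.3", i)
    # replace some negatives with Don't know / Refused
    for (q in qn) {
      neg <- which(raw[[q]] == "No")
      flip <- neg[stats::runif(length(neg)) < dkRate]
      raw[flip, q] <- sample(c("Don't know", "Refused"), length(flip),
                             replace = TRUE)
    }
    attr(raw, "rules") <- rm
    raw
  })
}
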