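# Impact of DIF on screening decisions: map the sum-score cut to the
# latent trait through the test characteristic curve, then compare
# sensitivity, specificity and classification rate per group between a
# DIF-free and a DIF-adjusted measurement model.

#' Map a sum-score cut to the latent trait
#'
#' Finds the unique latent value where the test characteristic curve
#' reaches the expected-score threshold: t = c - 0.5 under the midpoint
#' convention (expected-score rounding) or t = c under the strict
#' convention. Solved by bisection to |TCC(theta*) - t| < 1e-10.
#'
#' @param params an [ItemParameters-class] (typically the pooled DIF-free
#'   parameters).
#' @param cut observed sum-score cut c (screen in when X >= c).
#' @param convention "midpoint" (default) or "strict".
#' @return A [ScreeningCutpoint-class].
#' @examples
#' latentCutpoint(referenceItemParameters(), cut = 1)
#' @export
latentCutpoint <- function(params, cut = 1,
                           convention = c("midpoint", "strict")) {
  stopifnot(is(params, "ItemParameters"))
  convention <- match.arg(convention)
  J <- length(params@items)
  if (cut <= 0 || cut > J) stop("validation error: cut must be in (0, J]")
  t <- if (convention == "midpoint") cut - 0.5 else cut
  if (t <= 0 || t >= J)
    stop("validation error: expected-score threshold t must lie in (0, J)")
  lo <- -40; hi <- 40
  repeat {
    mid <- (lo + hi) / 2
    f <- tcc(mid, params) - t
    if (abs(f) < 1e-10 || (hi - lo) < 1e-14) break
    if (f > 0) hi <- mid else lo <- mid
  }
  new("ScreeningCutpoint", cut = cut, t = t, thetaStar = mid,
      convention = convention)
}

# Solve TCC_g(theta) = t for one group's parameters (same bisection).
.groupCut <- function(params, t) {
  lo <- -40; hi <- 40
  repeat {
    mid <- (lo + hi) / 2
    f <- tcc(mid, params) - t
    if (abs(f) < 1e-10 || (hi - lo) < 1e-14) break
    if (f > 0) hi <- mid else lo <- mid
  }
  mid
}

#' Screening classification accuracy under a measurement model
#'
#' Classifies each group against the latent cut-point theta* and the
#' observed screening decision, under the supplied multigroup model.
#'
#' In `empirical` mode each respondent receives an EAP score under their
#' group's parameters and latent prior; the expected observed score is the
#' group's TCC at that score. Sensitivity is the proportion of respondents
#' at or above theta* whose expected score meets the threshold t;
#' specificity the proportion below theta* whose expected score falls
#' short; the classification rate is the overall concordance. In
#' `integration` mode the empirical score distribution is replaced by the
#' group's latent normal density. `montecarlo` mode estimates the same
#' quantities as `integration` from random latent draws (a cross-check of
#' the quadrature, agreeing within Monte-Carlo error); because EAP scores
#' are discrete over response patterns, `empirical` indices can instead
#' sit a few percentage points from the `integration` ones — see the
#' methods vignette.
#'
#' The `expected` variant uses the indicator on the expected score (the
#' group TCC crossing t); the `probabilistic` variant replaces it with the
#' exact summed-score probability P(X >= c | theta) from the
#' Lord-Wingersky recursion, which reflects the Bernoulli noise of the
#' screening decision itself.
#'
#' @param model a [GroupModel-class]. For the DIF-free variant fit the
#'   model with every item anchored (and, for a standard-normal prior in
#'   all groups, `estimateMoments = FALSE`).
#' @param cutpoint a [ScreeningCutpoint-class], computed once from the
#'   DIF-free model and reused for both variants.
#' @param mode "empirical" (default; requires `data`), "integration" or
#'   "montecarlo".
#' @param data the [ResponseMatrix-class] used to fit the model
#'   (empirical mode).
#' @param variant "expected" (default) or "probabilistic".
#' @param grid a [QuadratureGrid-class] for EAP scoring and integration.
#' @param nMC latent draws per group in montecarlo mode (seed the RNG
#'   outside for reproducibility).
#' @return A [ClassificationIndices-class] with one row per group.
#' @export
classificationIndices <- function(model, cutpoint,
                                  mode = c("empirical", "integration",
                                           "montecarlo"),
                                  data = NULL,
                                  variant = c("expected", "probabilistic"),
                                  grid = quadratureGrid(101L, c(-8, 8)),
                                  nMC = 1e6) {
  stopifnot(is(model, "GroupModel"), is(cutpoint, "ScreeningCutpoint"))
  mode <- match.arg(mode)
  variant <- match.arg(variant)
  if (mode == "empirical" && is.null(data))
    stop("validation error: empirical mode requires the response data")
  thetaStar <- cutpoint@thetaStar
  t <- cutpoint@t
  rows <- vector("list", 2L)
  for (g in 1:2) {
    pars <- if (g == 1L) model@refParams else model@focalParams
    mu <- if (g == 1L) 0 else model@focalMean
    v <- if (g == 1L) 1 else model@focalVar
    cutG <- .groupCut(pars, t)
    if (mode == "empirical") {
      grp <- groupLabels(data)
      if (nlevels(grp) != 2L || !identical(levels(grp), model@groups))
        stop("validation error: data groups do not match the model")
      sub <- responseMatrix(responses(data)[grp == model@groups[g], , drop = FALSE])
      eap <- eapScores(sub, pars, grid, mean = mu, var = v)@eap
      above <- eap >= thetaStar
      if (variant == "expected") {
        inPred <- eap >= cutG   # equivalent to TCC_g(eap) >= t (TCC monotone)
        sens <- mean(inPred[above])
        spec <- mean(!inPred[!above])
        rate <- mean(inPred == above)
      } else {
        pg <- cutExceedanceProb(eap, pars, cutpoint@cut)
        sens <- mean(pg[above])
        spec <- mean(1 - pg[!above])
        rate <- (sum(pg[above]) + sum(1 - pg[!above])) / length(eap)
      }
      prop <- mean(above)
    } else if (mode == "montecarlo") {
      th <- stats::rnorm(nMC, mu, sqrt(v))
      above <- th >= thetaStar
      if (variant == "expected") {
        inPred <- th >= cutG
        sens <- mean(inPred[above])
        spec <- mean(!inPred[!above])
      } else {
        # interpolate P(X >= c | theta) from the grid (piecewise linear)
        pgGrid <- cutExceedanceProb(grid@nodes, pars, cutpoint@cut)
        pg <- stats::approx(grid@nodes, pgGrid, xout = th, rule = 2)$y
        sens <- mean(pg[above])
        spec <- mean(1 - pg[!above])
      }
      prop <- mean(above)
      rate <- sens * prop + spec * (1 - prop)
    } else {
      sd <- sqrt(v)
      prop <- stats::pnorm(thetaStar, mu, sd, lower.tail = FALSE)
      if (variant == "expected") {
        sens <- stats::pnorm(max(thetaStar, cutG), mu, sd, lower.tail = FALSE) / prop
        spec <- stats::pnorm(min(thetaStar, cutG), mu, sd) / (1 - prop)
      } else {
        nodes <- grid@nodes
        w <- .normalWeights(nodes, mu, v)
        pg <- cutExceedanceProb(nodes, pars, cutpoint@cut)
        hi <- nodes >= thetaStar
        sens <- sum(w[hi] * pg[hi]) / sum(w[hi])
        spec <- sum(w[!hi] * (1 - pg[!hi])) / sum(w[!hi])
      }
      rate <- sens * prop + spec * (1 - prop)
    }
    rows[[g]] <- data.frame(group = model@groups[g], sensitivity = sens,
                            specificity = spec, classificationRate = rate,
                            propAbove = prop)
  }
  new("ClassificationIndices", table = do.call(rbind, rows),
      cut = cutpoint, mode = mode, variant = variant)
}

#' Compare classification accuracy between model variants
#'
#' Differences (ignoring DIF minus accounting for DIF) in sensitivity,
#' specificity and classification rate, per group.
#'
#' @param ignoring [ClassificationIndices-class] from the DIF-free model.
#' @param accounting [ClassificationIndices-class] from the DIF model.
#' @return data.frame: group, index, ignoring, accounting, difference.
#' @export
compareModels <- function(ignoring, accounting) {
  stopifnot(is(ignoring, "ClassificationIndices"),
            is(accounting, "ClassificationIndices"))
  ti <- ignoring@table; ta <- accounting@table
  if (!identical(ti$group, ta$group))
    stop("validation error: the two variants cover different groups")
  if (abs(ignoring@cut@thetaStar - accounting@cut@thetaStar) > 1e-12 ||
      ignoring@cut@cut != accounting@cut@cut)
    stop("validation error: the two variants use different cut-points")
  idx <- c(sensitivity = "Sens", specificity = "Spec",
           classificationRate = "Classification rate")
  out <- do.call(rbind, lapply(names(idx), function(col) {
    data.frame(group = ti$group, index = idx[[col]],
               ignoring = ti[[col]], accounting = ta[[col]],
               difference = ti[[col]] - ta[[col]])
  }))
  rownames(out) <- NULL
  out
}

#' Wide impact report
#'
#' Reshapes a [compareModels()] result into the conventional layout:
#' one row per index (Sens, Spec, Classification rate), column blocks for
#' the model ignoring DIF, the model accounting for DIF, and their
#' difference, one column per group within each block. Values are rounded
#' to 3 decimals.
#'
#' @param comparison output of [compareModels()].
#' @return data.frame in wide layout.
#' @export
impactTable <- function(comparison) {
  groups <- unique(comparison$group)
  idxOrder <- c("Sens", "Spec", "Classification rate")
  out <- data.frame(index = idxOrder)
  for (block in c("ignoring", "accounting", "difference")) {
    for (g in groups) {
      v <- vapply(idxOrder, function(ix)
        comparison[[block]][comparison$group == g & comparison$index == ix],
        numeric(1L))
      out[[paste(block, g, sep = "_")]] <- round(v, 3)
    }
  }
  out
}
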