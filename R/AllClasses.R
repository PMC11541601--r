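#' @import methods
NULL

#' Respondent-by-item binary response data
#'
#' Container for dichotomous screening-rule outcomes (1 = screen in,
#' 0 = screen out), optionally with a two-level grouping factor used for
#' multigroup estimation and DIF testing. Missing responses are allowed and
#' are dropped from the corresponding item's likelihood contribution.
#'
#' @slot responses integer matrix, respondents in rows, items in columns;
#'   entries 0, 1 or NA; column names are the item identifiers.
#' @slot group factor of length `nrow(responses)` (or length 0 for
#'   single-group data); the first level is the reference group.
#'
#' @seealso [responseMatrix()], [simulateResponses()], [encodeScreeningRules()]
#' @export
setClass("ResponseMatrix",
  representation(responses = "matrix", group = "factor"),
  validity = function(object) {
    r <- object@responses
    msg <- character()
    if (is.null(colnames(r)) || anyDuplicated(colnames(r)))
      msg <- c(msg, "responses must have unique column names (item identifiers)")
    vals <- r[!is.na(r)]
    if (length(vals) && !all(vals %in% c(0L, 1L)))
      msg <- c(msg, "responses must be 0, 1 or NA")
    if (length(object@group) && length(object@group) != nrow(r))
      msg <- c(msg, "group must have one label per respondent")
    if (length(msg)) msg else TRUE
  }
)

#' Two-parameter logistic item parameters
#'
#' Discrimination (a, logistic slope) and difficulty (b, latent-trait
#' location where the endorsement probability is 0.5) for a set of binary
#' items, together with the scaling constant D bridging the logistic and
#' normal-ogive metrics. Standardised factor loadings
#' \eqn{\lambda = (a/D)/\sqrt{1 + (a/D)^2}} and communalities
#' \eqn{h^2 = \lambda^2} are derived, not stored.
#'
#' @slot items character vector of item identifiers.
#' @slot a numeric vector of discriminations, strictly positive.
#' @slot b numeric vector of difficulties, finite.
#' @slot D scaling constant (default 1.702).
#'
#' @seealso [itemParameters()], [itemLoadings()], [referenceItemParameters()]
#' @export
setClass("ItemParameters",
  representation(items = "character", a = "numeric", b = "numeric", D = "numeric"),
  prototype(D = 1.702),
  validity = function(object) {
    msg <- character()
    n <- length(object@items)
    if (length(object@a) != n || length(object@b) != n)
      msg <- c(msg, "items, a and b must have equal length")
    if (anyDuplicated(object@items))
      msg <- c(msg, "item identifiers must be unique")
    if (any(!is.finite(object@a)) || any(object@a <= 0))
      msg <- c(msg, "discriminations a must be finite and > 0")
    if (any(!is.finite(object@b)))
      msg <- c(msg, "difficulties b must be finite")
    if (length(object@D) != 1L || !is.finite(object@D) || object@D <= 0)
      msg <- c(msg, "D must be a single positive number")
    if (length(msg)) msg else TRUE
  }
)

#' Fixed quadrature grid for marginal likelihood integration
#'
#' @slot nodes strictly increasing latent-trait evaluation points.
#' @slot weights probability masses summing to 1 (within 1e-10).
#' @seealso [quadratureGrid()]
#' @export
setClass("QuadratureGrid",
  representation(nodes = "numeric", weights = "numeric"),
  validity = function(object) {
    msg <- character()
    if (length(object@nodes) != length(object@weights))
      msg <- c(msg, "nodes and weights must have equal length")
    if (is.unsorted(object@nodes, strictly = TRUE))
      msg <- c(msg, "nodes must be strictly increasing")
    if (abs(sum(object@weights) - 1) > 1e-10)
      msg <- c(msg, "weights must sum to 1 within 1e-10")
    if (any(object@weights < 0))
      msg <- c(msg, "weights must be non-negative")
    if (length(msg)) msg else TRUE
  }
)

#' Marginal-likelihood fit summary
#'
#' @slot logLik maximised marginal log-likelihood.
#' @slot nParameters number of free parameters.
#' @slot n number of respondents.
#' @slot converged logical; FALSE when the EM iteration cap was reached or a
#'   slope diverged to the cap.
#' @slot nIterations EM cycles used.
#' @slot logLikTrace per-cycle observed-data log-likelihood (non-decreasing).
#' @export
setClass("FitSummary",
  representation(logLik = "numeric", nParameters = "integer", n = "integer",
                 converged = "logical", nIterations = "integer",
                 logLikTrace = "numeric")
)

#' Single-group 2PL fit
#'
#' @slot params fitted [ItemParameters-class].
#' @slot fit [FitSummary-class].
#' @seealso [fit2pl()]
#' @export
setClass("TwoPLFit",
  representation(params = "ItemParameters", fit = "FitSummary"))

#' Expected a posteriori latent-trait scores
#'
#' @slot eap posterior mean of the latent trait per respondent.
#' @slot psd posterior standard deviation per respondent.
#' @seealso [eapScores()]
#' @export
setClass("LatentScore",
  representation(eap = "numeric", psd = "numeric"),
  validity = function(object) {
    msg <- character()
    if (length(object@eap) != length(object@psd))
      msg <- c(msg, "eap and psd must have equal length")
    if (any(!is.finite(object@eap)))
      msg <- c(msg, "EAP estimates must be finite")
    if (any(object@psd <= 0))
      msg <- c(msg, "posterior SDs must be > 0")
    if (length(msg)) msg else TRUE
  }
)

#' Multigroup 2PL model with equality constraints
#'
#' Joint two-group 2PL in which anchored items share parameters across
#' groups and free items have group-specific parameters. The reference
#' latent distribution is fixed standard normal; the focal mean and variance
#' are estimated whenever at least one item is anchored.
#'
#' @slot groups character(2): reference then focal group label.
#' @slot refParams [ItemParameters-class] for the reference group.
#' @slot focalParams [ItemParameters-class] for the focal group (identical
#'   entries for anchored items).
#' @slot anchored named logical vector per item.
#' @slot focalMean,focalVar focal-group latent moments.
#' @slot momentsEstimated logical; FALSE when the focal moments were fixed.
#' @slot fit [FitSummary-class].
#' @seealso [fitMultigroup()]
#' @export
setClass("GroupModel",
  representation(groups = "character", refParams = "ItemParameters",
                 focalParams = "ItemParameters", anchored = "logical",
                 focalMean = "numeric", focalVar = "numeric",
                 momentsEstimated = "logical", fit = "FitSummary"),
  validity = function(object) {
    msg <- character()
    if (length(object@groups) != 2L)
      msg <- c(msg, "exactly two groups (reference, focal) are supported")
    J <- length(object@refParams@items)
    if (length(object@anchored) != J || is.null(names(object@anchored)))
      msg <- c(msg, "anchored must be a named logical per item")
    if (!identical(object@refParams@items, object@focalParams@items))
      msg <- c(msg, "reference and focal parameter sets must cover the same items")
    anc <- which(object@anchored)
    if (length(anc) &&
        (any(abs(object@refParams@a[anc] - object@focalParams@a[anc]) > 1e-8) ||
         any(abs(object@refParams@b[anc] - object@focalParams@b[anc]) > 1e-8)))
      msg <- c(msg, "anchored items must have identical parameters across groups")
    if (object@focalVar <= 0)
      msg <- c(msg, "focal latent variance must be > 0")
    if (isTRUE(object@momentsEstimated) && !any(object@anchored))
      msg <- c(msg, "focal latent moments cannot be estimated without at least one anchor")
    if (length(msg)) msg else TRUE
  }
)

#' Formal DIF test results
#'
#' One likelihood-ratio test per non-anchor item of joint (a, b) equality
#' across groups, with Benjamini-Hochberg adjusted p-values.
#'
#' @slot table data.frame with columns item, lr, df, p, p_bh, flag.
#' @slot anchors character vector: the purified anchor set held equal.
#' @slot alpha significance level applied to adjusted p-values.
#' @slot sweep data.frame from the purification stage (empty if anchors were
#'   supplied directly).
#' @seealso [testDif()], [purifyAnchors()]
#' @export
setClass("DIFTestResult",
  representation(table = "data.frame", anchors = "character",
                 alpha = "numeric", sweep = "data.frame"),
  validity = function(object) {
    msg <- character()
    tb <- object@table
    need <- c("item", "lr", "df", "p", "p_bh", "flag")
    if (!all(need %in% names(tb)))
      msg <- c(msg, "table must have columns item, lr, df, p, p_bh, flag")
    else {
      if (any(tb$lr < -1e-8)) msg <- c(msg, "LR statistics must be non-negative")
      if (any(tb$p_bh + 1e-12 < tb$p)) msg <- c(msg, "adjusted p must be >= raw p")
    }
    if (!length(object@anchors)) msg <- c(msg, "anchor set must be non-empty")
    if (any(object@anchors %in% tb$item))
      msg <- c(msg, "anchored items cannot appear among tested items")
    if (length(msg)) msg else TRUE
  }
)

#' Pairwise tetrachoric correlation matrix
#'
#' @slot rho symmetric correlation matrix with unit diagonal.
#' @slot thresholds per-item normal threshold (qnorm of screen-out rate).
#' @slot flags symmetric logical matrix marking pairs that needed a
#'   continuity correction or boundary clamping.
#' @seealso [tetrachoric()], [tetrachoricMatrix()]
#' @export
setClass("TetrachoricMatrix",
  representation(rho = "matrix", thresholds = "numeric", flags = "matrix"),
  validity = function(object) {
    msg <- character()
    r <- object@rho
    if (nrow(r) != ncol(r) || max(abs(r - t(r))) > 1e-12)
      msg <- c(msg, "rho must be symmetric")
    if (max(abs(diag(r) - 1)) > 1e-12)
      msg <- c(msg, "rho must have unit diagonal")
    if (any(abs(r) > 1))
      msg <- c(msg, "correlations must lie in [-1, 1]")
    if (length(object@thresholds) != nrow(r))
      msg <- c(msg, "one threshold per item required")
    if (length(msg)) msg else TRUE
  }
)

#' One-factor CFA solution for binary indicators
#'
#' @slot loadings standardised loadings per item.
#' @slot h2 communalities (squared loadings).
#' @slot srmsr root mean square off-diagonal residual correlation.
#' @slot rmsea,cfi,tli global approximate-fit indices from a least-squares
#'   discrepancy against the independence baseline (estimator-dependent;
#'   see the methods vignette).
#' @slot itemRmsea per-item RMSEA from that item's residual row.
#' @slot discrepancy,df scaled discrepancy statistic and its degrees of freedom.
#' @slot n sample size the tetrachoric matrix was computed from.
#' @seealso [fitOneFactor()]
#' @export
setClass("CFAFit",
  representation(loadings = "numeric", h2 = "numeric", srmsr = "numeric",
                 rmsea = "numeric", cfi = "numeric", tli = "numeric",
                 itemRmsea = "numeric", discrepancy = "numeric",
                 df = "numeric", n = "integer")
)

#' Sum-score cut-point mapped to the latent trait
#'
#' @slot cut observed sum-score cut c (screen in when the score is >= c).
#' @slot t expected-score threshold: c - 0.5 under the midpoint convention,
#'   c under the strict convention.
#' @slot thetaStar unique latent value solving TCC(theta) = t.
#' @slot convention "midpoint" or "strict".
#' @seealso [latentCutpoint()]
#' @export
setClass("ScreeningCutpoint",
  representation(cut = "numeric", t = "numeric", thetaStar = "numeric",
                 convention = "character"))

#' Screening classification accuracy per group
#'
#' Sensitivity, specificity and classification rate of the observed
#' sum-score screen against the latent cut-point, per group, under one
#' model variant.
#'
#' @slot table data.frame with columns group, sensitivity, specificity,
#'   classificationRate, propAbove.
#' @slot cut the [ScreeningCutpoint-class] used.
#' @slot mode "empirical" or "integration".
#' @slot variant "expected" (indicator on the expected score) or
#'   "probabilistic" (Lord-Wingersky summed-score probabilities).
#' @seealso [classificationIndices()], [compareModels()]
#' @export
setClass("ClassificationIndices",
  representation(table = "data.frame", cut = "ScreeningCutpoint",
                 mode = "character", variant = "character"),
  validity = function(object) {
    tb <- object@table
    need <- c("group", "sensitivity", "specificity", "classificationRate")
    if (!all(need %in% names(tb)))
      return("table must have columns group, sensitivity, specificity, classificationRate")
    idx <- unlist(tb[, c("sensitivity", "specificity", "classificationRate")])
    if (any(idx < -1e-10 | idx > 1 + 1e-10, na.rm = TRUE))
      return("indices must lie in [0, 1]")
    TRUE
  }
)

#' Multigroup simulation configuration
#'
#' Truth for the synthetic-data generator: sample size, group split, latent
#' moments per group, per-group item parameters and optional injected DIF
#' offsets applied to the focal group.
#'
#' @slot n number of respondents.
#' @slot groups labels, reference first (length 1 for single-group data).
#' @slot proportions group proportions, summing to 1.
#' @slot refParams reference-group truth ([ItemParameters-class]).
#' @slot focalParams focal-group truth after applying `dif` offsets.
#' @slot focalMean,focalVar focal latent moments (reference fixed 0/1).
#' @slot dif data.frame (item, parameter, offset) of injected DIF.
#' @slot seed integer seed; generation is fully reproducible.
#' @seealso [simulationConfig()], [simulateResponses()]
#' @export
setClass("SimulationConfig",
  representation(n = "integer", groups = "character", proportions = "numeric",
                 refParams = "ItemParameters", focalParams = "ItemParameters",
                 focalMean = "numeric", focalVar = "numeric",
                 dif = "data.frame", seed = "integer"),
  validity = function(object) {
    msg <- character()
    if (object@n <= 0L) msg <- c(msg, "n must be positive")
    k <- length(object@groups)
    if (!k %in% 1:2) msg <- c(msg, "one or two groups are supported")
    if (length(object@proportions) != k ||
        any(object@proportions <= 0) || abs(sum(object@proportions) - 1) > 1e-8)
      msg <- c(msg, "proportions must be positive and sum to 1")
    if (object@focalVar <= 0) msg <- c(msg, "focal latent variance must be > 0")
    if (nrow(object@dif) &&
        !all(object@dif$item %in% object@refParams@items))
      msg <- c(msg, "dif offsets name unknown items")
    if (nrow(object@dif) && !all(object@dif$parameter %in% c("a", "b")))
      msg <- c(msg, "dif parameter must be \"a\" or \"b\"")
    if (length(msg)) msg else TRUE
  }
)

#' Compiled screening-rule definitions
#'
#' The nine dichotomous screening rules as boolean expressions over the
#' yes/no indicators of the gate questions. "No", "Don't know" and
#' "Refused" all evaluate as negative; screen-out is the complement of the
#' screen-in clause.
#'
#' @slot rules named list of unevaluated boolean expressions, one per rule,
#'   in rule order.
#' @slot questions declared gate-question identifiers the expressions may
#'   reference.
#' @seealso [screeningRules()], [encodeScreeningRules()]
#' @export
setClass("ScreeningRuleSet",
  representation(rules = "list", questions = "character"),
  validity = function(object) {
    msg <- character()
    if (length(object@rules) != 9L)
      msg <- c(msg, "exactly 9 screening rules are required")
    if (is.null(names(object@rules)) || anyDuplicated(names(object@rules)))
      msg <- c(msg, "rules must be uniquely named")
    used <- unique(unlist(lapply(object@rules, all.vars)))
    if (!all(used %in% object@questions))
      msg <- c(msg, paste("rule references undeclared question(s):",
                          paste(setdiff(used, object@questions), collapse = ", ")))
    if (length(msg)) msg else TRUE
  }
)
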