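#' Fit a constrained two-group 2PL model
#'
#' Joint marginal maximum likelihood over a reference and a focal group.
#' Anchored items share one (a, b) across groups; free items get
#' group-specific parameters. The reference latent distribution is fixed
#' standard normal; the focal mean and variance are estimated (by the EM
#' moment update of the focal posterior) whenever at least one item is
#' anchored, which identifies the common metric.
#'
#' @param data a [ResponseMatrix-class] with a two-level group factor
#'   (first level = reference).
#' @param anchored items held equal across groups: a character vector of
#'   item names, or a named logical over all items.
#' @param estimateMoments estimate the focal latent mean/variance
#'   (default: yes when any item is anchored). Requesting estimation with
#'   no anchors is an identification error.
#' @param grid a [QuadratureGrid-class].
#' @param control as in [fit2pl()]; also `minGroupN` (default 200), the
#'   smallest group size accepted.
#' @param partial optional named character vector giving partial equality
#'   constraints for non-anchored items: `"a"` (slope shared) or `"b"`
#'   (location shared). Used by the one-parameter follow-up DIF tests.
#' @param start optional warm start: list with `ref`, `focal`
#'   ([ItemParameters-class]) and `focalMean`, `focalVar`.
#' @return A [GroupModel-class].
#' @export
fitMultigroup <- function(data, anchored = character(),
                          estimateMoments = NULL, grid = quadratureGrid(),
                          control = list(), partial = NULL, start = NULL) {
  ctl <- .emControl(control)
  prep <- .prepareGroups(data, ctl)
  constraint <- .buildConstraint(prep$items, anchored, partial)
  if (is.null(estimateMoments)) estimateMoments <- any(constraint == "both")
  .emMultigroup(prep, constraint, estimateMoments, grid, ctl, start)
}

# Validate two-group data and collapse each group's response patterns.
.prepareGroups <- function(data, ctl) {
  stopifnot(is(data, "ResponseMatrix"))
  Y <- responses(data)
  grp <- groupLabels(data)
  if (nlevels(grp) != 2L || length(grp) != nrow(Y))
    stop("data must carry a two-level group factor (reference level first)")
  groups <- levels(grp)
  Ys <- list(Y[grp == groups[1L], , drop = FALSE],
             Y[grp == groups[2L], , drop = FALSE])
  for (g in 1:2) {
    if (nrow(Ys[[g]]) < ctl$minGroupN)
      stop(sprintf("group '%s' has %d respondents; the floor is %d (control$minGroupN)",
                   groups[g], nrow(Ys[[g]]), ctl$minGroupN))
    .checkItemVariance(Ys[[g]], label = groups[g])
  }
  phat <- colMeans(Y, na.rm = TRUE)
  list(items = colnames(Y), groups = groups,
       pats = lapply(Ys, .collapsePatterns),
       n = nrow(Y), phat = phat)
}

# Expand anchors + partial constraints to a per-item constraint vector.
.buildConstraint <- function(items, anchored = character(), partial = NULL) {
  if (is.logical(anchored)) {
    if (is.null(names(anchored)) || !setequal(names(anchored), items))
      stop("a logical 'anchored' must be named by the items")
    anchored <- names(which(anchored[items]))
  }
  if (!all(anchored %in% items))
    stop("unknown anchor item(s): ", paste(setdiff(anchored, items), collapse = ", "))
  constraint <- stats::setNames(ifelse(items %in% anchored, "both", "none"), items)
  if (!is.null(partial)) {
    if (!all(names(partial) %in% items) || !all(partial %in% c("a", "b")))
      stop("'partial' must be a named vector with values \"a\" or \"b\"")
    if (any(names(partial) %in% anchored))
      stop("partial constraints cannot target anchored items")
    constraint[names(partial)] <- partial
  }
  constraint
}

# Core two-group EM on prepared patterns.
.emMultigroup <- function(prep, constraint, estimateMoments, grid, ctl,
                          start = NULL) {
  if (estimateMoments && !any(constraint == "both"))
    stop("identification error: focal latent moments cannot be estimated without anchors")
  items <- prep$items
  pats <- prep$pats
  J <- length(items)
  nodes <- grid@nodes

  if (is.null(start)) {
    a <- matrix(1, J, 2L)
    b <- matrix(-stats::qlogis(pmin(pmax(prep$phat, 0.02), 0.98)), J, 2L)
    mu <- 0; v <- 1
  } else {
    a <- cbind(start$ref@a, start$focal@a)
    b <- cbind(start$ref@b, start$focal@b)
    mu <- start$focalMean; v <- start$focalVar
  }
  if (!estimateMoments) { mu <- 0; v <- 1 }

  iBoth <- which(constraint == "both")
  iFree <- which(constraint == "none")
  iPart <- which(constraint %in% c("a", "b"))

  trace <- numeric(0); converged <- FALSE; capped <- FALSE; iter <- 0L
  for (iter in seq_len(ctl$maxit)) {
    wFoc <- .normalWeights(nodes, mu, v)
    ec <- vector("list", 2L); logLik <- 0
    mFoc <- NULL
    for (g in 1:2) {
      ll <- .patternLoglik(pats[[g]], .logProbs(a[, g], b[, g], nodes))
      post <- .posterior(ll, if (g == 1L) grid@weights else wFoc,
                         pats[[g]]$counts)
      logLik <- logLik + post$logLik
      ec[[g]] <- .expectedCounts(pats[[g]], pats[[g]]$counts, post$post)
      if (g == 2L) mFoc <- colSums(pats[[g]]$counts * post$post)
    }
    trace <- c(trace, logLik)

    aNew <- a; bNew <- b; capped <- FALSE
    if (length(iBoth)) {
      m <- .mstepVec(ec[[1L]]$r[iBoth, , drop = FALSE] + ec[[2L]]$r[iBoth, , drop = FALSE],
                     ec[[1L]]$n[iBoth, , drop = FALSE] + ec[[2L]]$n[iBoth, , drop = FALSE],
                     nodes, a[iBoth, 1L], b[iBoth, 1L],
                     ridge = ctl$ridge, slopeCap = ctl$slopeCap)
      aNew[iBoth, 1L] <- aNew[iBoth, 2L] <- m$a
      bNew[iBoth, 1L] <- bNew[iBoth, 2L] <- m$b
      capped <- capped || m$capped
    }
    if (length(iFree)) for (g in 1:2) {
      m <- .mstepVec(ec[[g]]$r[iFree, , drop = FALSE],
                     ec[[g]]$n[iFree, , drop = FALSE],
                     nodes, a[iFree, g], b[iFree, g],
                     ridge = ctl$ridge, slopeCap = ctl$slopeCap)
      aNew[iFree, g] <- m$a; bNew[iFree, g] <- m$b
      capped <- capped || m$capped
    }
    for (j in iPart) {
      m <- .mstepNewton(list(ec[[1L]]$r[j, ], ec[[2L]]$r[j, ]),
                        list(ec[[1L]]$n[j, ], ec[[2L]]$n[j, ]),
                        nodes, constraint = constraint[j],
                        start = list(c(a[j, 1L], b[j, 1L]), c(a[j, 2L], b[j, 2L])),
                        ridge = ctl$ridge, slopeCap = ctl$slopeCap)
      aNew[j, ] <- vapply(m$ab, `[`, numeric(1L), 1L)
      bNew[j, ] <- vapply(m$ab, `[`, numeric(1L), 2L)
      capped <- capped || m$capped
    }
    muNew <- mu; vNew <- v
    if (estimateMoments) {
      Nf <- sum(mFoc)
      muNew <- sum(mFoc * nodes) / Nf
      vNew <- max(sum(mFoc * nodes^2) / Nf - muNew^2, 1e-3)
    }
    delta <- max(abs(c(aNew - a, bNew - b, muNew - mu, vNew - v)))
    a <- aNew; b <- bNew; mu <- muNew; v <- vNew
    if (delta < ctl$tol) { converged <- TRUE; break }
  }

  # final log-likelihood at the returned parameter values
  wFoc <- .normalWeights(nodes, mu, v)
  logLik <- 0
  for (g in 1:2) {
    ll <- .patternLoglik(pats[[g]], .logProbs(a[, g], b[, g], nodes))
    logLik <- logLik +
      .posterior(ll, if (g == 1L) grid@weights else wFoc, pats[[g]]$counts)$logLik
  }
  trace <- c(trace, logLik)

  nPar <- sum(c(both = 2L, a = 3L, b = 3L, none = 4L)[constraint]) +
    if (estimateMoments) 2L else 0L
  fit <- new("FitSummary", logLik = logLik, nParameters = as.integer(nPar),
             n = as.integer(prep$n), converged = converged && !capped,
             nIterations = iter, logLikTrace = trace)
  new("GroupModel", groups = prep$groups,
      refParams = itemParameters(items, a[, 1L], b[, 1L]),
      focalParams = itemParameters(items, a[, 2L], b[, 2L]),
      anchored = stats::setNames(constraint == "both", items),
      focalMean = mu, focalVar = v,
      momentsEstimated = estimateMoments, fit = fit)
}

# Warm start extracted from a fitted GroupModel.
.warmStart <- function(model)
  list(ref = model@refParams, focal = model@focalParams,
       focalMean = model@focalMean, focalVar = model@focalVar)

#' Group-specific parameters from a multigroup model
#'
#' @param model a [GroupModel-class].
#' @param group "reference" or "focal", or one of the group labels.
#' @return The group's [ItemParameters-class].
#' @export
groupParameters <- function(model, group = c("reference", "focal")) {
  stopifnot(is(model, "GroupModel"))
  if (group[1L] %in% model@groups)
    group <- c("reference", "focal")[match(group[1L], model@groups)]
  group <- match.arg(group)
  if (group == "reference") model@refParams else model@focalParams
}
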