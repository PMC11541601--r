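#' Fit a single-group 2PL model by marginal maximum likelihood
#'
#' Bock-Aitkin EM with a fixed standard-normal latent distribution: the
#' E-step computes each response pattern's posterior over the quadrature
#' nodes, the M-step refits each item's logistic curve to the expected
#' success/trial counts by damped Newton iterations. The observed-data
#' log-likelihood is non-decreasing across cycles.
#'
#' @param data a [ResponseMatrix-class] (any group labels are ignored).
#' @param grid a [QuadratureGrid-class]; 61 nodes on \[-6, 6\] by default.
#' @param control list overriding defaults: `tol` (max absolute parameter
#'   change declaring convergence, 1e-4), `maxit` (EM cycle cap, 500),
#'   `ridge` (slope penalty, 0), `slopeCap` (upper bound on a, 50).
#' @param start optional [ItemParameters-class] of starting values.
#' @return A [TwoPLFit-class]. The fit is flagged not converged when the
#'   cycle cap is reached or any slope escapes to the cap (as happens for
#'   Guttman-perfect data).
#' @examples
#' cfg <- simulationConfig(n = 500, seed = 7)
#' fit <- fit2pl(simulateResponses(cfg))
#' itemParams(fit)
#' @export
fit2pl <- function(data, grid = quadratureGrid(), control = list(),
                   start = NULL) {
  stopifnot(is(data, "ResponseMatrix"), is(grid, "QuadratureGrid"))
  ctl <- .emControl(control)
  Y <- responses(data)
  if (ncol(Y) < 2L) stop("at least 2 items are required")
  .checkItemVariance(Y)
  pat <- .collapsePatterns(Y)
  res <- .emSingle(pat, grid, ctl, start)
  items <- colnames(Y)
  params <- itemParameters(items, res$a, res$b)
  fit <- new("FitSummary", logLik = res$logLik,
             nParameters = 2L * ncol(Y), n = nrow(Y),
             converged = res$converged, nIterations = res$iter,
             logLikTrace = res$trace)
  new("TwoPLFit", params = params, fit = fit)
}

# Core single-group EM on collapsed patterns.
.emSingle <- function(pat, grid, ctl, start = NULL) {
  Y <- pat$Y; counts <- pat$counts
  J <- ncol(Y)
  nodes <- grid@nodes; w <- grid@weights
  if (is.null(start)) {
    phat <- colSums(Y * counts, na.rm = TRUE) /
      colSums((!is.na(Y)) * counts)
    a <- rep(1, J)
    b <- -stats::qlogis(pmin(pmax(phat, 0.02), 0.98))
  } else { a <- start@a; b <- start@b }

  trace <- numeric(0)
  converged <- FALSE; capped <- FALSE; iter <- 0L
  logLik <- -Inf
  for (iter in seq_len(ctl$maxit)) {
    ll <- .patternLoglik(pat, .logProbs(a, b, nodes))
    post <- .posterior(ll, w, counts)
    logLik <- post$logLik
    trace <- c(trace, logLik)
    ec <- .expectedCounts(pat, counts, post$post)
    m <- .mstepVec(ec$r, ec$n, nodes, a, b,
                   ridge = ctl$ridge, slopeCap = ctl$slopeCap)
    capped <- m$capped
    delta <- max(abs(c(m$a - a, m$b - b)))
    a <- m$a; b <- m$b
    if (delta < ctl$tol) { converged <- TRUE; break }
  }
  # final evaluation at the returned parameters
  ll <- .patternLoglik(pat, .logProbs(a, b, nodes))
  post <- .posterior(ll, w, counts)
  trace <- c(trace, post$logLik)
  list(a = a, b = b, logLik = post$logLik, trace = trace,
       converged = converged && !capped, iter = iter)
}

#' Expected a posteriori (EAP) latent-trait scores
#'
#' Posterior mean and SD of the latent trait for each respondent, given
#' fitted item parameters and a normal prior evaluated on the quadrature
#' grid. Identical response patterns receive identical scores.
#'
#' @param data a [ResponseMatrix-class].
#' @param params an [ItemParameters-class].
#' @param grid a [QuadratureGrid-class].
#' @param mean,var prior latent mean and variance (defaults 0, 1).
#' @return A [LatentScore-class] with one entry per respondent, in input
#'   order.
#' @export
eapScores <- function(data, params, grid = quadratureGrid(),
                      mean = 0, var = 1) {
  stopifnot(is(data, "ResponseMatrix"), is(params, "ItemParameters"))
  Y <- responses(data)
  if (!identical(colnames(Y), params@items))
    stop("item columns must match the parameter set (same items, same order)")
  pat <- .collapsePatterns(Y)
  sc <- .eapPatterns(pat, params, grid, mean, var)
  new("LatentScore", eap = sc$eap[pat$map], psd = sc$psd[pat$map])
}

# EAP per unique pattern (pat: a .patFromY()-style list).
.eapPatterns <- function(pat, params, grid, mean = 0, var = 1) {
  nodes <- grid@nodes
  w <- .normalWeights(nodes, mean, var)
  ll <- .patternLoglik(pat, .logProbs(params@a, params@b, nodes))
  post <- .posterior(ll, w, rep(1, nrow(pat$Y)))$post
  eap <- drop(post %*% nodes)
  m2 <- drop(post %*% nodes^2)
  list(eap = eap, psd = sqrt(pmax(m2 - eap^2, 1e-12)))
}
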