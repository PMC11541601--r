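# Two-parameter logistic building blocks: item/test characteristic
# functions, the loading conversion, quadrature, and the Lord-Wingersky
# summed-score recursion.

#' 2PL item characteristic curve
#'
#' Probability of endorsing a binary item under the two-parameter logistic
#' model, \eqn{P(\theta) = 1 / (1 + e^{-a(\theta - b)})}.
#'
#' @param theta latent-trait value(s).
#' @param a discrimination (slope), > 0 for a monotone increasing curve.
#' @param b difficulty: the latent location where P = 0.5.
#' @return Endorsement probabilities, recycled over the longest argument.
#' @examples
#' icc2pl(0, a = 1.752, b = 1.849)   # ~0.0377
#' icc2pl(1.849, a = 1.752, b = 1.849)  # exactly 0.5
#' @export
icc2pl <- function(theta, a, b) stats::plogis(a * (theta - b))

#' Convert a 2PL discrimination to a standardised factor loading
#'
#' Bridges the logistic slope metric to the normal-ogive factor-analytic
#' metric: \eqn{\lambda = (a/D) / \sqrt{1 + (a/D)^2}}. The communality is
#' the square of the returned loading.
#'
#' @param a discrimination(s), >= 0.
#' @param D scaling constant; 1.702 by default.
#' @return Loadings in [0, 1).
#' @examples
#' round(loadingFromDiscrimination(4.641), 3)  # 0.939
#' loadingFromDiscrimination(0)                # 0
#' @export
loadingFromDiscrimination <- function(a, D = 1.702) {
  if (any(!is.finite(a)) || any(a < 0))
    stop("discrimination 'a' must be finite and non-negative")
  if (length(D) != 1L || !is.finite(D) || D <= 0)
    stop("scaling constant 'D' must be a single positive number")
  x <- a / D
  x / sqrt(1 + x^2)
}

#' Fixed-node quadrature grid with standard-normal weights
#'
#' Equally spaced nodes carrying renormalised standard-normal masses, the
#' conventional grid for Bock-Aitkin marginal maximum likelihood.
#'
#' @param nNodes number of nodes (default 61).
#' @param bounds interval covered (default \[-6, 6\]).
#' @return A [QuadratureGrid-class].
#' @export
quadratureGrid <- function(nNodes = 61L, bounds = c(-6, 6)) {
  nodes <- seq(bounds[1L], bounds[2L], length.out = nNodes)
  w <- stats::dnorm(nodes)
  new("QuadratureGrid", nodes = nodes, weights = w / sum(w))
}

# Renormalised N(mean, var) masses on an existing grid (focal-group prior).
.normalWeights <- function(nodes, mean = 0, var = 1) {
  w <- stats::dnorm(nodes, mean = mean, sd = sqrt(var))
  w / sum(w)
}

#' Test characteristic curve
#'
#' Expected sum score \eqn{TCC(\theta) = \sum_j P_j(\theta)}; strictly
#' increasing from 0 to the number of items.
#'
#' @param theta latent-trait value(s).
#' @param params an [ItemParameters-class].
#' @return Expected sum scores, one per `theta`.
#' @export
tcc <- function(theta, params) {
  stopifnot(is(params, "ItemParameters"))
  vapply(theta, function(th) sum(icc2pl(th, params@a, params@b)),
         numeric(1L), USE.NAMES = FALSE)
}

#' Lord-Wingersky summed-score distribution
#'
#' Exact conditional distribution of the sum score given the latent trait,
#' by the standard recursion: start from the first item's Bernoulli
#' distribution and convolve the remaining items in one at a time.
#'
#' @param theta latent-trait value(s).
#' @param params an [ItemParameters-class] for J items.
#' @return Matrix with one row per `theta` and columns "0"..."J"; each row
#'   sums to 1 within 1e-12.
#' @examples
#' p <- itemParameters(c("i1", "i2"), a = c(1, 2), b = c(0, 1))
#' lordWingersky(0, p)
#' @export
lordWingersky <- function(theta, params) {
  stopifnot(is(params, "ItemParameters"))
  J <- length(params@a)
  out <- matrix(0, length(theta), J + 1L,
                dimnames = list(NULL, as.character(0:J)))
  for (i in seq_along(theta)) {
    p <- icc2pl(theta[i], params@a, params@b)
    f <- c(1 - p[1L], p[1L])
    if (J > 1L) for (j in 2:J) {
      f <- c(f * (1 - p[j]), 0) + c(0, f * p[j])
    }
    out[i, ] <- f
  }
  out
}

#' Probability of meeting a sum-score cut given the latent trait
#'
#' @param theta latent-trait value(s).
#' @param params an [ItemParameters-class].
#' @param cut sum-score cut c; returns P(X >= c | theta).
#' @return Probabilities, one per `theta`.
#' @export
cutExceedanceProb <- function(theta, params, cut = 1) {
  pmf <- lordWingersky(theta, params)
  J <- ncol(pmf) - 1L
  cols <- which(0:J >= cut)
  if (!length(cols)) return(rep(0, length(theta)))
  rowSums(pmf[, cols, drop = FALSE])
}
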