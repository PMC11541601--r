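# Tetrachoric correlation by two-step maximum likelihood: thresholds from
# the margins, then the bivariate-normal correlation maximising the 2x2
# multinomial likelihood. The bivariate normal CDF is computed by reducing
# to a univariate integral against the conditional normal CDF.

# P(Z1 <= h, Z2 <= k) for standard bivariate normal with correlation rho.
.pbvnorm <- function(h, k, rho) {
  if (abs(rho) < 1e-12) return(stats::pnorm(h) * stats::pnorm(k))
  if (rho > 1 - 1e-12) return(stats::pnorm(min(h, k)))
  if (rho < -1 + 1e-12) return(max(stats::pnorm(h) + stats::pnorm(k) - 1, 0))
  s <- sqrt(1 - rho^2)
  f <- function(x) stats::dnorm(x) * stats::pnorm((k - rho * x) / s)
  stats::integrate(f, -8.5, h, rel.tol = 1e-10, abs.tol = 1e-12)$value
}

#' Tetrachoric correlation of two binary items
#'
#' Estimates the correlation of the latent bivariate normal generating a
#' 2x2 table, with thresholds fixed at the margins. A 0.5 continuity
#' correction is added to all cells when exactly one cell is empty
#' (flagged). Tables with an empty diagonal or anti-diagonal pair are
#' degenerate: the ML estimate diverges, so the correlation is clamped at
#' the +/-(1 - 1e-6) boundary and flagged.
#'
#' @param x,y binary (0/1) vectors of equal length; each must show both
#'   categories.
#' @return List: `rho`, `thresholds` (length 2), `flag` (correction or
#'   clamping applied).
#' @export
tetrachoric <- function(x, y) {
  ok <- !(is.na(x) | is.na(y))
  x <- x[ok]; y <- y[ok]
  if (!all(x %in% 0:1) || !all(y %in% 0:1)) stop("inputs must be binary 0/1")
  if (length(unique(x)) < 2L || length(unique(y)) < 2L)
    stop("both vectors must contain both response categories")
  n11 <- sum(x == 1 & y == 1); n10 <- sum(x == 1 & y == 0)
  n01 <- sum(x == 0 & y == 1); n00 <- sum(x == 0 & y == 0)
  .tetrachoricCells(n11, n10, n01, n00)
}

.tetrachoricCells <- function(n11, n10, n01, n00) {
  bound <- 1 - 1e-6
  flag <- FALSE
  cells <- c(n11, n10, n01, n00)
  nEmpty <- sum(cells == 0)
  if ((n10 == 0 && n01 == 0) || (n11 == 0 && n00 == 0)) {
    # perfectly concordant/discordant: ML diverges to the boundary
    rho <- if (n10 == 0 && n01 == 0) bound else -bound
    n <- sum(cells)
    tx <- stats::qnorm((n01 + n00) / n); ty <- stats::qnorm((n10 + n00) / n)
    return(list(rho = rho, thresholds = c(tx, ty), flag = TRUE))
  }
  if (nEmpty > 0) { cells <- cells + 0.5; flag <- TRUE }
  n <- sum(cells)
  n11 <- cells[1L]; n10 <- cells[2L]; n01 <- cells[3L]; n00 <- cells[4L]
  # thresholds: P(X = 0) = pnorm(tx)
  tx <- stats::qnorm((n01 + n00) / n)
  ty <- stats::qnorm((n10 + n00) / n)
  negLL <- function(r) {
    p00 <- .pbvnorm(tx, ty, r)
    p0x <- stats::pnorm(tx); px0 <- stats::pnorm(ty)
    p01 <- p0x - p00; p10 <- px0 - p00
    p11 <- 1 - p0x - px0 + p00
    p <- pmax(c(p11, p10, p01, p00), 1e-12)
    -(n11 * log(p[1L]) + n10 * log(p[2L]) + n01 * log(p[3L]) + n00 * log(p[4L]))
  }
  opt <- stats::optimize(negLL, c(-bound, bound), tol = 1e-8)
  rho <- opt$minimum
  if (abs(rho) > bound - 1e-4) { rho <- sign(rho) * bound; flag <- TRUE }
  list(rho = rho, thresholds = c(tx, ty), flag = flag)
}

#' Pairwise tetrachoric correlation matrix
#'
#' @param data a [ResponseMatrix-class] (groups ignored).
#' @return A [TetrachoricMatrix-class].
#' @export
tetrachoricMatrix <- function(data) {
  stopifnot(is(data, "ResponseMatrix"))
  Y <- responses(data)
  J <- ncol(Y)
  rho <- diag(1, J); flags <- matrix(FALSE, J, J)
  dimnames(rho) <- dimnames(flags) <- list(colnames(Y), colnames(Y))
  thr <- stats::qnorm(1 - colMeans(Y, na.rm = TRUE))
  for (i in seq_len(J - 1L)) for (j in (i + 1L):J) {
    tt <- tetrachoric(Y[, i], Y[, j])
    rho[i, j] <- rho[j, i] <- tt$rho
    flags[i, j] <- flags[j, i] <- tt$flag
  }
  new("TetrachoricMatrix", rho = rho, thresholds = stats::setNames(thr, colnames(Y)),
      flags = flags)
}
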