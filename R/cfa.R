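#' One-factor CFA on a tetrachoric correlation matrix
#'
#' Least-squares factor analysis of the binary indicators: loadings
#' minimise the (optionally weighted) squared off-diagonal residuals
#' between the tetrachoric correlations and the rank-one structure
#' \eqn{\lambda \lambda'}. Global approximate-fit indices (RMSEA, CFI,
#' TLI) are derived from a sample-size-scaled least-squares discrepancy
#' against the independence baseline; SRMSR is the root mean square
#' off-diagonal residual. These indices are estimator-dependent
#' conventions — comparable across models fit by this function, not across
#' software. The per-item RMSEA applies the same scaling to one item's
#' residual row.
#'
#' @param R a [TetrachoricMatrix-class] or a plain correlation matrix.
#' @param n sample size behind the correlations (used in the index
#'   scaling).
#' @param weights optional symmetric matrix of positive least-squares
#'   weights (diagonally weighted least squares); unweighted by default.
#' @param smooth smooth a non-positive-semidefinite matrix by flooring its
#'   eigenvalues at 1e-6 and rescaling to unit diagonal (default TRUE;
#'   with `smooth = FALSE` a non-PSD input is an error).
#' @return A [CFAFit-class].
#' @examples
#' lam <- c(0.8, 0.7, 0.6, 0.5)
#' R <- tcrossprod(lam); diag(R) <- 1
#' fitOneFactor(R, n = 1000)
#' @export
fitOneFactor <- function(R, n, weights = NULL, smooth = TRUE) {
  if (is(R, "TetrachoricMatrix")) R <- R@rho
  R <- as.matrix(R)
  J <- nrow(R)
  stopifnot(J >= 3L, isTRUE(all.equal(R, t(R), tolerance = 1e-8)))
  ev <- eigen(R, symmetric = TRUE)
  if (min(ev$values) < -1e-10) {
    if (!smooth)
      stop("correlation matrix is not positive semi-definite (set smooth = TRUE)")
    vals <- pmax(ev$values, 1e-6)
    R <- ev$vectors %*% (vals * t(ev$vectors))
    d <- sqrt(diag(R))
    R <- R / tcrossprod(d)
    ev <- eigen(R, symmetric = TRUE)
  }
  W <- if (is.null(weights)) matrix(1, J, J) else as.matrix(weights)
  off <- upper.tri(R)

  # start: first principal component scaled to unit length loadings
  lam0 <- ev$vectors[, 1L] * sqrt(max(ev$values[1L], 0.1))
  lam0 <- pmin(pmax(lam0, -0.995), 0.995)
  fn <- function(l) {
    res <- R - tcrossprod(l)
    sum(W[off] * res[off]^2)
  }
  gr <- function(l) {
    res <- (R - tcrossprod(l)) * W
    diag(res) <- 0
    -2 * drop(res %*% l)
  }
  opt <- stats::optim(lam0, fn, gr, method = "BFGS",
                      control = list(maxit = 1000L, reltol = 1e-14))
  lam <- opt$par
  if (mean(lam) < 0) lam <- -lam
  res <- R - tcrossprod(lam)
  diag(res) <- 0

  srmsr <- sqrt(mean(res[off]^2))
  # scaled discrepancy vs the independence baseline
  Tstat <- (n - 1) * sum(res[off]^2)
  df <- J * (J - 1) / 2 - J
  Tbase <- (n - 1) * sum(R[off]^2)
  dfBase <- J * (J - 1) / 2
  rmsea <- sqrt(max(Tstat - df, 0) / (df * (n - 1)))
  cfi <- 1 - max(Tstat - df, 0) / max(Tbase - dfBase, Tstat - df, 0)
  tli <- min(((Tbase / dfBase) - (Tstat / df)) / ((Tbase / dfBase) - 1), 1)
  dfItem <- J - 2
  itemRmsea <- vapply(seq_len(J), function(j) {
    Tj <- (n - 1) * sum(res[j, -j]^2)
    sqrt(max(Tj - dfItem, 0) / (dfItem * (n - 1)))
  }, numeric(1L))
  names(lam) <- names(itemRmsea) <- rownames(R)
  new("CFAFit", loadings = lam, h2 = lam^2, srmsr = srmsr, rmsea = rmsea,
      cfi = cfi, tli = tli, itemRmsea = itemRmsea, discrepancy = Tstat,
      df = df, n = as.integer(n))
}

#' Serialise a CFA fit report to JSON
#'
#' @param fit a [CFAFit-class].
#' @param path file to write (or NULL to return the JSON string).
#' @return The JSON string, invisibly when written to file. Conventional
#'   good-fit annotations (RMSEA and SRMSR at or below 0.05, CFI and TLI at
#'   or above 0.95) are included as report annotations only.
#' @export
cfaReport <- function(fit, path = NULL) {
  stopifnot(is(fit, "CFAFit"))
  rep <- list(loadings = as.list(round(fit@loadings, 6)),
              h2 = as.list(round(fit@h2, 6)),
              srmsr = fit@srmsr, rmsea = fit@rmsea,
              cfi = fit@cfi, tli = fit@tli,
              item_rmsea = as.list(round(fit@itemRmsea, 6)),
              n = fit@n,
              conventional_cutoffs = list(rmsea_srmsr_max = 0.05,
                                          cfi_tli_min = 0.95))
  js <- jsonlite::toJSON(rep, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
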