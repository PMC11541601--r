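# Internal machinery shared by the single-group and multigroup marginal
# maximum likelihood (Bock-Aitkin EM) fits. Response data are collapsed to
# unique patterns so the cost per EM cycle is bounded by the number of
# distinct patterns (<= 2^J), not the sample size.

# Collapse a 0/1/NA matrix to unique patterns with counts. Patterns are
# keyed by base-3 encoding (NA -> 2); falls back to string keys for wide
# matrices where the encoding would overflow.
.collapsePatterns <- function(Y) {
  J <- ncol(Y)
  if (J <= 30L) {
    Z <- Y; Z[is.na(Z)] <- 2L
    key <- drop(Z %*% 3^(seq_len(J) - 1L))
  } else {
    key <- apply(Y, 1L, function(r) paste(ifelse(is.na(r), "N", r), collapse = ""))
  }
  idx <- which(!duplicated(key))
  counts <- tabulate(match(key, key[idx]), nbins = length(idx))
  c(.patFromY(Y[idx, , drop = FALSE]),
    list(counts = as.numeric(counts), map = match(key, key[idx])))
}

# Pattern matrix with cached observed-indicator and zero-filled copies.
.patFromY <- function(Y) {
  O <- !is.na(Y)
  Y0 <- Y; Y0[!O] <- 0L
  storage.mode(Y0) <- "double"; storage.mode(O) <- "double"
  list(Y = Y, Y0 = Y0, O = O)
}

# J x Q endorsement log-probabilities at the quadrature nodes.
.logProbs <- function(a, b, nodes) {
  eta <- outer(a, nodes) - a * b    # a_j * (theta_q - b_j)
  list(lp = stats::plogis(eta, log.p = TRUE),
       lq = stats::plogis(-eta, log.p = TRUE))
}

# Pattern-by-node conditional log-likelihood from a .patFromY() list.
.patternLoglik <- function(pat, lpq) {
  pat$Y0 %*% lpq$lp + (pat$O - pat$Y0) %*% lpq$lq
}

# Posterior over nodes and the observed-data log-likelihood.
# Returns list(post = patterns x Q, logLik = scalar).
.posterior <- function(ll, weights, counts) {
  lw <- sweep(ll, 2L, log(weights), "+")
  m <- lw[cbind(seq_len(nrow(lw)), max.col(lw, ties.method = "first"))]
  li <- m + log(rowSums(exp(lw - m)))
  list(post = exp(lw - li), logLik = sum(counts * li), patternLogLik = li)
}

# Expected success/trial counts per item and node from a posterior.
.expectedCounts <- function(pat, counts, post) {
  cp <- counts * post
  list(r = crossprod(pat$Y0, cp), n = crossprod(pat$O, cp))
}

# Vectorised damped-Newton M-step for a block of unconstrained items:
# each row of R (expected successes) and N (expected trials) is one item.
# Each accepted step cannot decrease that item's expected complete-data
# log-likelihood, so the EM ascent property is preserved.
.mstepVec <- function(R, N, nodes, a, b, ridge = 0, slopeCap = 50,
                      maxit = 4L) {
  J <- nrow(R)
  thetaM <- matrix(nodes, J, length(nodes), byrow = TRUE)
  obj <- function(a, b) {
    eta <- a * (thetaM - b)
    rowSums(R * eta - N * (pmax(eta, 0) + log1p(exp(-abs(eta))))) -
      ridge / 2 * a^2
  }
  f0 <- obj(a, b)
  for (it in seq_len(maxit)) {
    Z <- thetaM - b
    p <- stats::plogis(a * Z)
    e <- R - N * p
    s <- N * p * (1 - p)
    g1 <- rowSums(e * Z) - ridge * a
    g2 <- -a * rowSums(e)
    H11 <- -rowSums(s * Z^2) - ridge
    H12 <- a * rowSums(s * Z) - rowSums(e)
    H22 <- -a^2 * rowSums(s)
    det <- H11 * H22 - H12^2
    det[!is.finite(det) | abs(det) < 1e-12] <- 1e-12
    d1 <- (H22 * g1 - H12 * g2) / det
    d2 <- (H11 * g2 - H12 * g1) / det
    lam <- rep(1, J)
    for (h in 1:12) {
      aT <- pmin(pmax(a - lam * d1, 1e-3), slopeCap)
      bT <- b - lam * d2
      fT <- obj(aT, bT)
      bad <- !(is.finite(fT) & fT >= f0 - 1e-12)
      if (!any(bad)) { a <- aT; b <- bT; f0 <- fT; break }
      if (h == 12L) {
        aT[bad] <- a[bad]; bT[bad] <- b[bad]; fT[bad] <- f0[bad]
        a <- aT; b <- bT; f0 <- fT; break
      }
      lam[bad] <- lam[bad] / 2
    }
  }
  list(a = a, b = b, capped = any(a >= slopeCap - 1e-9))
}

# Per-group 2PL gradient and Hessian of the expected complete-data
# log-likelihood for one item, in the (a, b) parameterisation.
#   e_q = r_q - n_q p_q, s_q = n_q p_q (1 - p_q), z_q = theta_q - b.
.itemDerivs <- function(a, b, r, n, nodes) {
  z <- nodes - b
  p <- stats::plogis(a * z)
  e <- r - n * p
  s <- n * p * (1 - p)
  ab <- sum(a * s * z - e)
  list(g = c(sum(e * z), -a * sum(e)),
       H = matrix(c(-sum(s * z^2), ab, ab, -a^2 * sum(s)), 2L, 2L))
}

# Binomial log-likelihood of expected counts: sum r*eta - n*log(1+e^eta).
.binomLoglik <- function(r, n, eta) {
  sum(r * eta) - sum(n * (pmax(eta, 0) + log1p(exp(-abs(eta)))))
}

# Constrained Newton M-step for one item across G groups.
# constraint: "both" (a and b shared), "a" (a shared), "b" (b shared),
# "none" (all free). rList/nList: expected counts per group. start: list of
# c(a, b) per group. Returns list of c(a, b) per group plus a cap flag.
# `maxit` defaults to a handful of damped Newton steps: each step cannot
# decrease the expected complete-data log-likelihood, so the EM ascent
# property holds for any maxit (generalised EM).
.mstepNewton <- function(rList, nList, nodes, constraint = "both",
                         start, ridge = 0, slopeCap = 50,
                         maxit = 4L, tol = 1e-9) {
  G <- length(rList)
  # map free parameter vector p -> per-group (a, b)
  expand <- switch(constraint,
    both = function(p) rep(list(p), G),
    none = function(p) split(p, rep(seq_len(G), each = 2L)),
    a    = function(p) lapply(seq_len(G), function(g) c(p[1L], p[1L + g])),
    b    = function(p) lapply(seq_len(G), function(g) c(p[g], p[G + 1L])),
    stop("unknown constraint: ", constraint))
  p <- switch(constraint,
    both = start[[1L]],
    none = unlist(start),
    a    = c(start[[1L]][1L], vapply(start, `[`, numeric(1L), 2L)),
    b    = c(vapply(start, `[`, numeric(1L), 1L), start[[1L]][2L]))
  # indices of (a, b) of group g within the free vector
  coord <- switch(constraint,
    both = lapply(seq_len(G), function(g) c(1L, 2L)),
    none = lapply(seq_len(G), function(g) c(2L * g - 1L, 2L * g)),
    a    = lapply(seq_len(G), function(g) c(1L, 1L + g)),
    b    = lapply(seq_len(G), function(g) c(g, G + 1L)))
  aIdx <- unique(vapply(coord, `[`, integer(1L), 1L))

  objective <- function(p) {
    ab <- expand(p)
    ll <- 0
    for (g in seq_len(G))
      ll <- ll + .binomLoglik(rList[[g]], nList[[g]],
                              ab[[g]][1L] * (nodes - ab[[g]][2L]))
    ll - ridge / 2 * sum(p[aIdx]^2)
  }

  f0 <- objective(p)
  for (it in seq_len(maxit)) {
    ab <- expand(p)
    g <- numeric(length(p))
    H <- matrix(0, length(p), length(p))
    for (gg in seq_len(G)) {
      d <- .itemDerivs(ab[[gg]][1L], ab[[gg]][2L], rList[[gg]], nList[[gg]], nodes)
      ci <- coord[[gg]]
      g[ci] <- g[ci] + d$g
      H[ci, ci] <- H[ci, ci] + d$H
    }
    if (ridge > 0) {
      g[aIdx] <- g[aIdx] - ridge * p[aIdx]
      diag(H)[aIdx] <- diag(H)[aIdx] - ridge
    }
    step <- tryCatch(solve(H, g), error = function(e) g / max(abs(diag(H)), 1))
    # damped Newton: halve until the expected complete-data loglik improves
    lam <- 1
    repeat {
      pNew <- p - lam * step
      # keep slopes positive and bounded
      pNew[aIdx] <- pmin(pmax(pNew[aIdx], 1e-3), slopeCap)
      fNew <- objective(pNew)
      if (is.finite(fNew) && fNew >= f0 - 1e-12) break
      lam <- lam / 2
      if (lam < 1e-8) { pNew <- p; fNew <- f0; break }
    }
    delta <- max(abs(pNew - p))
    p <- pNew; f0 <- fNew
    if (delta < tol) break
  }
  ab <- expand(p)
  list(ab = ab, capped = any(vapply(ab, `[`, numeric(1L), 1L) >= slopeCap - 1e-9))
}

.emControl <- function(control = list()) {
  ctl <- list(tol = 1e-4, maxit = 500L, ridge = 0, slopeCap = 50,
              minGroupN = 200L)
  ctl[names(control)] <- control
  ctl
}

# Refuse to fit items without both response categories (per group when a
# group factor is supplied via `label`).
.checkItemVariance <- function(Y, label = NULL) {
  p <- colMeans(Y, na.rm = TRUE)
  bad <- which(!is.finite(p) | p <= 0 | p >= 1)
  if (length(bad))
    stop("item(s) with a single observed response category",
         if (!is.null(label)) paste0(" in group '", label, "'") else "",
         ": ", paste(colnames(Y)[bad], collapse = ", "))
  invisible(TRUE)
}
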