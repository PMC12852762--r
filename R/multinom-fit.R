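# Maximum-likelihood multinomial (softmax) logistic regression by Newton's
# method with step halving. Written for the bootstrap hot path: supports
# frequency weights (so resampling never copies data) and warm starts from
# the full-data fit. Cross-checked against nnet::multinom in the test suite.

# X: n x p design (with intercept); y: integer classes 1..K (1 = reference);
# w: frequency/analytic weights. Returns B (p x (K-1)) plus diagnostics.
.fit_multinom <- function(X, y, K, w = NULL, start = NULL,
                          tol = 1e-6, maxit = 200L) {
  n <- nrow(X); p <- ncol(X)
  if (is.null(w)) w <- rep(1, n)
  Y <- matrix(0, n, K - 1L)
  pos <- y > 1L
  Y[cbind(which(pos), y[pos] - 1L)] <- 1
  B <- if (is.null(start)) matrix(0, p, K - 1L) else start

  iy <- cbind(seq_len(n), pmax(y - 1L, 1L))
  posd <- as.numeric(pos)
  rowmax0 <- function(eta) {
    m <- rep(0, nrow(eta))
    for (j in seq_len(ncol(eta))) m <- pmax(m, eta[, j])
    m
  }
  loglik <- function(B) {
    eta <- X %*% B
    if (max(eta) < 30) {                     # overflow-safe fast path
      lse <- log1p(rowSums(exp(eta)))
    } else {
      m <- rowmax0(eta)
      lse <- m + log(exp(-m) + rowSums(exp(eta - m)))
    }
    sum(w * (posd * eta[iy] - lse))
  }
  probs <- function(B) {
    eta <- X %*% B
    if (max(eta) < 30) {
      E <- exp(eta)
      denom <- 1 + rowSums(E)
    } else {
      m <- rowmax0(eta)
      E <- exp(eta - m)
      denom <- exp(-m) + rowSums(E)
    }
    E / denom
  }
  ll <- loglik(B)
  if (!is.finite(ll)) {                      # unusable warm start: cold-start
    B <- matrix(0, p, K - 1L)
    ll <- loglik(B)
  }
  converged <- FALSE
  iter <- 0L
  Km <- K - 1L
  for (iter in seq_len(maxit)) {
    P <- probs(B)                       # n x (K-1), classes 2..K
    G <- crossprod(X, w * (Y - P))      # p x (K-1)
    if (max(abs(G)) < tol) { converged <- TRUE; break }
    H <- matrix(0, p * Km, p * Km)
    for (a in seq_len(Km)) {
      for (b in a:Km) {
        wab <- w * (P[, a] * ((a == b) - P[, b]))
        blk <- crossprod(X, wab * X)
        ra <- (a - 1L) * p + seq_len(p); rb <- (b - 1L) * p + seq_len(p)
        H[ra, rb] <- blk
        if (a != b) H[rb, ra] <- blk
      }
    }
    # ridge ladder: quasi-separated fits flatten the Hessian
    ridge_scale <- max(mean(abs(diag(H))), 1e-8)
    step <- NULL
    for (lambda in c(0, 1e-8, 1e-4, 1e-2) * ridge_scale) {
      step <- tryCatch(solve(H + diag(lambda + 1e-12, nrow(H)),
                             as.vector(G)),
                       error = function(e) NULL)
      if (!is.null(step) && all(is.finite(step))) break
      step <- NULL
    }
    if (is.null(step)) {
      warning("multinomial fit: singular Hessian, stopping early")
      break
    }
    # trust region: cap huge steps from near-separated configurations
    if (max(abs(step)) > 10) step <- step * (10 / max(abs(step)))
    shrink <- 1
    repeat {
      Bn <- B + matrix(shrink * step, p, Km)
      lln <- loglik(Bn)
      if (lln >= ll - 1e-10 || shrink < 1e-4) break
      shrink <- shrink / 2
    }
    if (abs(lln - ll) < 1e-12 && max(abs(G)) < sqrt(tol)) {
      B <- Bn; ll <- lln; converged <- TRUE; break
    }
    B <- Bn; ll <- lln
  }
  P <- probs(B)
  list(coefficients = B, fitted = cbind(1 - rowSums(P), P),
       loglik = ll, converged = converged, iterations = iter,
       gradient_norm = max(abs(crossprod(X, w * (Y - probs(B))))))
}
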