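# Lawson-Hanson active-set non-negative least squares:
# minimize ||C x - d||^2 subject to x >= 0.
# Standard algorithm with a generous iteration budget; the regularized
# IFT systems solved here are ill-conditioned enough that tightly capped
# implementations abort before convergence.
nnls_lh <- function(C, d, itmax = NULL) {
  m <- nrow(C); n <- ncol(C)
  stopifnot(length(d) == m)
  if (is.null(itmax)) itmax <- 50L * n
  tol <- 10 * .Machine$double.eps * norm(C, type = "2") * (max(n, m) + 1)
  x <- numeric(n)
  P <- logical(n)
  w <- crossprod(C, d - C %*% x)
  it <- 0L
  while (any(!P) && any(w[!P] > tol) && it < itmax) {
    wz <- rep(-Inf, n)
    wz[!P] <- w[!P]
    P[which.max(wz)] <- TRUE
    z <- numeric(n)
    z[P] <- tryCatch(qr.solve(C[, P, drop = FALSE], d),
                     error = function(e)
                       qr.coef(qr(C[, P, drop = FALSE],
                                  LAPACK = TRUE), d))
    z[P][is.na(z[P])] <- 0
    while (any(z[P] <= 0)) {
      it <- it + 1L
      if (it > itmax) break
      Q <- (z <= 0) & P
      a <- suppressWarnings(min(x[Q] / (x[Q] - z[Q]), na.rm = TRUE))
      if (!is.finite(a)) a <- 0
      x <- x + a * (z - x)
      P <- P & !(abs(x) < tol)
      z <- numeric(n)
      z[P] <- tryCatch(qr.solve(C[, P, drop = FALSE], d),
                       error = function(e)
                         qr.coef(qr(C[, P, drop = FALSE],
                                    LAPACK = TRUE), d))
      z[P][is.na(z[P])] <- 0
    }
    x <- z
    w <- crossprod(C, d - C %*% x)
    it <- it + 1L
  }
  list(x = pmax(x, 0), resid.norm = sum((d - C %*% x)^2))
}
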