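# Lawson-Hanson active-set non-negative least squares:
#   min ||A x - b||_2  subject to  x >= 0.
# Used by the expectation step when the unconstrained WLS solution leaves the
# feasible region. Dense A; problem sizes here are tiny (tens of unknowns).
nnls_solve <- function(A, b, tol = NULL, max_iter = NULL) {
  p <- ncol(A)
  if (is.null(tol)) tol <- 10 * .Machine$double.eps * max(abs(A)) * max(dim(A))
  if (is.null(max_iter)) max_iter <- 3L * p
  x <- numeric(p)
  passive <- logical(p)
  w <- drop(crossprod(A, b))          # gradient of 1/2||Ax-b||^2 at x = 0
  iter <- 0L
  while (any(!passive & w > tol) && iter < max_iter) {
    iter <- iter + 1L
    j <- which.max(ifelse(passive, -Inf, w))
    passive[j] <- TRUE
    repeat {
      Ap <- A[, passive, drop = FALSE]
      z <- numeric(p)
      z[passive] <- qr.coef(qr(Ap), b)
      z[passive][is.na(z[passive])] <- 0
      if (all(z[passive] > tol)) { x <- z; break }
      # step toward z until the first passive variable hits zero
      idx <- which(passive & z <= tol)
      alpha <- min(x[idx] / (x[idx] - z[idx]))
      x <- x + alpha * (z - x)
      passive <- passive & x > tol
      x[!passive] <- 0
    }
    w <- drop(crossprod(A, b - A %*% x))
  }
  x
}
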